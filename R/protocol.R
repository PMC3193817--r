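#' Piecewise-constant agonist application protocol
#'
#' A protocol is an ordered list of segments, each holding the agonist
#' concentration constant for a given duration; solution exchange is modelled
#' as instantaneous, matching fast-step perfusion. Segment durations are
#' snapped to the sampling grid.
#'
#' @param durations Segment durations in seconds (> 0).
#' @param concentrations Agonist concentration per segment, mM (>= 0).
#' @param sampling_interval Output sampling interval in seconds
#'   (default 1 ms).
#' @param max_samples Cap on total samples, guarding against accidental
#'   huge grids.
#' @return A `pulse_protocol` object.
#' @export
pulse_protocol <- function(durations, concentrations,
                           sampling_interval = 0.001,
                           max_samples = 2e6) {
  if (length(durations) != length(concentrations)) {
    stop("durations and concentrations must have equal length")
  }
  if (any(durations <= 0)) stop("segment durations must be positive")
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  if (sampling_interval <= 0) stop("sampling_interval must be positive")
  n_steps <- round(durations / sampling_interval)
  if (any(n_steps < 1)) stop("segment shorter than one sampling interval")
  if (any(abs(n_steps * sampling_interval - durations) > 1e-9)) {
    durations <- n_steps * sampling_interval
  }
  if (sum(n_steps) + 1 > max_samples) {
    stop("protocol exceeds max_samples (", max_samples, ")")
  }
  structure(list(durations = durations,
                 concentrations = concentrations,
                 sampling_interval = sampling_interval,
                 n_steps = as.integer(n_steps)),
            class = "pulse_protocol")
}

#' Paired-pulse protocol
#'
#' Two identical agonist pulses separated by a washout interval, preceded by
#' an agonist-free baseline and followed by a short tail, the standard
#' recovery-from-desensitization protocol.
#'
#' @param concentration Pulse agonist concentration, mM.
#' @param pulse_duration Pulse length, s.
#' @param interval Washout between pulse onsets' ends, s (must exceed
#'   `pulse_duration`... interpreted as the agonist-free gap between pulses).
#' @param baseline Agonist-free baseline before the first pulse, s.
#' @param tail Agonist-free tail after the second pulse, s.
#' @inheritParams pulse_protocol
#' @return A `pulse_protocol` with an attribute `pulse_onsets` giving the two
#'   pulse start times (s).
#' @export
paired_pulse_protocol <- function(concentration = 0.01, pulse_duration = 2,
                                  interval = 30, baseline = 0.5, tail = 1,
                                  sampling_interval = 0.001) {
  if (interval <= pulse_duration) {
    stop("interval must exceed pulse_duration")
  }
  if (pulse_duration < sampling_interval) {
    stop("pulse_duration must be at least one sampling interval")
  }
  durs <- c(baseline, pulse_duration, interval, pulse_duration, tail)
  concs <- c(0, concentration, 0, concentration, 0)
  keep <- durs > 0
  p <- pulse_protocol(durs[keep], concs[keep],
                      sampling_interval = sampling_interval)
  attr(p, "pulse_onsets") <- c(baseline, baseline + pulse_duration + interval)
  attr(p, "pulse_duration") <- pulse_duration
  p
}

#' Single-pulse protocol
#'
#' @inheritParams paired_pulse_protocol
#' @return A `pulse_protocol` with a `pulse_onsets` attribute of length 1.
#' @export
single_pulse_protocol <- function(concentration = 0.01, pulse_duration = 2,
                                  baseline = 0.5, tail = 0.5,
                                  sampling_interval = 0.001) {
  durs <- c(baseline, pulse_duration, tail)
  concs <- c(0, concentration, 0)
  keep <- durs > 0
  p <- pulse_protocol(durs[keep], concs[keep],
                      sampling_interval = sampling_interval)
  attr(p, "pulse_onsets") <- baseline
  attr(p, "pulse_duration") <- pulse_duration
  p
}

#' @export
print.pulse_protocol <- function(x, ...) {
  cat("Pulse protocol:", length(x$durations), "segments,",
      sum(x$durations), "s total, sampled at",
      1 / x$sampling_interval, "Hz\n")
  print(data.frame(duration_s = x$durations, conc_mM = x$concentrations))
  invisible(x)
}

#' Total duration of a protocol, seconds
#' @param protocol A `pulse_protocol`.
#' @return Numeric scalar.
#' @export
protocol_duration <- function(protocol) sum(protocol$durations)
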