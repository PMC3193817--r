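#' Baseline and peak amplitude of a current trace
#'
#' Baseline is the mean of the samples in the window preceding the response;
#' peak amplitude is the largest absolute deflection from baseline inside the
#' response window, reported as a magnitude with the deflection sign recorded
#' separately (inward currents are negative in pA traces, open-state
#' occupancy is positive).
#'
#' @param trace A `current_trace` (or any list with `time` and `value`).
#' @param response_window Length-2 numeric, start/end time (s) of the window
#'   searched for the peak.
#' @param baseline_window Length-2 numeric, start/end time of the baseline
#'   window; defaults to the 100 ms preceding the response window (clipped to
#'   the trace start). If no samples fall in it, baseline 0 is used.
#' @return List with `baseline`, `peak_amplitude` (magnitude), `peak_time`,
#'   `peak_sign` (+1/-1), and `no_response` flag (`TRUE` when the deflection
#'   is indistinguishable from zero).
#' @export
peak_and_baseline <- function(trace, response_window,
                              baseline_window = NULL) {
  t <- trace$time; v <- trace$value
  if (is.null(baseline_window)) {
    baseline_window <- c(max(min(t), response_window[1] - 0.1),
                         response_window[1])
  }
  bl_idx <- which(t >= baseline_window[1] & t < baseline_window[2])
  baseline <- if (length(bl_idx)) mean(v[bl_idx]) else 0
  win <- which(t >= response_window[1] & t <= response_window[2])
  if (!length(win)) stop("response window contains no samples")
  dev <- v[win] - baseline
  i <- which.max(abs(dev))
  peak_amplitude <- abs(dev[i])
  list(baseline = baseline,
       peak_amplitude = peak_amplitude,
       peak_time = t[win[i]],
       peak_sign = if (dev[i] >= 0) 1 else -1,
       no_response = peak_amplitude < .Machine$double.eps^0.5 *
         max(1, abs(baseline)))
}

#' 10-90% rise time of a response onset
#'
#' Time between the first crossings of 10% and 90% of the peak deflection,
#' with linear interpolation between samples. Onsets resolved by a single
#' sample are flagged as resolution-limited.
#'
#' @param trace A `current_trace`.
#' @param baseline Baseline value (same units as the trace).
#' @param peak_amplitude Peak deflection magnitude from baseline.
#' @param peak_sign +1 or -1, direction of the deflection.
#' @param onset_window Length-2 numeric, window (s) containing the onset
#'   (typically pulse start to peak time).
#' @return List with `rise_time` (s) and `resolution_limited` flag.
#' @export
rise_time_10_90 <- function(trace, baseline, peak_amplitude, peak_sign = 1,
                            onset_window = range(trace$time)) {
  idx <- which(trace$time >= onset_window[1] & trace$time <= onset_window[2])
  if (length(idx) < 2) stop("onset window contains fewer than 2 samples")
  t <- trace$time[idx]
  y <- peak_sign * (trace$value[idx] - baseline)  # rising, positive-going
  cross <- function(level) {
    thr <- level * peak_amplitude
    k <- which(y >= thr)[1]
    if (is.na(k)) return(NA_real_)
    if (k == 1) return(t[1])
    # linear interpolation between samples k-1 and k
    t[k - 1] + (thr - y[k - 1]) / (y[k] - y[k - 1]) * (t[k] - t[k - 1])
  }
  t10 <- cross(0.10); t90 <- cross(0.90)
  if (is.na(t10) || is.na(t90)) stop("no onset detected: thresholds not crossed")
  dt <- stats::median(diff(t))
  rise <- t90 - t10
  list(rise_time = rise, resolution_limited = rise <= 2 * dt)
}

#' Biexponential fit of the desensitizing current decay
#'
#' Fits \eqn{A_f e^{-t/\tau_f} + A_s e^{-t/\tau_s} + C} to the decay phase
#' (time measured from the window start), by bounded Levenberg-Marquardt
#' least squares. Components are ordered so `tau_fast < tau_slow` after the
#' fit. A non-negative offset term absorbs any residual steady-state
#' (non-desensitizing) current; leaving the offset unbounded makes it
#' degenerate with a long slow component over a finite window. A small
#' multistart over initial time constants guards against local optima of the
#' separable-exponential loss. Fits where the two time constants agree
#' within 5% or one component amplitude is below 1% of the total decay are
#' flagged as effectively monoexponential.
#'
#' @param trace A `current_trace` whose `value` decays inside the window
#'   (occupancy traces decay downward from the peak; pA traces are rectified
#'   by the caller via `peak_sign`).
#' @param fit_window Length-2 numeric, start (peak time) and end (agonist
#'   washout) of the decay window, s.
#' @param baseline Baseline to subtract before fitting.
#' @param peak_sign +1/-1 so that `peak_sign * (value - baseline)` is a
#'   positive decaying signal.
#' @return List with `amp_fast`, `tau_fast`, `amp_slow`, `tau_slow`,
#'   `offset`, `fit_r2`, and `monoexponential` flag.
#' @export
fit_biexponential <- function(trace, fit_window, baseline = 0,
                              peak_sign = 1) {
  idx <- which(trace$time >= fit_window[1] & trace$time <= fit_window[2])
  if (length(idx) < 20) stop("fit window must contain at least 20 samples")
  t <- trace$time[idx] - trace$time[idx[1]]
  y <- peak_sign * (trace$value[idx] - baseline)
  span <- max(t)
  y0 <- y[1]; yend <- y[length(y)]
  amp <- y0 - yend
  model <- function(p) p[["Af"]] * exp(-t / p[["tf"]]) +
    p[["As"]] * exp(-t / p[["ts"]]) + p[["C"]]
  lower <- c(Af = 0, tf = 1e-3 * span, As = 0, ts = 0.02 * span, C = 0)
  upper <- c(Af = Inf, tf = span, As = Inf, ts = 10 * span, C = Inf)
  fit <- NULL
  for (tf0 in span * c(0.02, 0.10)) {
    for (ts0 in span * c(0.60, 3)) {
      for (C0 in unique(c(0, max(yend, 0)))) {
        start <- c(Af = 0.5 * amp, tf = tf0, As = 0.5 * amp,
                   ts = ts0, C = C0)
        f <- try(minpack.lm::nls.lm(
          par = start, fn = function(p) y - model(p),
          lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 500)),
          silent = TRUE)
        if (inherits(f, "try-error") || f$info < 1 || f$info > 4 ||
            anyNA(f$par)) next
        if (is.null(fit) || sum(f$fvec^2) < sum(fit$fvec^2)) fit <- f
      }
    }
  }
  if (is.null(fit)) {
    stop("biexponential fit did not converge (initial guesses: tau_f = ",
         signif(0.1 * span, 3), ", tau_s = ", signif(0.6 * span, 3),
         " s, amplitude split equally)")
  }
  p <- fit$par
  comps <- data.frame(A = c(p[["Af"]], p[["As"]]),
                      tau = c(p[["tf"]], p[["ts"]]))
  comps <- comps[order(comps$tau), ]
  r2 <- 1 - sum(fit$fvec^2) / sum((y - mean(y))^2)
  tau_close <- abs(comps$tau[2] - comps$tau[1]) / comps$tau[2] < 0.05
  amp_small <- any(abs(comps$A) < 0.01 * max(abs(amp), .Machine$double.eps))
  list(amp_fast = comps$A[1], tau_fast = comps$tau[1],
       amp_slow = comps$A[2], tau_slow = comps$tau[2],
       offset = p[["C"]], fit_r2 = r2,
       monoexponential = tau_close || amp_small)
}

#' Paired-pulse recovery ratio
#'
#' @param first_peak Peak amplitude of the conditioning response (> 0).
#' @param second_peak Peak amplitude of the test response.
#' @return Recovery in percent, `100 * second_peak / first_peak`. Values
#'   above 100 are allowed (and flagged via attribute `over_100`).
#' @export
recovery_ratio <- function(first_peak, second_peak) {
  if (!is.finite(first_peak) || first_peak <= 0) {
    stop("first peak must be positive")
  }
  r <- 100 * second_peak / first_peak
  if (r > 100) attr(r, "over_100") <- TRUE
  r
}

#' Current density
#'
#' Peak current normalized by cell membrane capacitance, pA/pF.
#'
#' @param peak_pA Peak amplitude, pA (magnitude).
#' @param capacitance_pF Cell capacitance, pF (> 0).
#' @return Current density in pA/pF.
#' @export
current_density <- function(peak_pA, capacitance_pF) {
  if (!is.finite(capacitance_pF) || capacitance_pF <= 0) {
    stop("capacitance must be positive")
  }
  peak_pA / capacitance_pF
}

#' Extract all reported features from a simulated or recorded trace
#'
#' Runs the full per-trace analysis: baseline and peak over the agonist
#' pulse, 10-90% rise time over the onset, biexponential fit of the decay
#' from the peak to the end of agonist application, and current density when
#' capacitance is available. Pulse timing is taken from the protocol stored
#' in the trace metadata unless given explicitly.
#'
#' @param trace A `current_trace`.
#' @param pulse_onset,pulse_duration Optional explicit pulse timing, s.
#' @param capacitance_pF Optional cell capacitance for current density.
#' @param baseline_duration Baseline window length before the pulse, s.
#' @return A `trace_features` list: `peak_amplitude`, `peak_time`,
#'   `baseline`, `rise_time_10_90`, `amp_fast`, `tau_fast`, `amp_slow`,
#'   `tau_slow`, `fit_r2`, `monoexponential`, `current_density` (or NA),
#'   `resolution_limited`, `no_response`.
#' @export
analyze_trace <- function(trace, pulse_onset = NULL, pulse_duration = NULL,
                          capacitance_pF = NULL, baseline_duration = 0.1) {
  prot <- trace$metadata$protocol
  if (is.null(pulse_onset)) {
    onsets <- attr(prot, "pulse_onsets")
    if (is.null(onsets)) stop("pulse_onset not given and not in metadata")
    pulse_onset <- onsets[1]
  }
  if (is.null(pulse_duration)) {
    pulse_duration <- attr(prot, "pulse_duration")
    if (is.null(pulse_duration)) stop("pulse_duration not given and not in metadata")
  }
  if (is.null(capacitance_pF)) {
    capacitance_pF <- trace$metadata$capacitance_pF
  }
  pulse_end <- pulse_onset + pulse_duration
  pk <- peak_and_baseline(trace, c(pulse_onset, pulse_end),
                          baseline_window = c(pulse_onset - baseline_duration,
                                              pulse_onset))
  if (pk$no_response) {
    return(structure(list(peak_amplitude = 0, peak_time = NA_real_,
                          baseline = pk$baseline,
                          rise_time_10_90 = NA_real_,
                          amp_fast = NA_real_, tau_fast = NA_real_,
                          amp_slow = NA_real_, tau_slow = NA_real_,
                          fit_r2 = NA_real_, monoexponential = NA,
                          current_density = NA_real_,
                          resolution_limited = NA, no_response = TRUE),
                     class = "trace_features"))
  }
  rt <- rise_time_10_90(trace, pk$baseline, pk$peak_amplitude, pk$peak_sign,
                        onset_window = c(pulse_onset, pk$peak_time))
  fit <- fit_biexponential(trace, c(pk$peak_time, pulse_end),
                           baseline = pk$baseline, peak_sign = pk$peak_sign)
  dens <- if (!is.null(capacitance_pF)) {
    current_density(pk$peak_amplitude, capacitance_pF)
  } else NA_real_
  structure(list(peak_amplitude = pk$peak_amplitude,
                 peak_time = pk$peak_time,
                 baseline = pk$baseline,
                 rise_time_10_90 = rt$rise_time,
                 amp_fast = fit$amp_fast, tau_fast = fit$tau_fast,
                 amp_slow = fit$amp_slow, tau_slow = fit$tau_slow,
                 fit_r2 = fit$fit_r2, monoexponential = fit$monoexponential,
                 current_density = dens,
                 resolution_limited = rt$resolution_limited,
                 no_response = FALSE),
            class = "trace_features")
}

#' @export
print.trace_features <- function(x, ...) {
  cat(sprintf(
    "Trace features: peak %.4g, rise(10-90%%) %.4g ms, tau_fast %.4g ms, tau_slow %.4g ms\n",
    x$peak_amplitude, 1000 * x$rise_time_10_90,
    1000 * x$tau_fast, 1000 * x$tau_slow))
  invisible(x)
}

#' Compare a feature between two groups of cells
#'
#' Two-sided unpaired comparison, reported the way electrophysiology papers
#' do: group means +/- SEM with n, plus the test statistic and p-value.
#' `method = "ttest"` uses Welch's t-test; `method = "ranksum"` uses the
#' Mann-Whitney-Wilcoxon rank-sum test (exact when both groups have <= 20
#' observations and no ties; mid-rank normal approximation with continuity
#' correction otherwise).
#'
#' @param group_a,group_b Numeric vectors of per-cell feature values
#'   (each n >= 2).
#' @param method `"ttest"` or `"ranksum"`.
#' @return List with `statistic`, `p_value`, `mean_a`, `sem_a`, `n_a`,
#'   `mean_b`, `sem_b`, `n_b`, `method`.
#' @export
compare_groups <- function(group_a, group_b,
                           method = c("ttest", "ranksum")) {
  method <- match.arg(method)
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 finite observations")
  }
  if (method == "ttest") {
    ht <- stats::t.test(group_a, group_b)
  } else {
    exact <- length(group_a) <= 20 && length(group_b) <= 20 &&
      !anyDuplicated(c(group_a, group_b))
    ht <- suppressWarnings(
      stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  list(statistic = unname(ht$statistic),
       p_value = ht$p.value,
       mean_a = mean(group_a), sem_a = sem(group_a), n_a = length(group_a),
       mean_b = mean(group_b), sem_b = sem(group_b), n_b = length(group_b),
       method = method)
}
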