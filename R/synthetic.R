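#' Specification of a synthetic whole-cell recording population
#'
#' Describes a population of simulated cells whose alpha,beta-meATP-evoked
#' P2X3 currents are generated from the kinetic model: each cell gets a
#' latent peak amplitude drawn from a lognormal distribution (positivity;
#' parameterized so the sample mean and SEM match the requested targets in
#' expectation), a capacitance from a normal distribution truncated at 5 pF,
#' a holding-current offset, and additive white Gaussian recording noise on
#' top of the deterministic kinetic trace, scaled inward-negative.
#'
#' The between-cell amplitude SD is `peak_sem * sqrt(n_cells)`: group
#' statistics are usually printed as mean +/- SEM, and this is the
#' population dispersion consistent with them.
#'
#' @param condition Condition label (e.g. `"WT_control"`).
#' @param n_cells Number of cells (>= 1).
#' @param peak_mean,peak_sem Target sample mean and SEM of peak amplitude,
#'   pA.
#' @param cap_mean,cap_sem Target mean and SEM of cell capacitance, pF.
#' @param rates A `rate_set` (or packaged name) driving the trace shape.
#' @param noise_sd Recording-noise SD, pA.
#' @param sampling_rate Sampling rate, Hz.
#' @param holding_mean,holding_sd Holding-current offset distribution, pA
#'   (negative = inward).
#' @param concentration Agonist concentration, mM.
#' @param pulse_duration Pulse length, s.
#' @param baseline,tail Pre- and post-pulse agonist-free segments, s.
#' @param seed Integer seed; recorded in every trace's metadata.
#' @return A `population_spec` object.
#' @export
population_spec <- function(condition, n_cells = 33,
                            peak_mean = 338, peak_sem = 26,
                            cap_mean = 32, cap_sem = 2,
                            rates = "control",
                            noise_sd = 5, sampling_rate = 10000,
                            holding_mean = -50, holding_sd = 20,
                            concentration = 0.01, pulse_duration = 2,
                            baseline = 0.5, tail = 0.5, seed = 1L) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (peak_sem < 0 || cap_sem < 0 || noise_sd < 0 || holding_sd < 0) {
    stop("dispersions must be non-negative")
  }
  if (is.character(rates)) rates <- load_rate_set(rates)
  structure(list(condition = condition, n_cells = as.integer(n_cells),
                 peak_mean = peak_mean, peak_sem = peak_sem,
                 cap_mean = cap_mean, cap_sem = cap_sem,
                 rates = rates, noise_sd = noise_sd,
                 sampling_rate = sampling_rate,
                 holding_mean = holding_mean, holding_sd = holding_sd,
                 concentration = concentration,
                 pulse_duration = pulse_duration,
                 baseline = baseline, tail = tail,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# deterministic per-cell seed derivation (kept below 2^31)
.cell_seed <- function(seed, cell_index) {
  as.integer((as.numeric(seed) * 10007 + cell_index * 97) %% 2147483647)
}

# noiseless kinetic template shared by all cells of a spec
.base_trace <- function(spec, scheme) {
  prot <- single_pulse_protocol(spec$concentration, spec$pulse_duration,
                                baseline = spec$baseline, tail = spec$tail,
                                sampling_interval = 1 / spec$sampling_rate)
  simulate_trace(spec$rates, prot, scheme = scheme)
}

#' Generate one synthetic cell recording
#'
#' @param spec A `population_spec`.
#' @param cell_index Cell number within the population (1-based); fixes the
#'   per-cell random substream, so a cell is reproducible on its own or as
#'   part of [generate_population()].
#' @param base_trace Optional precomputed noiseless kinetic template (from
#'   the same spec); computed on the fly when omitted.
#' @param scheme A `kinetic_scheme`.
#' @return A `current_trace` in pA (inward-negative) whose metadata records
#'   the latent peak amplitude, capacitance, holding offset, condition,
#'   cell id and seed.
#' @export
generate_cell <- function(spec, cell_index, base_trace = NULL,
                          scheme = p2x3_scheme()) {
  stopifnot(inherits(spec, "population_spec"))
  if (is.null(base_trace)) base_trace <- .base_trace(spec, scheme)
  occ <- base_trace$states[, "A3Ro"]
  peak_occ <- max(occ)
  set.seed(.cell_seed(spec$seed, cell_index))
  cell_sd <- spec$peak_sem * sqrt(spec$n_cells)
  if (cell_sd > 0) {
    s2 <- log(1 + (cell_sd / spec$peak_mean)^2)
    amp <- stats::rlnorm(1, meanlog = log(spec$peak_mean) - s2 / 2,
                         sdlog = sqrt(s2))
  } else {
    amp <- spec$peak_mean
  }
  cap_sd <- spec$cap_sem * sqrt(spec$n_cells)
  cap <- stats::rnorm(1, spec$cap_mean, cap_sd)
  while (cap <= 5) cap <- stats::rnorm(1, spec$cap_mean, cap_sd)
  offset <- stats::rnorm(1, spec$holding_mean, spec$holding_sd)
  value <- offset - (amp / peak_occ) * occ
  if (spec$noise_sd > 0) {
    value <- value + stats::rnorm(length(value), 0, spec$noise_sd)
  }
  structure(list(
    time = base_trace$time,
    value = value,
    states = NULL,
    metadata = list(rate_label = attr(spec$rates, "label"),
                    protocol = base_trace$metadata$protocol,
                    units = "pA",
                    scale_pA_per_unit = amp / peak_occ,
                    capacitance_pF = cap,
                    condition = spec$condition,
                    cell_id = cell_index,
                    latent_peak_pA = amp,
                    holding_pA = offset,
                    seed = spec$seed)),
    class = "current_trace")
}

#' Generate a synthetic cell population
#'
#' @inheritParams generate_cell
#' @return List with `traces` (list of `current_trace`) and `manifest`
#'   (data frame of latent per-cell values: `cell_id`, `condition`,
#'   `latent_peak_pA`, `capacitance_pF`, `holding_pA`, `seed`). With a
#'   single cell the manifest carries attribute `sem_undefined = TRUE`.
#' @export
generate_population <- function(spec, scheme = p2x3_scheme()) {
  stopifnot(inherits(spec, "population_spec"))
  base <- .base_trace(spec, scheme)
  traces <- lapply(seq_len(spec$n_cells), function(i) {
    generate_cell(spec, i, base_trace = base, scheme = scheme)
  })
  manifest <- data.frame(
    cell_id = seq_len(spec$n_cells),
    condition = spec$condition,
    latent_peak_pA = vapply(traces, function(tr)
      tr$metadata$latent_peak_pA, numeric(1)),
    capacitance_pF = vapply(traces, function(tr)
      tr$metadata$capacitance_pF, numeric(1)),
    holding_pA = vapply(traces, function(tr)
      tr$metadata$holding_pA, numeric(1)),
    seed = spec$seed,
    stringsAsFactors = FALSE)
  if (spec$n_cells == 1) attr(manifest, "sem_undefined") <- TRUE
  list(traces = traces, manifest = manifest)
}

#' Analyse every trace of a population
#'
#' Maps [analyze_trace()] over a population and binds per-cell features into
#' a table, using each cell's recorded capacitance for current density.
#'
#' @param population Result of [generate_population()] (or a list of
#'   `current_trace` objects).
#' @return Data frame, one row per cell, with the `trace_features` fields
#'   plus `cell_id` and `condition`.
#' @export
analyze_population <- function(population) {
  traces <- if (!is.null(population$traces)) population$traces else population
  rows <- lapply(traces, function(tr) {
    ft <- analyze_trace(tr)
    data.frame(cell_id = tr$metadata$cell_id %||% NA_integer_,
               condition = tr$metadata$condition %||% NA_character_,
               peak_amplitude = ft$peak_amplitude,
               rise_time_10_90 = ft$rise_time_10_90,
               tau_fast = ft$tau_fast, tau_slow = ft$tau_slow,
               fit_r2 = ft$fit_r2,
               current_density = ft$current_density,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
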