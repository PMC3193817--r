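#' Write a current trace to CSV (+ JSON metadata sidecar)
#'
#' CSV schema: header `time_s,value`, LF line endings, `.` decimal
#' separator. Metadata (units, condition, capacitance, latent values, seed)
#' goes to `<path>.meta.json` when `sidecar = TRUE`.
#'
#' @param trace A `current_trace`.
#' @param path Output CSV path.
#' @param sidecar Write the metadata sidecar as well?
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, sidecar = TRUE) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE,
                   quote = FALSE, eol = "\n")
  if (sidecar) {
    meta <- trace$metadata
    meta$protocol <- if (!is.null(meta$protocol)) {
      list(durations = meta$protocol$durations,
           concentrations = meta$protocol$concentrations,
           sampling_interval = meta$protocol$sampling_interval,
           pulse_onsets = attr(meta$protocol, "pulse_onsets"),
           pulse_duration = attr(meta$protocol, "pulse_duration"))
    }
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a current trace from CSV (+ optional metadata sidecar)
#'
#' @param path CSV path written by [write_trace_csv()] (or any CSV with
#'   columns `time_s,value`).
#' @return A `current_trace`.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- list(units = "unknown")
  side <- paste0(path, ".meta.json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$protocol)) {
      p <- pulse_protocol(meta$protocol$durations,
                          meta$protocol$concentrations,
                          meta$protocol$sampling_interval)
      attr(p, "pulse_onsets") <- meta$protocol$pulse_onsets
      attr(p, "pulse_duration") <- meta$protocol$pulse_duration
      meta$protocol <- p
    }
  }
  structure(list(time = df$time_s, value = df$value, states = NULL,
                 metadata = meta),
            class = "current_trace")
}

#' Reproduce the paired-pulse simulation comparison
#'
#' Runs the 10 uM (0.01 mM), 2-s paired-pulse protocol with a 30-s interval
#' under both packaged rate sets, writes per-condition trace CSVs, an
#' optional two-panel figure, and a JSON summary holding both recovery
#' percentages, the per-condition trace features, and the condition deltas.
#' The control recovery is checked against the 24% reference value and
#' flagged in the summary if it falls outside `recovery_tolerance`
#' percentage points. Fully deterministic: two runs with the same arguments
#' produce byte-identical summaries.
#'
#' @param output_dir Directory for artifacts (created if needed).
#' @param sampling_interval Simulation sampling interval, s.
#' @param recovery_tolerance Allowed deviation of the control recovery from
#'   24 percentage points before flagging.
#' @param plot Write a PNG figure of both traces?
#' @param scheme A `kinetic_scheme`.
#' @return The summary list, invisibly; artifacts in `output_dir`
#'   (`trace_control.csv`, `trace_mbcd.csv`, `summary.json`, optionally
#'   `paired_pulse.png`).
#' @export
reproduce_figure5 <- function(output_dir, sampling_interval = 0.001,
                              recovery_tolerance = 5, plot = TRUE,
                              scheme = p2x3_scheme()) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  conds <- list(control = load_rate_set("control"),
                MbCD = load_rate_set("MbCD"))
  res <- lapply(conds, function(rs) {
    pp <- simulate_paired_pulse(rs, 0.01, 2, 30,
                                sampling_interval = sampling_interval,
                                scheme = scheme)
    ft <- analyze_trace(pp$trace)
    list(pp = pp, features = ft)
  })
  write_trace_csv(res$control$pp$trace,
                  file.path(output_dir, "trace_control.csv"))
  write_trace_csv(res$MbCD$pp$trace,
                  file.path(output_dir, "trace_mbcd.csv"))
  feat <- function(r) list(
    first_peak = r$pp$first_peak,
    second_peak = r$pp$second_peak,
    recovery_percent = as.numeric(r$pp$recovery_percent),
    rise_time_10_90_s = r$features$rise_time_10_90,
    tau_fast_s = r$features$tau_fast,
    tau_slow_s = r$features$tau_slow)
  ctl <- feat(res$control); mb <- feat(res$MbCD)
  summary <- list(
    protocol = list(concentration_mM = 0.01, pulse_s = 2, interval_s = 30),
    control = ctl,
    MbCD = mb,
    deltas = list(
      peak_ratio = mb$first_peak / ctl$first_peak,
      tau_slow_ratio = mb$tau_slow_s / ctl$tau_slow_s,
      tau_fast_ratio = mb$tau_fast_s / ctl$tau_fast_s,
      rise_time_ratio = mb$rise_time_10_90_s / ctl$rise_time_10_90_s,
      recovery_difference = mb$recovery_percent - ctl$recovery_percent),
    control_recovery_reference = 24,
    control_recovery_within_tolerance =
      abs(ctl$recovery_percent - 24) <= recovery_tolerance)
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (plot) {
    grDevices::png(file.path(output_dir, "paired_pulse.png"),
                   width = 900, height = 600)
    graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    for (nm in names(res)) {
      tr <- res[[nm]]$pp$trace
      graphics::plot(tr$time, tr$value, type = "l",
                     xlab = "time (s)", ylab = "fraction open",
                     main = nm, ylim = c(0, 0.6))
    }
    grDevices::dev.off()
  }
  invisible(summary)
}

# tiny polynomial rolling hash of a deparsed object, for provenance records
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' Run the synthetic-data / analysis / comparison / fitting pipeline
#'
#' Executes the requested stages in order on two synthetic populations
#' (e.g. WT vs KI): `synth` generates the populations, `analyze` extracts
#' per-cell features, `compare` tests the peak-amplitude difference between
#' groups, `fit` runs a rate-constant fit against the first population's
#' mean features. Artifacts (manifests, feature tables, comparison JSON,
#' fitted rates) and a provenance record (config hash, package version,
#' seed) are written to the output directory. A single global seed fans out
#' to per-stage seeds deterministically.
#'
#' @param config A list (or path to a JSON file) with fields:
#'   `output_dir`; `seed`; `stages` (subset of
#'   `c("synth","analyze","compare","fit")`); `population_a` and
#'   `population_b` (argument lists for [population_spec()], seeds filled
#'   from the global seed); optional `rate_files` (paths to rate-set JSONs
#'   used instead of packaged names); optional `fit` (list with `free`,
#'   `lower`, `upper`, `max_eval`).
#' @return List of stage results, invisibly; errors name the failing stage.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$output_dir)) stop("config must set output_dir")
  stages <- config$stages %||% c("synth", "analyze", "compare")
  seed <- as.integer(config$seed %||% 1L)
  if (!is.null(config$rate_files)) {
    missing <- config$rate_files[!file.exists(unlist(config$rate_files))]
    if (length(missing)) {
      stop("rate-set file(s) not found: ", paste(missing, collapse = ", "))
    }
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage_seed <- function(k) as.integer((seed * 1009 + k * 9973) %% 2147483647)
  out <- list()
  run_stage <- function(name, fun) {
    r <- try(fun(), silent = TRUE)
    if (inherits(r, "try-error")) {
      stop("pipeline stage '", name, "' failed: ",
           attr(r, "condition")$message)
    }
    r
  }
  if ("synth" %in% stages) {
    out$synth <- run_stage("synth", function() {
      mk <- function(args, k) {
        args$seed <- stage_seed(k)
        do.call(population_spec, args)
      }
      pa <- generate_population(mk(config$population_a, 1))
      pb <- generate_population(mk(config$population_b, 2))
      utils::write.csv(pa$manifest,
                       file.path(config$output_dir, "manifest_a.csv"),
                       row.names = FALSE)
      utils::write.csv(pb$manifest,
                       file.path(config$output_dir, "manifest_b.csv"),
                       row.names = FALSE)
      list(a = pa, b = pb)
    })
  }
  if ("analyze" %in% stages) {
    if (is.null(out$synth)) stop("pipeline stage 'analyze' needs 'synth'")
    out$analyze <- run_stage("analyze", function() {
      fa <- analyze_population(out$synth$a)
      fb <- analyze_population(out$synth$b)
      utils::write.csv(fa, file.path(config$output_dir, "features_a.csv"),
                       row.names = FALSE)
      utils::write.csv(fb, file.path(config$output_dir, "features_b.csv"),
                       row.names = FALSE)
      list(a = fa, b = fb)
    })
  }
  if ("compare" %in% stages) {
    if (is.null(out$analyze)) stop("pipeline stage 'compare' needs 'analyze'")
    out$compare <- run_stage("compare", function() {
      cmp <- compare_groups(out$analyze$a$peak_amplitude,
                            out$analyze$b$peak_amplitude,
                            method = "ranksum")
      jsonlite::write_json(cmp, file.path(config$output_dir, "compare.json"),
                           auto_unbox = TRUE, digits = NA)
      cmp
    })
  }
  if ("fit" %in% stages) {
    if (is.null(out$analyze)) stop("pipeline stage 'fit' needs 'analyze'")
    out$fit <- run_stage("fit", function() {
      fcfg <- config$fit %||% list()
      base <- load_rate_set("control")
      free <- fcfg$free %||% c("k4", "d5", "n4")
      targets <- simulated_features(base,
                                    sampling_interval = 0.002)
      spec <- fit_spec(free, base, targets,
                       lower = setNames(as.numeric(base[free]) / 2, free),
                       upper = setNames(as.numeric(base[free]) * 2, free),
                       seed = stage_seed(3),
                       max_eval = fcfg$max_eval %||% 200L)
      res <- fit_rates(spec)
      write_rate_set(res$rates,
                     file.path(config$output_dir, "fitted_rates.json"))
      res
    })
  }
  prov <- list(config_hash = .config_hash(config),
               package_version =
                 as.character(utils::packageVersion("p2x3kinetics")),
               seed = seed, stages = stages)
  jsonlite::write_json(prov, file.path(config$output_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
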