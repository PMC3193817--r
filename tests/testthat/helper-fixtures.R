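# shared fixtures: scheme and packaged rate sets are read once per run
fx_scheme <- p2x3_scheme()
fx_control <- load_rate_set("control")
fx_mbcd <- load_rate_set("MbCD")

# coarse-grid single pulse used where sub-ms resolution is not the point
fx_quick_pulse <- function(dt = 0.002, tail = 0.5) {
  single_pulse_protocol(0.01, 2, baseline = 0.5, tail = tail,
                        sampling_interval = dt)
}

# write a modified copy of a packaged rate-set document, return its path
fx_rate_file <- function(drop = NULL, set = NULL, dir = tempdir()) {
  doc <- jsonlite::read_json(system.file("extdata", "rates_control.json",
                                         package = "p2x3kinetics"))
  if (!is.null(drop)) doc$rates[drop] <- NULL
  for (nm in names(set)) doc$rates[[nm]]$value <- set[[nm]]
  path <- tempfile("rates", tmpdir = dir, fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  path
}
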