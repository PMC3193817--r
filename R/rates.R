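#' Load a rate-constant set
#'
#' Loads one of the two packaged rate-constant sets (`"control"` for
#' untreated neurons, `"MbCD"` for cholesterol-depleted neurons), or a
#' user-supplied JSON document with the same layout: a `label` field and a
#' `rates` mapping from each of the 26 canonical rate-constant names to
#' `{value, units}`. Binding constants (`k1`-`k3`, `m1`-`m3`) must carry
#' units `"mM^-1 s^-1"`; all others `"s^-1"`.
#'
#' @param source `"control"`, `"MbCD"`, or a path to a rate-set JSON file.
#' @return A `rate_set` object: named numeric vector of the 26 rate-constant
#'   values with attributes `label` and `units` (named character vector).
#' @export
#' @examples
#' ctrl <- load_rate_set("control")
#' ctrl[["k4"]]   # 75 s^-1
load_rate_set <- function(source) {
  packaged <- c(control = "rates_control.json", MbCD = "rates_mbcd.json")
  if (length(source) == 1 && source %in% names(packaged)) {
    source <- system.file("extdata", packaged[[source]],
                          package = "p2x3kinetics", mustWork = TRUE)
  }
  if (!file.exists(source)) {
    stop("rate-set source not found: ", source)
  }
  doc <- jsonlite::read_json(source, simplifyVector = FALSE)
  if (is.null(doc$rates)) stop("rate-set document lacks a 'rates' field")
  vals <- vapply(doc$rates, function(r) as.numeric(r$value), numeric(1))
  units <- vapply(doc$rates, function(r) as.character(r$units), character(1))
  rate_set(vals, label = doc$label %||% "unnamed", units = units)
}

#' Construct and validate a rate set
#'
#' @param values Named numeric vector covering all 26 canonical rate-constant
#'   names; all values must be non-negative.
#' @param label Condition label (e.g. `"control"`).
#' @param units Optional named character vector of units; when omitted, the
#'   canonical units implied by each constant's ligand order are assumed.
#' @return A validated `rate_set`.
#' @export
rate_set <- function(values, label = "unnamed", units = NULL) {
  expected_units <- ifelse(.canonical_rate_names %in% .ligand_dependent_rates,
                           "mM^-1 s^-1", "s^-1")
  names(expected_units) <- .canonical_rate_names
  missing <- setdiff(.canonical_rate_names, names(values))
  if (length(missing)) {
    stop("missing rate constants: ", paste(missing, collapse = ", "))
  }
  unknown <- setdiff(names(values), .canonical_rate_names)
  if (length(unknown)) {
    stop("unknown rate constants: ", paste(unknown, collapse = ", "))
  }
  values <- values[.canonical_rate_names]
  if (anyNA(values)) stop("non-numeric rate-constant value")
  if (any(values < 0)) {
    stop("negative rate constants: ",
         paste(names(values)[values < 0], collapse = ", "))
  }
  if (!is.null(units)) {
    units <- units[.canonical_rate_names]
    bad <- names(units)[!is.na(units) & units != expected_units]
    if (length(bad)) {
      stop("unit mismatch for ", paste(bad, collapse = ", "),
           ": binding constants k1-k3/m1-m3 take mM^-1 s^-1, all others s^-1")
    }
  }
  structure(values, label = label, units = expected_units,
            class = c("rate_set", "numeric"))
}

#' Write a rate set to a JSON document
#'
#' @param rates A `rate_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rate_set <- function(rates, path) {
  stopifnot(inherits(rates, "rate_set"))
  units <- attr(rates, "units")
  doc <- list(
    label = attr(rates, "label"),
    rates = setNames(lapply(names(rates), function(nm) {
      list(value = unname(rates[[nm]]), units = unname(units[[nm]]))
    }), names(rates)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Modify selected constants of a rate set
#'
#' @param rates A `rate_set`.
#' @param ... Named replacements, e.g. `k4 = 40`.
#' @param label Label for the modified set; defaults to the original label
#'   with a `"*"` suffix.
#' @return A new validated `rate_set`.
#' @export
update_rates <- function(rates, ..., label = NULL) {
  repl <- c(...)
  vals <- as.numeric(rates)
  names(vals) <- names(rates)
  vals[names(repl)] <- repl
  rate_set(vals, label = label %||% paste0(attr(rates, "label"), "*"))
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Rate set '", attr(x, "label"), "' (26 constants)\n", sep = "")
  df <- data.frame(value = as.numeric(x), units = attr(x, "units"),
                   row.names = names(x))
  print(df)
  invisible(x)
}
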