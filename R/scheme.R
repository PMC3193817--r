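#' Cyclic 10-state P2X3 receptor kinetic scheme
#'
#' Constructs the cyclic Markov scheme of P2X3 receptor operation: an upper
#' (non-desensitized) branch `R -> AR -> A2R -> A3R` of three sequential
#' agonist-binding steps (`k1`-`k3` forward, `l1`-`l3` unbinding), gating of
#' the fully occupied receptor `A3R <-> A3Ro` (`k4`/`l4`), a lower
#' desensitized branch `D -> AD -> A2D -> A3D` (`m1`-`m3`/`n1`-`n3`) ending in
#' the rapidly desensitizing state `A3Df` (`m4`/`n4`), and five vertical
#' desensitization/resensitization pairs connecting the branches
#' (`d1`-`d5` downward, `r1`-`r5` upward; in particular `d5` takes the open
#' state `A3Ro` into `A3Df` and `r5` reopens it).
#'
#' Agonist-binding transitions (`k1`, `k2`, `k3`, `m1`, `m2`, `m3`) carry
#' `ligand_order = 1`: their propensity is the rate constant times the agonist
#' concentration in mM. All other transitions are concentration-independent.
#'
#' @param path Optional path to a scheme document (JSON); defaults to the
#'   packaged canonical scheme.
#' @return A `kinetic_scheme` object: list with `name`, `states` (character),
#'   and `transitions` (data.frame with columns `from`, `to`, `rate`,
#'   `ligand_order`).
#' @export
#' @examples
#' sch <- p2x3_scheme()
#' length(sch$states)      # 10
#' nrow(sch$transitions)   # 26
p2x3_scheme <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scheme_p2x3.json",
                        package = "p2x3kinetics", mustWork = TRUE)
  }
  read_scheme(path, strict = TRUE)
}

#' Read a kinetic scheme from a JSON document
#'
#' @param path Path to a JSON document with fields `states` (array of state
#'   names) and `transitions` (array of objects with `from`, `to`, `rate`,
#'   `ligand_order`).
#' @param strict If `TRUE`, additionally require the canonical P2X3 layout
#'   (10 states, 26 transitions in 13 reversible pairs, the canonical rate
#'   names, ligand order 1 exactly on the six binding steps).
#' @return A `kinetic_scheme` object.
#' @export
read_scheme <- function(path, strict = FALSE) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  tx <- as.data.frame(doc$transitions, stringsAsFactors = FALSE)
  names(tx)[names(tx) == "from"] <- "from"
  scheme <- structure(
    list(name = doc$name %||% "kinetic_scheme",
         states = as.character(doc$states),
         transitions = data.frame(from = as.character(tx$from),
                                  to = as.character(tx$to),
                                  rate = as.character(tx$rate),
                                  ligand_order = as.integer(tx$ligand_order),
                                  stringsAsFactors = FALSE)),
    class = "kinetic_scheme")
  validate_scheme(scheme, strict = strict)
  scheme
}

#' Write a kinetic scheme to a JSON document
#'
#' Serialization is lossless: `read_scheme(write_scheme(s, f))` returns a
#' scheme with identical states and transitions.
#'
#' @param scheme A `kinetic_scheme`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  doc <- list(name = scheme$name,
              states = scheme$states,
              transitions = scheme$transitions)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# canonical rate-name sets
.canonical_rate_names <- c(paste0("k", 1:4), paste0("l", 1:4),
                           paste0("m", 1:4), paste0("n", 1:4),
                           paste0("d", 1:5), paste0("r", 1:5))
.ligand_dependent_rates <- c("k1", "k2", "k3", "m1", "m2", "m3")
.canonical_states <- c("R", "AR", "A2R", "A3R", "A3Ro",
                       "D", "AD", "A2D", "A3D", "A3Df")

#' Validate a kinetic scheme
#'
#' Structural checks: unique states, transitions referencing known states,
#' unique rate names, ligand orders in {0, 1}, every state with at least one
#' incoming and one outgoing edge, and a connected transition graph. With
#' `strict = TRUE` the canonical P2X3 constraints are enforced as well.
#'
#' @inheritParams read_scheme
#' @param scheme A `kinetic_scheme`.
#' @return `scheme`, invisibly; errors describe the first violation found.
#' @export
validate_scheme <- function(scheme, strict = FALSE) {
  st <- scheme$states
  tx <- scheme$transitions
  if (anyDuplicated(st)) stop("duplicate state names in scheme")
  if (!all(tx$from %in% st) || !all(tx$to %in% st)) {
    stop("scheme transition references unknown state")
  }
  if (anyDuplicated(tx$rate)) stop("duplicate rate-constant names in scheme")
  if (!all(tx$ligand_order %in% c(0L, 1L))) {
    stop("ligand_order must be 0 or 1")
  }
  if (!all(st %in% tx$from) || !all(st %in% tx$to)) {
    stop("every state needs at least one outgoing and one incoming transition")
  }
  # connectivity of the undirected transition graph
  adj <- unique(rbind(tx[, c("from", "to")],
                      setNames(tx[, c("to", "from")], c("from", "to"))))
  reached <- st[1]
  repeat {
    nxt <- unique(adj$to[adj$from %in% reached])
    new <- setdiff(nxt, reached)
    if (!length(new)) break
    reached <- c(reached, new)
  }
  if (!setequal(reached, st)) stop("scheme graph is not connected")
  if (strict) {
    if (length(st) != 10L || nrow(tx) != 26L) {
      stop("canonical scheme must have 10 states and 26 transitions")
    }
    if (!setequal(st, .canonical_states)) {
      stop("canonical scheme states must be ",
           paste(.canonical_states, collapse = ", "))
    }
    if (!setequal(tx$rate, .canonical_rate_names)) {
      stop("canonical scheme rate names must be k1..k4, l1..l4, m1..m4, ",
           "n1..n4, d1..d5, r1..r5")
    }
    lig <- tx$rate[tx$ligand_order == 1L]
    if (!setequal(lig, .ligand_dependent_rates)) {
      stop("ligand_order must be 1 exactly for k1-k3 and m1-m3")
    }
    # 13 reversible pairs: each edge's reverse must be present
    key <- paste(tx$from, tx$to)
    rev <- paste(tx$to, tx$from)
    if (!all(rev %in% key)) stop("every transition must have a reverse partner")
  }
  invisible(scheme)
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme '", x$name, "': ", length(x$states), " states, ",
      nrow(x$transitions), " transitions\n", sep = "")
  cat("states:", paste(x$states, collapse = " "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
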