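#' Assemble the concentration-dependent generator (Q) matrix
#'
#' Builds the 10x10 generator of the occupancy ODE system
#' \eqn{dx/dt = Q(c) x} for a given agonist concentration. The convention is
#' column-based: off-diagonal entry `Q[target, source]` is the propensity of
#' the `source -> target` transition (rate constant times `c` for the
#' ligand-dependent binding steps), and each diagonal entry is minus the sum
#' of its column's off-diagonals, so all columns sum to zero and total
#' occupancy is conserved by construction.
#'
#' @param scheme A `kinetic_scheme`.
#' @param rates A `rate_set`.
#' @param concentration Agonist concentration in mM (>= 0).
#' @return A 10x10 numeric matrix with state names on both dimensions.
#' @export
#' @examples
#' Q <- build_generator(p2x3_scheme(), load_rate_set("control"), 0.01)
#' Q["AR", "R"]        # k1 * 0.01 = 240
#' max(abs(colSums(Q)))  # ~ 0
build_generator <- function(scheme, rates, concentration) {
  stopifnot(inherits(scheme, "kinetic_scheme"), inherits(rates, "rate_set"))
  if (!is.numeric(concentration) || length(concentration) != 1 ||
      is.na(concentration) || concentration < 0) {
    stop("concentration must be a single non-negative number (mM)")
  }
  st <- scheme$states
  n <- length(st)
  Q <- matrix(0, n, n, dimnames = list(st, st))
  tx <- scheme$transitions
  prop <- as.numeric(rates[tx$rate]) * concentration^tx$ligand_order
  for (i in seq_len(nrow(tx))) {
    Q[tx$to[i], tx$from[i]] <- Q[tx$to[i], tx$from[i]] + prop[i]
  }
  diag(Q) <- diag(Q) - colSums(Q)
  Q
}

#' Stationary occupancy distribution of the scheme
#'
#' Solves \eqn{Q v = 0}, \eqn{\sum v = 1}, \eqn{v \ge 0} for the generator at
#' the given concentration, via the null space of Q (singular value
#' decomposition). At zero agonist the chain funnels into the agonist-free
#' pair \{R, D\}, where detailed balance `d1 R = r1 D` gives a desensitized
#' fraction `d1/(d1+r1)`; the SVD solution reproduces this limit.
#'
#' @inheritParams build_generator
#' @param tol Residual tolerance on `max|Q v|` before the solve is declared
#'   degenerate.
#' @return A `state_vector`: named numeric occupancies summing to 1, with a
#'   `concentration` attribute.
#' @export
steady_state <- function(scheme, rates, concentration, tol = 1e-8) {
  Q <- build_generator(scheme, rates, concentration)
  sv <- svd(Q)
  v <- sv$v[, ncol(Q)]
  if (sum(v) < 0) v <- -v
  v <- v / sum(v)
  # clamp numerical negatives of null-space extraction
  v[v < 0 & v > -1e-12] <- 0
  if (any(v < 0)) {
    stop("steady-state solve produced negative occupancy (residual ",
         format(max(abs(Q %*% v))), "); generator may be reducible")
  }
  v <- v / sum(v)
  resid <- max(abs(Q %*% v))
  if (!is.finite(resid) || resid > tol) {
    stop("steady-state solve did not converge: residual ", format(resid))
  }
  structure(setNames(as.numeric(v), scheme$states),
            concentration = concentration, class = "state_vector")
}
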