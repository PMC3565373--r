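## Bragg-Williams mean-field equation of state for the lattice binary
## mixture.
##
## Derivation (documented because the analytic backend is built on it).
## The per-site Bragg-Williams free energy of the nearest-neighbor
## interaction energy with z = 4 neighbors is
##   f(X) = kBT [X ln X + (1-X) ln(1-X)]
##          + (z/2) [Uaa X^2 + 2 Uab X (1-X) + Ubb (1-X)^2].
## Differentiating, the relative chemical potential G(X) = df/dX is
##   G(X) = kBT ln(X/(1-X)) + z (Uab - Ubb) - 4 z J X,
## with J = (2 Uab - Uaa - Ubb)/4.  At X = 1/2 this reduces to
## G(1/2) = z/2 (Uaa - Ubb) = 2 (Uaa - Ubb) = mu_alphabeta for z = 4,
## reproducing the transition chemical potential of the exact model.
## Subtracting mu_alphabeta and dividing by kBT gives the reduced shifted
## chemical potential
##   dG(X) / kBT = ln(X/(1-X)) - (2 z / Tbar) (2 X - 1),
## which is odd about X = 1/2.  Its slope at 1/2 vanishes at
## Tbar = z = 4: the mean-field critical temperature.

#' Mean-field critical temperature
#'
#' The Bragg-Williams closure on the square lattice (coordination number
#' z = 4) loses its single-well structure at \eqn{\bar T_c^{mf} = z = 4}.
#'
#' @return 4, the mean-field \eqn{\bar T_c} in units of \eqn{J}.
#' @export
mf_tc <- function() 4

# unflattened mean-field dG(X)/kBT (van der Waals loop retained)
mf_deltaG_raw <- function(x, tbar) {
  log(x / (1 - x)) - (2 * LATTICE_Z / tbar) * (2 * x - 1)
}

#' Mean-field reduced shifted chemical potential
#'
#' \eqn{\Delta G(X)/k_B T = \ln(X/(1-X)) - (2z/\bar T)(2X - 1)} with
#' z = 4, Maxwell-flattened: on the mean-field coexistence interval
#' \eqn{[x_\beta^{mf}, x_\alpha^{mf}]} the returned value is exactly 0,
#' so the function is globally non-decreasing as thermodynamic stability
#' requires, strictly increasing outside the binodal interval, and odd
#' about X = 1/2.
#'
#' @param x Mole fraction(s) in (0, 1); vectorized.
#' @param tbar Reduced temperature \eqn{\bar T > 0} (scalar).
#' @param flatten If \code{FALSE}, return the unflattened Bragg-Williams
#'   loop (used internally for root finding).
#' @return \eqn{\Delta G(X)/k_B T}.
#' @examples
#' mf_deltaG(0.5, 2)    # 0 (odd symmetry)
#' mf_deltaG(0.2, 2)    # 0: inside the coexistence interval at Tbar = 2
#' mf_deltaG(0.01, 2)   # negative: a-poor one-phase branch
#' @export
mf_deltaG <- function(x, tbar, flatten = TRUE) {
  stopifnot(length(tbar) == 1L, is.finite(tbar), tbar > 0)
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    stop("x must lie strictly inside (0, 1)")
  g <- mf_deltaG_raw(x, tbar)
  if (flatten && tbar < mf_tc()) {
    b <- mf_binodals(tbar)
    g[x >= b$x_beta & x <= b$x_alpha] <- 0
  }
  g
}

#' Mean-field binodals
#'
#' For \eqn{\bar T < \bar T_c^{mf} = 4} the symmetric pair of nontrivial
#' roots of the unflattened \code{\link{mf_deltaG}}, located by bracketed
#' root search on \eqn{(0, 1/2)}; by the odd symmetry of the loop this
#' coincides with the Maxwell equal-area construction.  Returns
#' (1/2, 1/2) at and above \eqn{\bar T_c^{mf}}.
#'
#' @inheritParams spontaneous_order
#' @return As \code{\link{exact_binodals}}: a \code{"binodal_pair"} for
#'   scalar input, a data frame for vector input.
#' @examples
#' mf_binodals(2)$x_beta   # ~0.0286
#' mf_binodals(4)$x_beta   # 0.5 (critical point)
#' @export
mf_binodals <- function(tbar) {
  if (any(!is.finite(tbar)) || any(tbar <= 0))
    stop("tbar must be positive and finite")
  one <- function(t) {
    if (t >= mf_tc()) return(0.5)
    # lower nontrivial root of the loop, solved for the log-odds
    # u = log(x/(1-x)) so that the low-temperature binodal
    # (x ~ exp(-2z/t)) keeps full relative precision
    f <- function(u) u - (2 * LATTICE_Z / t) * (2 * stats::plogis(u) - 1)
    lo <- -(2 * LATTICE_Z / t) - 1      # f(lo) < 0: log term dominates
    hi <- -1e-8                          # f < 0 only below the binodal
    if (f(hi) < 0) return(0.5)           # within ~1e-8 of the critical point
    stats::plogis(uniroot(f, c(lo, hi), tol = 1e-12)$root)
  }
  xb <- vapply(tbar, one, numeric(1))
  if (length(tbar) == 1L) {
    structure(list(x_beta = xb, x_alpha = 1 - xb, tbar = tbar),
              class = "binodal_pair")
  } else {
    data.frame(tbar = tbar, x_beta = xb, x_alpha = 1 - xb)
  }
}
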