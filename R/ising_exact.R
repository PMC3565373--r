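## Exact square-lattice Ising results: critical temperature, Onsager-Yang
## spontaneous order parameter, and the exact binodals of the equivalent
## lattice binary mixture.

#' Exact critical temperature of the square-lattice Ising model
#'
#' \eqn{\bar T_c = 2 / \ln(1 + \sqrt 2) \approx 2.269} in units of the
#' coupling \eqn{J} (i.e. \eqn{k_B T_c / J}).
#'
#' @return The dimensionless critical temperature.
#' @examples
#' ising_tc()  # 2.269185...
#' @export
ising_tc <- function() 2 / log(1 + sqrt(2))

#' Spontaneous order parameter of the square-lattice Ising model
#'
#' The zero-field magnetization
#' \deqn{\Upsilon(\bar T) = [1 - \sinh(2/\bar T)^{-4}]^{1/8}}
#' for \eqn{\bar T < \bar T_c}, and exactly 0 for
#' \eqn{\bar T \ge \bar T_c}.  In the lattice binary mixture
#' \eqn{\Upsilon} sets the binodal width: \eqn{X_{a,\alpha} -
#' X_{a,\beta} = \Upsilon}.
#'
#' Near \eqn{\bar T_c} the bracket \eqn{1 - \sinh(2/\bar T)^{-4}} is
#' evaluated through \code{expm1} to avoid catastrophic cancellation.
#'
#' @param tbar Reduced temperature(s) \eqn{\bar T > 0}; vectorized.
#' @return \eqn{\Upsilon(\bar T)} in [0, 1].
#' @examples
#' spontaneous_order(2.0)         # 0.9113194
#' spontaneous_order(ising_tc())  # 0
#' @export
spontaneous_order <- function(tbar) {
  if (any(!is.finite(tbar)) || any(tbar <= 0))
    stop("tbar must be positive and finite")
  ups <- numeric(length(tbar))
  below <- tbar < ising_tc()
  if (any(below)) {
    t <- tbar[below]
    # 1 - sinh(2/t)^-4 = -expm1(-4*log(sinh(2/t))): cancellation-safe
    bracket <- -expm1(-4 * log(sinh(2 / t)))
    ups[below] <- bracket^(1 / 8)
  }
  ups
}

#' Exact binodals of the uniform lattice binary mixture
#'
#' The coexisting mole fractions of the liquid-disordered (beta, a-poor)
#' and liquid-ordered (alpha, a-rich) phases:
#' \deqn{X_{a,\beta} = 1/2 - \Upsilon/2, \quad
#'       X_{a,\alpha} = 1/2 + \Upsilon/2.}
#' The pair collapses to (1/2, 1/2) for \eqn{\bar T \ge \bar T_c} and
#' satisfies \eqn{X_{a,\beta} + X_{a,\alpha} = 1} at every temperature
#' (particle-hole symmetry).
#'
#' @inheritParams spontaneous_order
#' @return For scalar input, an object of class \code{"binodal_pair"}
#'   (list with \code{x_beta}, \code{x_alpha}, \code{tbar}); for vector
#'   input a data frame with columns \code{tbar}, \code{x_beta},
#'   \code{x_alpha}.
#' @examples
#' exact_binodals(2.0)  # x_beta = 0.0443, x_alpha = 0.9557
#' @export
exact_binodals <- function(tbar) {
  ups <- spontaneous_order(tbar)
  if (length(tbar) == 1L) {
    structure(list(x_beta = 0.5 - ups / 2, x_alpha = 0.5 + ups / 2,
                   tbar = tbar),
              class = "binodal_pair")
  } else {
    data.frame(tbar = tbar, x_beta = 0.5 - ups / 2, x_alpha = 0.5 + ups / 2)
  }
}

#' @export
print.binodal_pair <- function(x, ...) {
  cat(sprintf("Binodal pair at Tbar = %g: x_beta = %.6f, x_alpha = %.6f\n",
              x$tbar, x$x_beta, x$x_alpha))
  invisible(x)
}
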