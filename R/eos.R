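## Equation-of-state backends.
##
## Both backends expose the same contract: reduced temperature, critical
## temperature, binodal pair, and the reduced shifted chemical potential
## dG(X)/kBT where available.  The "meanfield" backend has a full dG; the
## "exact-limit" backend knows dG only on coexistence (where it is 0) --
## there is no exact closed form for the 2D Ising equation of state in a
## finite ordering field -- so its off-coexistence spectator compositions
## are the limiting values for small or large affinity contrast.

#' Construct an equation-of-state backend
#'
#' @param backend \code{"meanfield"} or \code{"exact-limit"}.
#' @param tbar Reduced temperature \eqn{\bar T} in units of J.  Note the
#'   two backends have different critical temperatures
#'   (\code{\link{ising_tc}()} = 2.269 vs \code{\link{mf_tc}()} = 4); use
#'   \code{t_over_tc} to specify temperature on the normalized scale.
#' @param t_over_tc Alternative to \code{tbar}: temperature as a fraction
#'   of the backend's own critical temperature.
#' @return An object of class \code{"membrane_eos"}: a list with
#'   \code{backend}, \code{tbar}, \code{tc}, \code{t_over_tc},
#'   \code{binodals} (a \code{"binodal_pair"}) and \code{deltaG}
#'   (function of X, or \code{NULL} for the exact-limit backend).
#' @examples
#' eos <- membrane_eos("meanfield", t_over_tc = 0.5)
#' eos$binodals
#' @export
membrane_eos <- function(backend = c("meanfield", "exact-limit"),
                         tbar = NULL, t_over_tc = NULL) {
  backend <- match.arg(backend)
  tc <- if (backend == "meanfield") mf_tc() else ising_tc()
  if (is.null(tbar) && is.null(t_over_tc))
    stop("supply either tbar or t_over_tc")
  if (!is.null(tbar) && !is.null(t_over_tc))
    stop("supply only one of tbar and t_over_tc")
  if (is.null(tbar)) tbar <- t_over_tc * tc
  stopifnot(is.finite(tbar), tbar > 0)
  binodals <- if (backend == "meanfield") mf_binodals(tbar)
              else exact_binodals(tbar)
  deltaG <- if (backend == "meanfield") {
    force(tbar)
    function(x) mf_deltaG(x, tbar)
  } else NULL
  structure(
    list(backend = backend, tbar = tbar, tc = tc, t_over_tc = tbar / tc,
         binodals = binodals, deltaG = deltaG),
    class = "membrane_eos"
  )
}

#' @export
print.membrane_eos <- function(x, ...) {
  cat(sprintf("Equation of state [%s]: Tbar = %g (T/Tc = %.4f)\n",
              x$backend, x$tbar, x$t_over_tc))
  cat(sprintf("  binodals: x_beta = %.6f, x_alpha = %.6f\n",
              x$binodals$x_beta, x$binodals$x_alpha))
  invisible(x)
}
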