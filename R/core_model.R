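## Core parameter types and exact mappings between molecular interaction
## energies, reduced Ising variables, and segment affinities.
##
## Nearest-neighbor energies Uaa, Uab, Ubb define the Ising coupling
##   J = (2 Uab - Uaa - Ubb) / 4,
## the reduced temperature Tbar = kBT / J, and the transition chemical
## potential mu_alphabeta = 2 (Uaa - Ubb).  Sign convention throughout:
## attractive interaction potentials are negative; no auto-flipping.

#' Pairwise lattice interaction parameters
#'
#' Bundle the three nearest-neighbor interaction energies of the lattice
#' binary mixture together with the thermal energy, and derive the Ising
#' coupling \eqn{J = (2 U_{ab} - U_{aa} - U_{bb})/4} and the reduced
#' temperature \eqn{\bar T = k_B T / J}.
#'
#' A demixing transition requires \eqn{J > 0}, i.e.
#' \eqn{2 U_{ab} > U_{aa} + U_{bb}}: unlike pairs must be energetically
#' disfavored relative to the mean of the like pairs.
#'
#' @param Uaa,Uab,Ubb Nearest-neighbor interaction energies for a-a, a-b
#'   and b-b pairs (any consistent energy unit; attractive = negative).
#' @param kBT Thermal energy in the same unit; must be positive.
#' @return An object of class \code{"interaction_params"}: a list with
#'   elements \code{Uaa}, \code{Uab}, \code{Ubb}, \code{kBT}, \code{J}
#'   and \code{tbar}.
#' @examples
#' p <- interaction_params(Uaa = -1, Ubb = -1, Uab = 0, kBT = 1)
#' p$J     # 0.5
#' p$tbar  # 2
#' @export
interaction_params <- function(Uaa, Uab, Ubb, kBT = 1) {
  stopifnot(is.finite(Uaa), is.finite(Uab), is.finite(Ubb), is.finite(kBT))
  if (kBT <= 0) stop("kBT must be positive")
  J <- (2 * Uab - Uaa - Ubb) / 4
  if (J <= 0)
    stop("coupling J = (2*Uab - Uaa - Ubb)/4 must be positive for a ",
         "demixing transition (got J = ", format(J), ")")
  structure(
    list(Uaa = Uaa, Uab = Uab, Ubb = Ubb, kBT = kBT, J = J, tbar = kBT / J),
    class = "interaction_params"
  )
}

#' @export
print.interaction_params <- function(x, ...) {
  cat("Lattice binary mixture interaction parameters\n")
  cat(sprintf("  Uaa = %g, Uab = %g, Ubb = %g (kBT = %g)\n",
              x$Uaa, x$Uab, x$Ubb, x$kBT))
  cat(sprintf("  coupling J = %g, reduced temperature Tbar = %g\n",
              x$J, x$tbar))
  invisible(x)
}

#' Reduced temperature of the lattice binary mixture
#'
#' \eqn{\bar T = k_B T / J = 4 k_B T / (2 U_{ab} - U_{aa} - U_{bb})}.
#'
#' @param params An \code{\link{interaction_params}} object.
#' @return The dimensionless temperature \eqn{\bar T}.
#' @export
reduced_temperature <- function(params) {
  stopifnot(inherits(params, "interaction_params"))
  params$kBT / params$J
}

#' Transition chemical potential of the uniform mixture
#'
#' The relative chemical potential at which the uniform (uni-env) lattice
#' binary mixture undergoes its demixing transition for
#' \eqn{0 \le \bar T < \bar T_c}:
#' \eqn{\mu_{\alpha\beta} = 2 (U_{aa} - U_{bb})}.
#'
#' @inheritParams reduced_temperature
#' @return \eqn{\mu_{\alpha\beta}} in the energy unit of \code{params}.
#' @export
mu_alphabeta <- function(params) {
  stopifnot(inherits(params, "interaction_params"))
  2 * (params$Uaa - params$Ubb)
}

#' Dimensionless ordering field of the equivalent Ising model
#'
#' \eqn{\bar H = [\Delta\mu/2 - (U_{aa} - U_{bb})] / k_B T}, where
#' \eqn{\Delta\mu = \mu_a - \mu_b} is the relative chemical potential.
#' \eqn{\bar H = 0} exactly when \eqn{\Delta\mu = \mu_{\alpha\beta}}.
#'
#' @param dmu Relative chemical potential \eqn{\Delta\mu} (energy unit of
#'   \code{params}).
#' @inheritParams reduced_temperature
#' @return The dimensionless field \eqn{\bar H}.
#' @export
ordering_field <- function(dmu, params) {
  stopifnot(inherits(params, "interaction_params"), is.finite(dmu))
  (dmu / 2 - (params$Uaa - params$Ubb)) / params$kBT
}

#' Segment affinities of an adhering membrane
#'
#' Each membrane segment S[m] (m = 1, 2) is characterized by the
#' interaction potentials \code{Ua} and \code{Ub} of the a- and
#' b-molecules with the segment's environment (attractive = negative; an
#' unbound segment has both equal to 0).  The relative affinity of
#' segment m is \eqn{\Delta U^{[m]} = U_a^{[m]} - U_b^{[m]}} and the
#' affinity contrast between the segments is
#' \eqn{\Delta U^{2,1} = \Delta U^{[2]} - \Delta U^{[1]}}.
#'
#' \eqn{\Delta U^{2,1} > 0} means the b-molecules are the stickier
#' species in segment 2 relative to segment 1, so a-molecules are
#' recruited into segment 1.
#'
#' @param Ua1,Ub1 Interaction potentials of a- and b-molecules with the
#'   environment of segment 1 (default 0 0: unbound segment).
#' @param Ua2,Ub2 Same for segment 2.
#' @param kBTc Optional thermal energy at the critical point, used only to
#'   report the reduced contrast \eqn{\Delta U^{2,1} / k_B T_c}.
#' @return An object of class \code{"segment_affinities"} with elements
#'   \code{Ua1}, \code{Ub1}, \code{Ua2}, \code{Ub2}, \code{dU1},
#'   \code{dU2}, \code{dU21} and (if \code{kBTc} given)
#'   \code{dU21_reduced}.
#' @examples
#' # unbound segment 1; b-molecules stickier than a-molecules in segment 2
#' aff <- segment_affinities(Ua2 = -1, Ub2 = -3)
#' aff$dU21  # +2
#' @export
segment_affinities <- function(Ua1 = 0, Ub1 = 0, Ua2 = 0, Ub2 = 0,
                               kBTc = NULL) {
  stopifnot(is.finite(Ua1), is.finite(Ub1), is.finite(Ua2), is.finite(Ub2))
  dU1 <- Ua1 - Ub1
  dU2 <- Ua2 - Ub2
  out <- list(Ua1 = Ua1, Ub1 = Ub1, Ua2 = Ua2, Ub2 = Ub2,
              dU1 = dU1, dU2 = dU2, dU21 = dU2 - dU1)
  if (!is.null(kBTc)) {
    stopifnot(is.finite(kBTc), kBTc > 0)
    out$dU21_reduced <- out$dU21 / kBTc
  }
  structure(out, class = "segment_affinities")
}

#' Affinity contrast between the two membrane segments
#'
#' \eqn{\Delta U^{2,1} = \Delta U^{[2]} - \Delta U^{[1]}}; antisymmetric
#' under relabeling the segments.
#'
#' @param aff A \code{\link{segment_affinities}} object.
#' @return The affinity contrast (energy unit of the inputs).
#' @export
affinity_contrast <- function(aff) {
  stopifnot(inherits(aff, "segment_affinities"))
  aff$dU21
}

#' Membrane composition and segmentation parameters
#'
#' @param q1 Area fraction of segment 1, in [0, 1].
#' @param Xa Overall mole fraction of the a-molecules, in [0, 1].
#' @return An object of class \code{"membrane_spec"} with \code{q1},
#'   \code{q2 = 1 - q1}, \code{Xa} and \code{Xb = 1 - Xa}.
#' @export
membrane_spec <- function(q1, Xa) {
  stopifnot(is.finite(q1), is.finite(Xa))
  if (q1 < 0 || q1 > 1) stop("q1 must lie in [0, 1]")
  if (Xa < 0 || Xa > 1) stop("Xa must lie in [0, 1]")
  structure(list(q1 = q1, q2 = 1 - q1, Xa = Xa, Xb = 1 - Xa),
            class = "membrane_spec")
}
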