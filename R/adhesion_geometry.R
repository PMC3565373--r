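## Spherical-cap geometry of strongly adhering vesicles and the
## strong-adhesion criterion.
##
## A vesicle in the strong-adhesion regime assumes a spherical-cap shape
## with effective contact angle theta_eff.  With sphere radius R and
## h = R (1 - cos theta):
##   unbound cap area   A1 = 2 pi R^2 (1 - cos theta)
##   contact-disk area  A2 = pi (R sin theta)^2
##   enclosed volume    V  = (pi/3) h^2 (3 R - h)
## so the unbound area fraction is
##   q1 = A1 / (A1 + A2) = 2 / (3 + cos theta)
## using sin^2 = (1 - cos)(1 + cos).  The reduced volume is
##   v = 3 V / (4 pi) / (A / (4 pi))^(3/2),
## scale-free (independent of R), equal to 1 for the free sphere.

#' Unbound area fraction of a spherical-cap vesicle
#'
#' \eqn{q^{[1]} = 2 / (3 + \cos\theta_{eff})}, increasing from 1/2
#' (flat pancake, \eqn{\theta \to 0}) through 2/3 (hemisphere,
#' \eqn{\theta = \pi/2}) to 1 (free sphere touching at a point,
#' \eqn{\theta = \pi}).
#'
#' @param theta_eff Effective contact angle(s) in radians, in
#'   \eqn{(0, \pi]}; vectorized.
#' @return Area fraction(s) in (1/2, 1].
#' @examples
#' q1_from_angle(pi / 2)  # 2/3
#' @export
q1_from_angle <- function(theta_eff) {
  if (any(!is.finite(theta_eff)) || any(theta_eff <= 0) ||
      any(theta_eff > pi))
    stop("theta_eff must lie in (0, pi]")
  2 / (3 + cos(theta_eff))
}

#' Full spherical-cap geometry
#'
#' @inheritParams q1_from_angle
#' @param R Sphere radius (length scale; the dimensionless outputs q1
#'   and v do not depend on it).
#' @return An object of class \code{"cap_geometry"}: list with
#'   \code{theta_eff}, \code{q1}, \code{v} (reduced volume), \code{R},
#'   \code{A}, \code{A1}, \code{A2}, \code{V}.
#' @examples
#' cap_geometry(pi / 2)$v  # 0.7698
#' @export
cap_geometry <- function(theta_eff, R = 1) {
  stopifnot(length(theta_eff) == 1L, is.finite(R), R > 0)
  if (!is.finite(theta_eff) || theta_eff <= 0 || theta_eff > pi)
    stop("theta_eff must lie in (0, pi]")
  ct <- cos(theta_eff)
  A1 <- 2 * pi * R^2 * (1 - ct)
  A2 <- pi * (R * sin(theta_eff))^2
  A <- A1 + A2
  h <- R * (1 - ct)
  V <- (pi / 3) * h^2 * (3 * R - h)
  v <- (3 * V / (4 * pi)) / (A / (4 * pi))^1.5
  structure(list(theta_eff = theta_eff, q1 = q1_from_angle(theta_eff),
                 v = v, R = R, A = A, A1 = A1, A2 = A2, V = V),
            class = "cap_geometry")
}

#' @export
print.cap_geometry <- function(x, ...) {
  cat(sprintf(
    "Spherical cap: theta_eff = %.4f rad, q1 = %.6f, v = %.6f\n",
    x$theta_eff, x$q1, x$v))
  cat(sprintf("  A1/A = %.6f, A2/A = %.6f (R = %g)\n",
              x$A1 / x$A, x$A2 / x$A, x$R))
  invisible(x)
}

#' Unbound area fraction from reduced volume
#'
#' The reduced volume v is strictly increasing in the contact angle, so
#' it determines the cap shape uniquely; this inverts
#' \code{\link{cap_geometry}} by monotone root search and applies
#' \code{\link{q1_from_angle}}.
#'
#' @param v Reduced volume(s) in (0, 1]; vectorized.
#' @return Area fraction(s) q1.
#' @examples
#' q1_from_reduced_volume(1)  # 1 (free sphere)
#' @export
q1_from_reduced_volume <- function(v) {
  if (any(!is.finite(v)) || any(v <= 0) || any(v > 1))
    stop("v must lie in (0, 1]")
  one <- function(vv) {
    if (vv == 1) return(1)
    theta <- uniroot(function(th) cap_geometry(th)$v - vv,
                     c(1e-9, pi), tol = 1e-14)$root
    q1_from_angle(theta)
  }
  vapply(v, one, numeric(1))
}

#' Contact curvature radius
#'
#' \eqn{R_{co} = \sqrt{\kappa / (2 |W|)}}: the radius of curvature of
#' the membrane along the contact line, set by the bending rigidity
#' \eqn{\kappa} and the adhesion free energy per area W (negative for
#' an attractive surface).
#'
#' @param kappa Bending rigidity (energy), > 0.
#' @param W Adhesion free energy per area (energy/length^2), < 0.
#' @return \eqn{R_{co}} in the consistent length unit.
#' @examples
#' contact_radius(1e-19, -2e-7)  # 0.5e-6 m for kappa in J, W in J/m^2
#' @export
contact_radius <- function(kappa, W) {
  stopifnot(is.finite(kappa), is.finite(W))
  if (kappa <= 0) stop("kappa must be positive")
  if (W >= 0) stop("W must be negative (attractive substrate)")
  sqrt(kappa / (2 * abs(W)))
}

#' Strong-adhesion threshold adhesion strength
#'
#' \eqn{|W|_* = \kappa / (2 L_*^2)}: the adhesion strength at which the
#' contact curvature radius equals the resolution length \eqn{L_*}.
#' For \eqn{\kappa = 10^{-19}} J and \eqn{L_* = 0.5\,\mu m} (optical
#' resolution) this gives \eqn{2 \times 10^{-7}} J/m\eqn{^2} =
#' \eqn{2 \times 10^{-4}} mJ/m\eqn{^2}.
#'
#' @inheritParams contact_radius
#' @param Lstar Resolution length, > 0 (same length unit as kappa's).
#' @return \eqn{|W|_*} (energy/length^2).
#' @export
strong_adhesion_threshold <- function(kappa, Lstar) {
  stopifnot(is.finite(kappa), is.finite(Lstar))
  if (kappa <= 0) stop("kappa must be positive")
  if (Lstar <= 0) stop("Lstar must be positive")
  kappa / (2 * Lstar^2)
}

#' Strong-adhesion predicate
#'
#' The strong-adhesion regime requires the contact curvature radius to
#' be much smaller than the vesicle size \eqn{R_{ve} = (A/4\pi)^{1/2}},
#' equivalently \eqn{|W| \gg 2\pi\kappa/A}.  "Much smaller" is encoded
#' by a configurable separation factor (default 10): the membrane is in
#' the strong regime iff \eqn{|W| \ge f \cdot 2\pi\kappa/A}.
#'
#' @inheritParams contact_radius
#' @param A Total membrane area (length^2), > 0.
#' @param factor Separation factor f, default 10.
#' @return Logical.
#' @export
in_strong_regime <- function(kappa, W, A, factor = 10) {
  stopifnot(is.finite(A), A > 0, is.finite(factor), factor > 0)
  if (kappa <= 0) stop("kappa must be positive")
  if (W >= 0) stop("W must be negative (attractive substrate)")
  abs(W) >= factor * 2 * pi * kappa / A
}

#' Thermal-energy unit conversions at room temperature
#'
#' Convenience constants for expressing mechanical membrane parameters
#' in thermal units at \eqn{T_o} = 25 degrees C = 298.15 K.
#'
#' @param energy_J Energy in joules.
#' @return The energy in units of \eqn{k_B T_o}.
#' @examples
#' kBT_room(1e-19)  # ~24: a typical lipid-bilayer bending rigidity
#' @export
kBT_room <- function(energy_J) {
  kB <- 1.380649e-23  # J/K, exact SI value
  energy_J / (kB * 298.15)
}
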