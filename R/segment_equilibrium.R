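## Coupled partitioning + chemical-equilibrium system for the two
## membrane segments.
##
## Two relations determine the segment compositions Xa1, Xa2 at given
## overall composition Xa, area fraction q1 and affinity contrast dU21
## (in units of kBT):
##   partitioning (lever rule):   q1 * Xa1 + (1 - q1) * Xa2 = Xa
##   chemical equilibrium:        dG(Xa1) = dG(Xa2) + dU21
## When one segment phase separates, its dG is pinned to 0 and the other
## segment becomes a uniform "spectator" phase whose composition solves
## dG(x) = -dU21 (segment 1 separating) or dG(x) = +dU21 (segment 2
## separating).

# composition tolerance of the solvers; epsilon margin at the (0,1) ends
.SOLVE_TOL <- 1e-12
.X_EPS <- 1e-9

#' Spectator-phase mole fraction
#'
#' When segment \code{separating} undergoes phase separation, the other
#' segment stays uniform (the spectator phase).  Its mole fraction
#' \eqn{X_{a,*}} solves \eqn{\Delta G(x) = -\Delta U^{2,1}} if segment 1
#' separates, or \eqn{\Delta G(x) = +\Delta U^{2,1}} if segment 2
#' separates, on the monotone branch selected by the sign of the
#' contrast: a positive contrast drives a-molecules into segment 1, so
#' the spectator in segment 2 is a-poor (\eqn{x < x_\beta}) while a
#' spectator in segment 1 is a-rich (\eqn{x > x_\alpha}); the branches
#' swap for negative contrast.
#'
#' The mean-field backend finds the root numerically.  The exact-limit
#' backend has no off-coexistence equation of state, so it returns the
#' limiting values: for small contrast the adjacent binodal
#' (\eqn{x_\beta} or \eqn{x_\alpha}), for large contrast full depletion
#' or saturation (0 or 1).  Which regime applies is an explicit caller
#' choice via \code{regime}.
#'
#' @param separating Which segment phase separates: 1 or 2.
#' @param du21 Affinity contrast \eqn{\Delta U^{2,1}} in units of
#'   \eqn{k_B T}; must be nonzero (a zero contrast means the whole
#'   membrane separates and no spectator exists).
#' @param eos A \code{\link{membrane_eos}} below its critical
#'   temperature.
#' @param regime For the exact-limit backend: \code{"small"} or
#'   \code{"large"} contrast limit.  Ignored by the mean-field backend.
#' @return The spectator mole fraction in [0, 1].
#' @examples
#' eos <- membrane_eos("meanfield", tbar = 2)
#' x <- spectator_fraction(1, du21 = 1, eos)   # in (0, x_beta)
#' mf_deltaG(x, 2)  # == -1
#' @export
spectator_fraction <- function(separating, du21, eos,
                               regime = c("small", "large")) {
  stopifnot(separating %in% c(1, 2), inherits(eos, "membrane_eos"),
            is.finite(du21))
  if (du21 == 0)
    stop("du21 = 0 is the degenerate whole-membrane coexistence case; ",
         "use solve_state()")
  if (eos$tbar >= eos$tc)
    stop("no coexistence above the critical temperature of the '",
         eos$backend, "' backend")
  # dG at the spectator composition
  target <- if (separating == 1) -du21 else du21
  b <- eos$binodals
  if (eos$backend == "exact-limit") {
    regime <- match.arg(regime)
    if (target < 0) {      # a-poor branch
      return(if (regime == "small") b$x_beta else 0)
    } else {               # a-rich branch
      return(if (regime == "small") b$x_alpha else 1)
    }
  }
  # mean-field: bracketed root of the unflattened loop on the strict
  # branch, solved in logit space so that compositions exponentially
  # close to 0 or 1 (large contrasts) keep full relative precision
  if (target < 0) {
    mf_branch_root(target, eos$tbar, upper_branch = FALSE,
                   x_bound = b$x_beta)
  } else {
    mf_branch_root(target, eos$tbar, upper_branch = TRUE,
                   x_bound = b$x_alpha)
  }
}

#' Solve the phase state of an adhering membrane
#'
#' Classifies the membrane at overall composition \code{Xa} into one of
#' three states and returns the segment compositions:
#' \itemize{
#'   \item \code{coex_segment_1}: segment 1 holds coexisting
#'     alpha/beta domains (\eqn{x_\beta \le X_a^{[1]} \le x_\alpha})
#'     while segment 2 is the uniform spectator phase;
#'   \item \code{coex_segment_2}: the mirror situation;
#'   \item \code{one_phase}: both segments uniform.
#' }
#' At zero affinity contrast the molecules have no segment preference:
#' \eqn{X_a^{[1]} = X_a^{[2]} = X_a} and the \emph{whole} membrane
#' coexists whenever \eqn{X_a} lies between the binodals (reported with
#' \code{whole_membrane = TRUE}).
#'
#' The coexistence windows in overall composition are closed intervals
#' obtained by inserting the binodal bounds and the spectator fraction
#' into the lever rule; boundary points classify as coexistence.  For a
#' nonzero contrast the two windows are provably disjoint (the
#' intermediate one-phase region); this is asserted, not assumed.
#'
#' In the one-phase state the mean-field backend solves the full
#' two-equation system by monotone bracketed root search; the
#' exact-limit backend (which lacks an off-coexistence equation of
#' state) labels the state but reports \code{NA} compositions.
#'
#' @param Xa Overall mole fraction of a-molecules, in [0, 1].
#' @param q1 Area fraction of segment 1, in [0, 1].  The limits 0 and 1
#'   reduce to the uniform-environment problem on the surviving segment.
#' @param du21 Affinity contrast per \eqn{k_B T}.
#' @param eos A \code{\link{membrane_eos}}.
#' @param regime Exact-limit contrast regime, see
#'   \code{\link{spectator_fraction}}.
#' @return An object of class \code{"segment_state"}: list with
#'   \code{Xa1}, \code{Xa2}, \code{Xa}, \code{q1}, \code{du21},
#'   \code{phase}, \code{whole_membrane}, and \code{spectator} (list
#'   with \code{segment} and \code{x}, or \code{NULL}).
#' @examples
#' eos <- membrane_eos("exact-limit", tbar = 2)
#' solve_state(0.3, q1 = 0.7, du21 = 50, eos, regime = "large")
#' @export
solve_state <- function(Xa, q1, du21, eos, regime = c("small", "large")) {
  stopifnot(inherits(eos, "membrane_eos"))
  if (!is.finite(Xa) || !is.finite(q1) || !is.finite(du21))
    stop("Xa, q1 and du21 must be finite")
  if (Xa < 0 || Xa > 1) stop("Xa must lie in [0, 1]")
  if (q1 < 0 || q1 > 1) stop("q1 must lie in [0, 1]")
  b <- eos$binodals
  mk <- function(Xa1, Xa2, phase, whole = FALSE, spectator = NULL) {
    structure(list(Xa1 = Xa1, Xa2 = Xa2, Xa = Xa, q1 = q1, du21 = du21,
                   phase = phase, whole_membrane = whole,
                   spectator = spectator),
              class = "segment_state")
  }

  ## (i) zero contrast: no segment preference, whole membrane behaves
  ##     as the uni-env mixture
  if (du21 == 0) {
    coex <- eos$tbar < eos$tc && Xa >= b$x_beta && Xa <= b$x_alpha
    return(mk(Xa, Xa, if (coex) "coex_segment_1" else "one_phase",
              whole = coex))
  }

  windows <- segment_windows(q1, du21, eos, regime)
  w1 <- windows$window1
  w2 <- windows$window2
  if (!is.null(w1) && !is.null(w2)) {
    # interiors must be disjoint; a shared endpoint is allowed (the
    # exact small-contrast limit collapses the one-phase gap to a point)
    overlap <- max(w1[1], w2[1]) < min(w1[2], w2[2])
    if (overlap)
      stop("internal error: coexistence windows overlap for nonzero ",
           "contrast")  # nocov
  }

  ## (ii) segment-1 coexistence window
  if (!is.null(w1) && Xa >= w1[1] && Xa <= w1[2]) {
    xs2 <- spectator_fraction(1, du21, eos, regime)
    Xa1 <- if (q1 > 0) (Xa - (1 - q1) * xs2) / q1 else NA_real_
    return(mk(Xa1, xs2, "coex_segment_1",
              spectator = list(segment = 2L, x = xs2)))
  }
  ## (iii) segment-2 coexistence window
  if (!is.null(w2) && Xa >= w2[1] && Xa <= w2[2]) {
    xs1 <- spectator_fraction(2, du21, eos, regime)
    Xa2 <- if (q1 < 1) (Xa - q1 * xs1) / (1 - q1) else NA_real_
    return(mk(xs1, Xa2, "coex_segment_2",
              spectator = list(segment = 1L, x = xs1)))
  }

  ## (iv) one-phase region
  if (eos$backend == "exact-limit")
    return(mk(NA_real_, NA_real_, "one_phase"))
  sol <- one_phase_solve(Xa, q1, du21, eos)
  mk(sol[1], sol[2], "one_phase")
}

# root of mf_deltaG_raw(x) = target on one strict monotone branch,
# parameterized by the log-odds u = log(x/(1-x)); the linear term of the
# loop is bounded by 2z/tbar, which gives a guaranteed outer bracket
mf_branch_root <- function(target, tbar, upper_branch, x_bound) {
  f <- function(u) {
    x <- stats::plogis(u)
    u - (2 * LATTICE_Z / tbar) * (2 * x - 1) - target
  }
  span <- 2 * LATTICE_Z / tbar + 1
  u_bound <- log(x_bound / (1 - x_bound))
  bracket <- if (upper_branch) c(u_bound, target + span)
             else c(target - span, u_bound)
  if (f(bracket[1]) > 0 || f(bracket[2]) < 0)
    stop("internal error: no spectator root on the ",
         if (upper_branch) "a-rich" else "a-poor", " branch")  # nocov
  u <- uniroot(f, bracket, tol = .SOLVE_TOL)$root
  stats::plogis(u)
}

# mean-field one-phase compositions: monotone root search on Xa1 with
# Xa2 eliminated through the lever rule
one_phase_solve <- function(Xa, q1, du21, eos) {
  tbar <- eos$tbar
  if (Xa <= 0) return(c(0, 0))
  if (Xa >= 1) return(c(1, 1))
  if (q1 == 1) {
    # ghost segment 2 (zero area) still equilibrates chemically
    x2 <- ghost_composition(Xa, -du21, tbar)
    return(c(Xa, x2))
  }
  if (q1 == 0) {
    x1 <- ghost_composition(Xa, du21, tbar)
    return(c(x1, Xa))
  }
  g <- function(x) mf_deltaG(x, tbar)
  lo <- max(.X_EPS, (Xa - (1 - q1) * (1 - .X_EPS)) / q1)
  hi <- min(1 - .X_EPS, (Xa - (1 - q1) * .X_EPS) / q1)
  f <- function(x1) {
    x2 <- (Xa - q1 * x1) / (1 - q1)
    g(x1) - g(x2) - du21
  }
  # f is non-decreasing in x1; endpoints diverge to -Inf/+Inf except
  # when the root hugs the feasibility boundary closer than the epsilon
  # margin (saturated segments at extreme contrasts) -- then clamp
  x1 <- if (f(lo) >= 0) lo else if (f(hi) <= 0) hi
        else uniroot(f, c(lo, hi), tol = .SOLVE_TOL)$root
  x2 <- (Xa - q1 * x1) / (1 - q1)
  c(x1, x2)
}

# composition of a zero-area segment in chemical equilibrium with a
# uniform segment at composition x_other: dG(x) = dG(x_other) + shift
ghost_composition <- function(x_other, shift, tbar) {
  target <- mf_deltaG(x_other, tbar) + shift
  b <- mf_binodals(tbar)
  if (target < 0)
    mf_branch_root(target, tbar, upper_branch = FALSE,
                   x_bound = b$x_beta)
  else if (target > 0)
    mf_branch_root(target, tbar, upper_branch = TRUE,
                   x_bound = b$x_alpha)
  else 0.5
}

#' @export
print.segment_state <- function(x, ...) {
  cat(sprintf("Membrane state at Xa = %g, q1 = %g, dU21/kBT = %g\n",
              x$Xa, x$q1, x$du21))
  cat(sprintf("  phase: %s%s\n", x$phase,
              if (isTRUE(x$whole_membrane)) " (whole membrane)" else ""))
  cat(sprintf("  Xa[1] = %s, Xa[2] = %s\n",
              format(x$Xa1), format(x$Xa2)))
  if (!is.null(x$spectator))
    cat(sprintf("  spectator: segment %d at Xa,* = %.6f\n",
                x$spectator$segment, x$spectator$x))
  invisible(x)
}
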