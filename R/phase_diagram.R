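## Phase diagrams of adhering membranes in the (Xa, T/Tc)-plane.
##
## Inserting the binodal interval of the separating segment and the
## spectator fraction of the other segment into the lever rule maps each
## segment's coexistence region into overall composition:
##   window1 = [q1*x_beta + (1-q1)*Xs2,  q1*x_alpha + (1-q1)*Xs2]
##   window2 = [q1*Xs1 + (1-q1)*x_beta,  q1*Xs1 + (1-q1)*x_alpha]
## For nonzero affinity contrast the two windows are disjoint and
## separated by an intermediate one-phase region.

#' Coexistence windows of the two segments in overall composition
#'
#' @inheritParams solve_state
#' @param q1 Area fraction of segment 1.
#' @return List with \code{window1} and \code{window2}, each a numeric
#'   \code{c(lo, hi)} or \code{NULL} when empty (above the backend's
#'   critical temperature, or zero segment area).
#' @examples
#' eos <- membrane_eos("exact-limit", tbar = 2)
#' segment_windows(0.7, du21 = 50, eos, regime = "large")
#' @export
segment_windows <- function(q1, du21, eos, regime = c("small", "large")) {
  stopifnot(inherits(eos, "membrane_eos"), is.finite(q1), is.finite(du21))
  if (q1 < 0 || q1 > 1) stop("q1 must lie in [0, 1]")
  if (eos$tbar >= eos$tc)
    return(list(window1 = NULL, window2 = NULL))
  b <- eos$binodals
  if (du21 == 0) {
    # degenerate: whole membrane coexists over the uni-env window
    w <- c(b$x_beta, b$x_alpha)
    return(list(window1 = if (q1 > 0) w else NULL,
                window2 = if (q1 < 1) w else NULL))
  }
  w1 <- if (q1 > 0) {
    xs2 <- spectator_fraction(1, du21, eos, regime)
    q1 * c(b$x_beta, b$x_alpha) + (1 - q1) * xs2
  }
  w2 <- if (q1 < 1) {
    xs1 <- spectator_fraction(2, du21, eos, regime)
    q1 * xs1 + (1 - q1) * c(b$x_beta, b$x_alpha)
  }
  list(window1 = w1, window2 = w2)
}

#' Uni-env reference binodals over a temperature grid
#'
#' Binodals of the same two-component membrane in a uniform environment,
#' the reference system whose single coexistence region splits under
#' adhesion.
#'
#' @param t_over_tc Vector of reduced temperatures T/Tc (each backend's
#'   own critical temperature).
#' @param backend \code{"meanfield"} or \code{"exact-limit"}.
#' @return Data frame with columns \code{t_over_tc}, \code{x_beta},
#'   \code{x_alpha}.
#' @export
uniform_reference <- function(t_over_tc, backend = c("meanfield",
                                                     "exact-limit")) {
  backend <- match.arg(backend)
  tc <- if (backend == "meanfield") mf_tc() else ising_tc()
  tb <- t_over_tc * tc
  b <- if (backend == "meanfield") mf_binodals(tb) else exact_binodals(tb)
  if (length(tb) == 1L) b <- data.frame(tbar = tb, x_beta = b$x_beta,
                                        x_alpha = b$x_alpha)
  data.frame(t_over_tc = t_over_tc, x_beta = b$x_beta,
             x_alpha = b$x_alpha)
}

#' Build a full adhering-membrane phase diagram
#'
#' Computes, for each temperature on the grid, the coexistence windows
#' of both segments in overall composition plus the uni-env reference
#' binodals.  Empty windows (above the critical point or zero segment
#' area) are stored as \code{NA} so the table is schema-stable.
#'
#' @param t_over_tc Temperature grid in units of the backend's critical
#'   temperature; default 200 points on [0.05, 1.05].
#' @param q1 Area fraction of segment 1.
#' @param du21 Affinity contrast per \eqn{k_B T}.
#' @param backend \code{"meanfield"} or \code{"exact-limit"}.
#' @param regime Exact-limit contrast regime, see
#'   \code{\link{spectator_fraction}}.
#' @return A data frame of class \code{"phase_diagram"} with columns
#'   \code{t_over_tc}, \code{seg1_lo}, \code{seg1_hi}, \code{seg2_lo},
#'   \code{seg2_hi}, \code{uni_lo}, \code{uni_hi}; attributes
#'   \code{backend}, \code{q1}, \code{du21}, \code{regime}.
#' @examples
#' pd <- build_diagram(seq(0.1, 1, length.out = 10), q1 = 0.7,
#'                     du21 = 50, backend = "exact-limit",
#'                     regime = "large")
#' head(pd)
#' @export
build_diagram <- function(t_over_tc = seq(0.05, 1.05, length.out = 200),
                          q1, du21,
                          backend = c("meanfield", "exact-limit"),
                          regime = c("small", "large")) {
  backend <- match.arg(backend)
  stopifnot(all(is.finite(t_over_tc)), all(t_over_tc > 0))
  rows <- lapply(t_over_tc, function(tt) {
    eos <- membrane_eos(backend, t_over_tc = tt)
    w <- segment_windows(q1, du21, eos, regime)
    c(seg1_lo = if (is.null(w$window1)) NA_real_ else w$window1[1],
      seg1_hi = if (is.null(w$window1)) NA_real_ else w$window1[2],
      seg2_lo = if (is.null(w$window2)) NA_real_ else w$window2[1],
      seg2_hi = if (is.null(w$window2)) NA_real_ else w$window2[2])
  })
  wmat <- do.call(rbind, rows)
  uni <- uniform_reference(t_over_tc, backend)
  out <- data.frame(t_over_tc = t_over_tc, wmat,
                    uni_lo = uni$x_beta, uni_hi = uni$x_alpha)
  structure(out, backend = backend, q1 = q1, du21 = du21,
            regime = if (backend == "exact-limit")
              match.arg(regime) else NA_character_,
            class = c("phase_diagram", "data.frame"))
}

#' Plot a phase diagram
#'
#' Base-graphics rendering: segment-1 coexistence region in blue,
#' segment-2 in red, the uni-env reference binodals as broken lines.
#'
#' @param x A \code{"phase_diagram"} object.
#' @param ... Passed to \code{plot.default}.
#' @export
plot.phase_diagram <- function(x, ...) {
  plot(NA, xlim = c(0, 1), ylim = range(x$t_over_tc),
       xlab = expression(X[a]), ylab = expression(T / T[c]), ...)
  shade <- function(lo, hi, col) {
    ok <- !is.na(lo)
    if (!any(ok)) return(invisible())
    tt <- x$t_over_tc[ok]
    graphics::polygon(c(lo[ok], rev(hi[ok])), c(tt, rev(tt)),
                      col = grDevices::adjustcolor(col, 0.3), border = col)
  }
  shade(x$seg1_lo, x$seg1_hi, "blue")
  shade(x$seg2_lo, x$seg2_hi, "red")
  graphics::lines(x$uni_lo, x$t_over_tc, lty = 2)
  graphics::lines(x$uni_hi, x$t_over_tc, lty = 2)
  invisible(x)
}
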