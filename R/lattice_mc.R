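## Semi-grand-canonical Metropolis Monte Carlo on the two-sublattice
## configurational energy, plus an exact-enumeration oracle for tiny
## lattices.
##
## Geometry: an L x L square lattice, periodic in both directions, split
## into vertical strips -- columns 1..c form segment 1, columns c+1..L
## form segment 2 -- so q1 = c/L.  Bonds joining sites of different
## segments are the lattice realization of the domain-boundary energy;
## they are included by default (physically contiguous membrane) and can
## be excluded to mimic the fully decoupled large-membrane limit.
##
## Ensemble: single-site species flips n_i -> 1 - n_i (semi-grand
## canonical: inserting an a-molecule removes a b-molecule), accepted
## with the Metropolis probability min(1, exp(-dE/kBT)).
##
## Units: all energies per kBT.  When only the reduced parameters
## (Tbar, dmu, dU) are given, the pair energies are fixed in the
## symmetric gauge Uaa = Ubb = 0, Uab = 2J, which leaves the physics
## (J, Tbar) unchanged and puts the uniform transition at dmu = 0
## (mu_alphabeta = 0, Hbar = dmu/2).

#' Two-segment lattice specification
#'
#' @param L Linear lattice size (sites per side), >= 2.
#' @param c Column split: columns 1..c belong to segment 1, the rest to
#'   segment 2; \code{q1 = c / L}.  0 or L gives a uniform lattice.
#' @param cross_boundary Include bonds joining the two segments
#'   (default \code{TRUE}).
#' @return Object of class \code{"lattice_spec"}: list with \code{L},
#'   \code{c}, \code{cross_boundary}, \code{n1}, \code{n2}, \code{q1}.
#' @export
lattice_spec <- function(L, c = 0L, cross_boundary = TRUE) {
  L <- as.integer(L); c <- as.integer(c)
  stopifnot(length(L) == 1L, length(c) == 1L, L >= 2, c >= 0, c <= L)
  structure(list(L = L, c = c, cross_boundary = isTRUE(cross_boundary),
                 n1 = c * L, n2 = (L - c) * L, q1 = c / L),
            class = "lattice_spec")
}

#' Monte Carlo run parameters
#'
#' Either reduced parameters (\code{tbar} with per-\eqn{k_B T} fields)
#' or raw energies (an \code{\link{interaction_params}} object with
#' \code{dmu}, \code{du1}, \code{du2} in the same energy unit) may be
#' given.
#'
#' @param tbar Reduced temperature \eqn{\bar T} (ignored when
#'   \code{interaction} is supplied).
#' @param dmu Relative chemical potential \eqn{\Delta\mu}; per
#'   \eqn{k_B T} in the reduced parametrization, in energy units with
#'   \code{interaction}.  In the reduced gauge the uniform-lattice
#'   transition sits at \code{dmu = 0}.
#' @param du1,du2 Relative affinities \eqn{\Delta U^{[m]}} of the two
#'   segments (same units as \code{dmu}).
#' @param sweeps Total sweeps (one sweep = L^2 flip attempts).
#' @param burnin Sweeps discarded before measuring; \code{burnin <
#'   sweeps}.
#' @param stride Sweeps between measurements.
#' @param seed Integer seed of the simulator's own xorshift64* stream;
#'   identical seed and parameters give a bit-identical trajectory.
#' @param init Initial configuration: \code{"random"}, \code{"all_a"} or
#'   \code{"all_b"}.
#' @param interaction Optional \code{\link{interaction_params}} for the
#'   raw-energy parametrization.
#' @return Object of class \code{"mc_params"} with per-\eqn{k_B T}
#'   fields \code{uaa}, \code{uab}, \code{ubb}, \code{dmu}, \code{du1},
#'   \code{du2} plus the run controls.
#' @export
mc_params <- function(tbar = 2, dmu = 0, du1 = 0, du2 = 0,
                      sweeps = 2000L, burnin = 200L, stride = 1L,
                      seed = 12345L,
                      init = c("random", "all_a", "all_b"),
                      interaction = NULL) {
  init <- match.arg(init)
  sweeps <- as.integer(sweeps); burnin <- as.integer(burnin)
  stride <- as.integer(stride); seed <- as.integer(seed)
  stopifnot(sweeps > 0, burnin >= 0, sweeps > burnin, stride >= 1)
  if (!is.null(interaction)) {
    stopifnot(inherits(interaction, "interaction_params"))
    kBT <- interaction$kBT
    pars <- list(uaa = interaction$Uaa / kBT, uab = interaction$Uab / kBT,
                 ubb = interaction$Ubb / kBT, dmu = dmu / kBT,
                 du1 = du1 / kBT, du2 = du2 / kBT,
                 tbar = interaction$tbar)
  } else {
    stopifnot(is.finite(tbar), tbar > 0)
    # symmetric gauge: Uaa = Ubb = 0, Uab = 2J  =>  Uab/kBT = 2/Tbar
    pars <- list(uaa = 0, uab = 2 / tbar, ubb = 0, dmu = dmu,
                 du1 = du1, du2 = du2, tbar = tbar)
  }
  structure(c(pars, list(sweeps = sweeps, burnin = burnin,
                         stride = stride, seed = seed, init = init)),
            class = "mc_params")
}

# per-site field term (dU[m] - dmu) by segment, per kBT
.field_by_segment <- function(params) {
  c(params$du1 - params$dmu, params$du2 - params$dmu)
}

# bond energy per kBT for occupations a, b (vectorized)
.bond_energy <- function(a, b, params) {
  params$uaa * a * b + params$uab * (a + b - 2 * a * b) +
    params$ubb * (1 - a) * (1 - b)
}

#' Total reduced configurational energy of a lattice configuration
#'
#' Sums the nearest-neighbor pair energies within (and, when enabled,
#' across) the two sublattices and the per-site environment field
#' \eqn{(\Delta U^{[m]} - \Delta\mu) n_i}, all in units of \eqn{k_B T}.
#'
#' @param config L x L matrix of occupation numbers (1 = a-molecule,
#'   0 = b-molecule); columns index the segment direction.
#' @param spec A \code{\link{lattice_spec}}.
#' @param params An \code{\link{mc_params}}.
#' @return Total energy per \eqn{k_B T} (scalar).
#' @export
lattice_energy <- function(config, spec, params) {
  stopifnot(inherits(spec, "lattice_spec"), inherits(params, "mc_params"))
  L <- spec$L
  if (!is.matrix(config) || any(dim(config) != L))
    stop("config must be an L x L matrix")
  if (!all(config %in% c(0, 1))) stop("config must contain only 0/1")
  right <- config[, c(seq_len(L)[-1], 1), drop = FALSE]
  down <- config[c(seq_len(L)[-1], 1), , drop = FALSE]
  e_right <- .bond_energy(config, right, params)
  e_down <- .bond_energy(config, down, params)
  if (!spec$cross_boundary && spec$c > 0 && spec$c < L) {
    seg <- ifelse(seq_len(L) <= spec$c, 1L, 2L)
    segr <- seg[c(seq_len(L)[-1], 1)]
    e_right[, seg != segr] <- 0
  }
  field <- .field_by_segment(params)
  seg <- ifelse(seq_len(L) <= spec$c, 1L, 2L)
  # column-major: each column of config sits in one segment
  e_field <- sum(config * rep(field[seg], each = L))
  sum(e_right) + sum(e_down) + e_field
}

#' Exact semi-grand-canonical averages by enumeration
#'
#' Brute-force partition sum over all \eqn{2^N} configurations of a
#' lattice with at most 16 sites, with log-sum-exp stabilization.  The
#' reference oracle for \code{\link{metropolis_run}}.
#'
#' @inheritParams lattice_energy
#' @return List with \code{n1_mean}, \code{n2_mean} (exact mean
#'   occupations per segment; \code{NA} for an empty segment),
#'   \code{n_mean} (overall), \code{e_mean} (mean energy per site, per
#'   \eqn{k_B T}) and \code{logZ}.
#' @export
enumerate_exact <- function(spec, params) {
  stopifnot(inherits(spec, "lattice_spec"), inherits(params, "mc_params"))
  L <- spec$L
  N <- L * L
  if (N > 16) stop("enumeration limited to lattices with <= 16 sites")
  nstates <- 2^N
  states <- 0:(nstates - 1)
  # occupancy matrix: nstates x N, site id = row + (col-1)*L
  occ <- vapply(seq_len(N) - 1L,
                function(bit) bitwAnd(bitwShiftR(states, bit), 1L),
                integer(nstates))
  storage.mode(occ) <- "double"
  seg_of_col <- ifelse(seq_len(L) <= spec$c, 1L, 2L)
  site_seg <- rep(seg_of_col, each = L)
  # energies over all states
  E <- numeric(nstates)
  for (col in seq_len(L)) {
    for (row in seq_len(L)) {
      i <- row + (col - 1L) * L
      # right and down bonds from site i (each bond counted once)
      jr <- row + (col %% L) * L
      jd <- (row %% L) + 1L + (col - 1L) * L
      keep_r <- spec$cross_boundary || site_seg[i] == site_seg[jr]
      if (keep_r) E <- E + .bond_energy(occ[, i], occ[, jr], params)
      E <- E + .bond_energy(occ[, i], occ[, jd], params)
    }
  }
  field <- .field_by_segment(params)
  E <- E + occ %*% (field[site_seg])
  E <- as.numeric(E)
  # log-sum-exp
  m <- min(E)
  w <- exp(-(E - m))
  Z <- sum(w)
  logZ <- log(Z) - m
  avg <- function(cols) {
    if (length(cols) == 0) return(NA_real_)
    sum(w * rowMeans(occ[, cols, drop = FALSE])) / Z
  }
  list(n1_mean = avg(which(site_seg == 1L)),
       n2_mean = avg(which(site_seg == 2L)),
       n_mean = avg(seq_len(N)),
       e_mean = sum(w * E) / Z / N,
       logZ = logZ)
}

#' Metropolis Monte Carlo run
#'
#' Single-site species flips with Metropolis acceptance on the
#' two-sublattice Hamiltonian; deterministic for a given seed (own
#' xorshift64* stream, independent of R's RNG).  Standard errors are
#' blocked: the post-burn-in measurements are split into up to 32
#' blocks and the block means treated as independent.
#'
#' @inheritParams lattice_energy
#' @return Object of class \code{"mc_result"}: list with per-segment
#'   mean occupations and blocked standard errors (\code{n1_mean},
#'   \code{n1_se}, \code{n2_mean}, \code{n2_se}), overall \code{n_mean}
#'   and \code{m_mean} (order parameter \eqn{\langle 2n - 1 \rangle}),
#'   \code{e_mean} (energy per site), \code{acceptance},
#'   \code{n_measurements}, \code{n_blocks}, and the final
#'   configuration \code{config}.
#' @examples
#' sp <- lattice_spec(8, c = 4)
#' pp <- mc_params(tbar = 100, sweeps = 500, burnin = 100, seed = 1)
#' metropolis_run(sp, pp)$n_mean  # ~0.5 in the entropy-dominated limit
#' @export
metropolis_run <- function(spec, params) {
  stopifnot(inherits(spec, "lattice_spec"), inherits(params, "mc_params"))
  init_code <- match(params$init, c("all_b", "all_a", "random")) - 1L
  res <- mc_run_cpp(spec$L, spec$c, spec$cross_boundary,
                    params$uaa, params$uab, params$ubb,
                    params$dmu, params$du1, params$du2,
                    params$sweeps, params$burnin, params$stride,
                    params$seed, init_code)
  blocked <- function(x) {
    M <- length(x)
    if (M == 0) return(c(NA_real_, NA_real_, 0))
    nb <- min(32L, M)
    bl <- floor(M / nb)
    use <- x[seq_len(nb * bl)]
    bm <- colMeans(matrix(use, nrow = bl))
    se <- if (nb > 1) sd(bm) / sqrt(nb) else NA_real_
    c(mean(use), se, nb)
  }
  s1 <- blocked(res$n1_series)
  s2 <- blocked(res$n2_series)
  sa <- blocked(res$n_series)
  se_ <- blocked(res$e_series)
  structure(list(
    n1_mean = if (spec$n1 > 0) s1[1] else NA_real_,
    n1_se = if (spec$n1 > 0) s1[2] else NA_real_,
    n2_mean = if (spec$n2 > 0) s2[1] else NA_real_,
    n2_se = if (spec$n2 > 0) s2[2] else NA_real_,
    n_mean = sa[1], n_se = sa[2],
    m_mean = 2 * sa[1] - 1, m_se = 2 * sa[2],
    e_mean = se_[1], e_se = se_[2],
    acceptance = res$acceptance,
    n_measurements = length(res$n_series),
    n_blocks = sa[3],
    config = matrix(res$config, nrow = spec$L),
    spec = spec, params = params
  ), class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("MC result (L = %d, c = %d, Tbar = %g, seed = %d)\n",
              x$spec$L, x$spec$c, x$params$tbar, x$params$seed))
  cat(sprintf("  <n>1 = %s +- %s, <n>2 = %s +- %s\n",
              format(x$n1_mean), format(x$n1_se),
              format(x$n2_mean), format(x$n2_se)))
  cat(sprintf("  <2n-1> = %.5f, <e>/site = %.5f, acceptance = %.3f\n",
              x$m_mean, x$e_mean, x$acceptance))
  invisible(x)
}
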