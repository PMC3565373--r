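test_that("spectator fraction sits on the branch selected by the contrast", {
  eos <- membrane_eos("meanfield", tbar = 2)
  b <- eos$binodals
  # segment 1 separating: spectator (segment 2) a-poor for positive contrast
  x <- spectator_fraction(1, 1, eos)
  expect_gt(x, 0); expect_lt(x, b$x_beta)
  expect_lt(abs(mf_deltaG(x, 2, flatten = FALSE) + 1), 1e-10)
  # ... and a-rich for negative contrast
  x <- spectator_fraction(1, -1, eos)
  expect_gt(x, b$x_alpha); expect_lt(x, 1)
  # segment 2 separating at contrast -1: spectator (segment 1) a-poor
  x <- spectator_fraction(2, -1, eos)
  expect_gt(x, 0); expect_lt(x, b$x_beta)
  expect_lt(abs(mf_deltaG(x, 2, flatten = FALSE) + 1), 1e-10)

  expect_error(spectator_fraction(1, 0, eos), "degenerate")
  expect_error(
    spectator_fraction(1, 1, membrane_eos("meanfield", tbar = 5)),
    "critical")
})

test_that("exact-limit spectator fractions are the documented limits", {
  eos <- membrane_eos("exact-limit", tbar = 2)
  b <- eos$binodals
  # segment 1 separating
  expect_equal(spectator_fraction(1, 1, eos, "small"), b$x_beta)
  expect_equal(spectator_fraction(1, 1, eos, "large"), 0)
  expect_equal(spectator_fraction(1, -1, eos, "small"), b$x_alpha)
  expect_equal(spectator_fraction(1, -1, eos, "large"), 1)
  # segment 2 separating
  expect_equal(spectator_fraction(2, 1, eos, "small"), b$x_alpha)
  expect_equal(spectator_fraction(2, 1, eos, "large"), 1)
  expect_equal(spectator_fraction(2, -1, eos, "small"), b$x_beta)
  expect_equal(spectator_fraction(2, -1, eos, "large"), 0)
})

test_that("spectator fraction decreases in the contrast and jumps at zero", {
  eos <- membrane_eos("meanfield", tbar = 2)
  b <- eos$binodals
  neg <- sapply(c(-4, -2, -1, -0.5, -0.1), function(d)
    spectator_fraction(1, d, eos))
  pos <- sapply(c(0.1, 0.5, 1, 2, 4), function(d)
    spectator_fraction(1, d, eos))
  # strictly decreasing on each sign branch as the contrast increases
  expect_true(all(diff(neg) < 0))
  expect_true(all(diff(pos) < 0))
  # limits at vanishing contrast: the two binodals, with a jump across 0
  expect_equal(spectator_fraction(1, -1e-6, eos), b$x_alpha,
               tolerance = 1e-4)
  expect_equal(spectator_fraction(1, 1e-6, eos), b$x_beta,
               tolerance = 1e-4)
  # large-contrast saturation
  expect_lt(spectator_fraction(1, 50, eos), 1e-10)
  expect_gt(spectator_fraction(1, -50, eos), 1 - 1e-10)
})

test_that("zero contrast gives whole-membrane behavior", {
  eos <- membrane_eos("exact-limit", tbar = 2)
  st <- solve_state(0.5, q1 = 0.7, du21 = 0, eos)
  expect_equal(st$Xa1, 0.5)
  expect_equal(st$Xa2, 0.5)
  expect_equal(st$phase, "coex_segment_1")
  expect_true(st$whole_membrane)
  # outside the binodal interval: a single uniform phase
  st2 <- solve_state(0.01, q1 = 0.7, du21 = 0, eos)
  expect_equal(st2$phase, "one_phase")
  expect_equal(st2$Xa1, 0.01)
})

test_that("exact-limit lever arithmetic matches the saturated spectator", {
  eos <- membrane_eos("exact-limit", tbar = 2)
  st <- solve_state(0.3, q1 = 0.7, du21 = 50, eos, regime = "large")
  expect_equal(st$phase, "coex_segment_1")
  expect_equal(st$Xa2, 0)
  expect_equal(st$Xa1, 0.3 / 0.7)
  expect_true(st$Xa1 >= eos$binodals$x_beta &&
                st$Xa1 <= eos$binodals$x_alpha)
  # overall composition beyond the segment-1 window: segment 2 coexists
  st2 <- solve_state(0.8, q1 = 0.7, du21 = 50, eos, regime = "large")
  expect_equal(st2$phase, "coex_segment_2")
  expect_equal(st2$Xa1, 1)
  expect_equal(st2$Xa2, (0.8 - 0.7) / 0.3)
})

test_that("mean-field solver meets both residual contracts everywhere", {
  eos <- membrane_eos("meanfield", tbar = 2)
  set.seed(31)
  for (k in 1:60) {
    Xa <- runif(1, 0.02, 0.98)
    q1 <- runif(1)
    du21 <- runif(1, -3, 3)
    st <- solve_state(Xa, q1, du21, eos)
    expect_lt(abs(lever_residual(st)), 1e-10)
    if (st$phase == "one_phase") {
      resid <- mf_deltaG(st$Xa1, 2) - mf_deltaG(st$Xa2, 2) - du21
      expect_lt(abs(resid), 1e-8)
    } else if (st$phase == "coex_segment_1") {
      expect_true(st$Xa1 >= eos$binodals$x_beta - 1e-12 &&
                    st$Xa1 <= eos$binodals$x_alpha + 1e-12)
    } else {
      expect_true(st$Xa2 >= eos$binodals$x_beta - 1e-12 &&
                    st$Xa2 <= eos$binodals$x_alpha + 1e-12)
    }
  }
})

test_that("solutions mirror under contrast sign flip and relabeling", {
  eos <- membrane_eos("meanfield", tbar = 2.5)
  set.seed(32)
  for (k in 1:25) {
    Xa <- runif(1, 0.05, 0.95)
    q1 <- runif(1, 0.05, 0.95)
    du21 <- runif(1, -2, 2)
    a <- solve_state(Xa, q1, du21, eos)
    bb <- solve_state(1 - Xa, q1, -du21, eos)
    # a <-> b relabeling maps compositions X -> 1 - X segmentwise
    expect_equal(a$Xa1, 1 - bb$Xa1, tolerance = 1e-8)
    expect_equal(a$Xa2, 1 - bb$Xa2, tolerance = 1e-8)
    swap <- c(one_phase = "one_phase", coex_segment_1 = "coex_segment_1",
              coex_segment_2 = "coex_segment_2")
    expect_equal(a$phase, unname(swap[bb$phase]))
  }
})

test_that("area-fraction limits reduce to the uni-env problem", {
  eos <- membrane_eos("meanfield", tbar = 2)
  b <- eos$binodals
  st <- solve_state(0.5, q1 = 1, du21 = 1.5, eos)
  expect_equal(st$phase, "coex_segment_1")
  expect_equal(st$Xa1, 0.5)
  st0 <- solve_state(0.5, q1 = 0, du21 = 1.5, eos)
  expect_equal(st0$phase, "coex_segment_2")
  expect_equal(st0$Xa2, 0.5)
  # one-phase at the limits still reports both compositions (ghost segment)
  st1 <- solve_state(0.005, q1 = 1, du21 = 1.5, eos)
  expect_equal(st1$phase, "one_phase")
  expect_equal(st1$Xa1, 0.005)
  expect_true(is.finite(st1$Xa2))
})

test_that("invalid inputs are rejected", {
  eos <- membrane_eos("meanfield", tbar = 2)
  expect_error(solve_state(NA, 0.5, 1, eos), "finite")
  expect_error(solve_state(1.5, 0.5, 1, eos), "Xa")
  expect_error(solve_state(0.5, -0.1, 1, eos), "q1")
})
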