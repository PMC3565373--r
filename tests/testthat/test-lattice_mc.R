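test_that("lattice energy counts bonds and fields as in the Hamiltonian", {
  ip <- interaction_params(Uaa = -1, Uab = 0.5, Ubb = -0.5, kBT = 1)
  pars <- mc_params(interaction = ip, dmu = 0.3, du1 = 0, du2 = -2)
  sp <- lattice_spec(4, c = 2)
  L <- 4

  # all-b configuration: every bond contributes Ubb, fields vanish
  conf <- matrix(0, L, L)
  expect_equal(lattice_energy(conf, sp, pars), 2 * L * L * ip$Ubb)

  # single a-site flipped in the all-b background: 4 bonds change
  # b-b -> a-b and the site picks up its field term
  for (col in c(1, 3)) {                 # one site per segment
    conf1 <- conf; conf1[2, col] <- 1
    dU <- if (col <= sp$c) 0 else -2
    dE <- 4 * (ip$Uab - ip$Ubb) + (dU - 0.3)
    expect_equal(lattice_energy(conf1, sp, pars) -
                   lattice_energy(conf, sp, pars), dE)
  }

  # translation invariance on the uniform lattice (c = 0)
  spu <- lattice_spec(4, c = 0)
  set.seed(51)
  conf <- matrix(rbinom(16, 1, 0.5), 4, 4)
  shifted <- conf[c(2:4, 1), c(2:4, 1)]
  expect_equal(lattice_energy(conf, spu, pars),
               lattice_energy(shifted, spu, pars))

  expect_error(lattice_energy(matrix(0, 3, 3), sp, pars), "L x L")
  expect_error(lattice_energy(matrix(2, 4, 4), sp, pars), "0/1")
})

test_that("excluding cross-boundary bonds removes exactly the strip seams", {
  ip <- interaction_params(Uaa = 0, Uab = 1, Ubb = 0)
  pars <- mc_params(interaction = ip)
  sp_in <- lattice_spec(4, c = 2, cross_boundary = TRUE)
  sp_ex <- lattice_spec(4, c = 2, cross_boundary = FALSE)
  # alternate columns a/b so every cross-seam bond is an a-b contact
  conf <- matrix(rep(c(1, 1, 0, 0), each = 4), 4, 4)
  # two seams (at the split and at the periodic wrap), L bonds each
  expect_equal(lattice_energy(conf, sp_in, pars) -
                 lattice_energy(conf, sp_ex, pars), 2 * 4 * 1)
})

test_that("exact enumeration reproduces entropy- and field-dominated limits", {
  sp <- lattice_spec(2, c = 0)
  # entropy-dominated: equal occupation
  ex <- enumerate_exact(sp, mc_params(tbar = 1e6))
  expect_equal(ex$n_mean, 0.5, tolerance = 1e-5)
  # strong positive relative chemical potential: all a
  ex <- enumerate_exact(sp, mc_params(tbar = 2, dmu = 50))
  expect_equal(ex$n_mean, 1, tolerance = 1e-10)
  expect_true(is.na(ex$n1_mean))  # empty segment 1
  ex <- enumerate_exact(sp, mc_params(tbar = 2, dmu = -50))
  expect_equal(ex$n_mean, 0, tolerance = 1e-10)
  expect_error(enumerate_exact(lattice_spec(5, 0), mc_params()),
               "16 sites")
})

test_that("a sticky segment environment enriches its preferred species", {
  # negative dU2 lowers the energy of a-molecules in segment 2
  sp <- lattice_spec(3, c = 1)
  pars <- mc_params(tbar = 2, dmu = 0, du1 = 0, du2 = -2)
  ex <- enumerate_exact(sp, pars)
  expect_gt(ex$n2_mean, ex$n1_mean)
})

test_that("enumeration obeys particle-hole duality exactly", {
  sp <- lattice_spec(3, c = 2)
  set.seed(52)
  for (k in 1:5) {
    tbar <- runif(1, 1, 4)
    dmu <- runif(1, -1, 1)
    du1 <- runif(1, -1, 1)
    du2 <- runif(1, -1, 1)
    a <- enumerate_exact(sp, mc_params(tbar, dmu, du1, du2))
    # relabel a <-> b: in the symmetric gauge mu_alphabeta = 0, the dual
    # has dmu -> -dmu and dU[m] -> -dU[m]
    b <- enumerate_exact(sp, mc_params(tbar, -dmu, -du1, -du2))
    expect_lt(abs(a$n1_mean - (1 - b$n1_mean)), 1e-10)
    expect_lt(abs(a$n2_mean - (1 - b$n2_mean)), 1e-10)
  }
})

test_that("segment transitions shift with the relative affinity", {
  # uniform lattice, single nonzero dU: at dmu = mu_alphabeta + dU the
  # Hamiltonian is particle-hole symmetric, pinning <n> = 1/2 exactly
  sp <- lattice_spec(4, c = 0)   # all of the lattice is segment 2
  du <- 0.8
  ex <- enumerate_exact(sp, mc_params(tbar = 2, dmu = du, du2 = du))
  expect_equal(ex$n_mean, 0.5, tolerance = 1e-12)
  above <- enumerate_exact(sp, mc_params(tbar = 2, dmu = du + 0.2,
                                         du2 = du))
  below <- enumerate_exact(sp, mc_params(tbar = 2, dmu = du - 0.2,
                                         du2 = du))
  expect_gt(above$n_mean, 0.5)
  expect_lt(below$n_mean, 0.5)

  # MC on a larger lattice: the order parameter changes sign across the
  # shifted transition at Tbar = 2
  spL <- lattice_spec(16, c = 0)
  hi <- metropolis_run(spL, mc_params(tbar = 2, dmu = du + 0.5, du2 = du,
                                      sweeps = 2000, burnin = 500,
                                      seed = 3))
  lo <- metropolis_run(spL, mc_params(tbar = 2, dmu = du - 0.5, du2 = du,
                                      sweeps = 2000, burnin = 500,
                                      seed = 3))
  expect_gt(hi$m_mean, 0.5)
  expect_lt(lo$m_mean, -0.5)
})

test_that("Metropolis runs are seed-reproducible and entropy-correct", {
  sp <- lattice_spec(8, c = 4)
  pars <- mc_params(tbar = 100, sweeps = 2000, burnin = 200, seed = 99)
  r1 <- metropolis_run(sp, pars)
  r2 <- metropolis_run(sp, pars)
  expect_identical(r1$n_mean, r2$n_mean)
  expect_identical(r1$e_mean, r2$e_mean)
  expect_identical(r1$config, r2$config)
  # different seed, different trajectory
  r3 <- metropolis_run(sp, mc_params(tbar = 100, sweeps = 2000,
                                     burnin = 200, seed = 100))
  expect_false(identical(r1$n_mean, r3$n_mean))
  # entropy-dominated limit
  expect_lt(abs(r1$n_mean - 0.5), 3 * r1$n_se)
  expect_gt(r1$acceptance, 0.9)
})

test_that("Metropolis means match exact enumeration on a tiny lattice", {
  sp <- lattice_spec(3, c = 1)
  pars <- mc_params(tbar = 2.5, dmu = 0.2, du1 = 0.3, du2 = -0.7,
                    sweeps = 20000, burnin = 2000, seed = 7)
  ex <- enumerate_exact(sp, pars)
  mc <- metropolis_run(sp, pars)
  expect_lt(abs(mc$n1_mean - ex$n1_mean), 3 * mc$n1_se)
  expect_lt(abs(mc$n2_mean - ex$n2_mean), 3 * mc$n2_se)
  expect_lt(abs(mc$e_mean - ex$e_mean), 5 * mc$e_se)
})

test_that("run-parameter validation catches inconsistent controls", {
  expect_error(mc_params(sweeps = 0), "sweeps")
  expect_error(mc_params(sweeps = 100, burnin = 100))
  expect_error(mc_params(tbar = -1), "tbar")
})
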