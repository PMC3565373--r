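---
title: "Adhesion-induced phase behavior of two-component membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adhesion-induced phase behavior of two-component membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memphase)
```

## The physical problem

A two-component fluid membrane -- think of a cholesterol/phospholipid
bilayer that can demix into liquid-ordered (alpha, cholesterol-rich) and
liquid-disordered (beta, cholesterol-poor) phases -- changes its phase
behavior when it adheres to a surface.  Adhesion splits the membrane
into two segments: an unbound segment S1 and a bound segment S2 (for a
vesicle on a substrate), or a pore-spanning and a supported segment (for
solid-supported membranes).  The two environments interact differently
with the two lipid species, and this *affinity contrast* reorganizes the
phase diagram: the single coexistence region of the uniform-environment
("uni-env") membrane splits into **two** coexistence regions -- one per
segment -- separated by an intermediate one-phase region in which
demixing is suppressed altogether.

`memphase` implements this lattice theory end to end: exact and
mean-field thermodynamic backends, the coupled equilibrium solver for
the two segments, phase-diagram construction, the spherical-cap
adhesion geometry, and a Monte Carlo simulator that validates the
analytic results.

## The lattice model

The membrane is discretized on a square lattice (coordination number
z = 4, fixed); each site carries one molecule, `n_i = 1` for an
a-molecule, `n_i = 0` for a b-molecule.  Nearest neighbors interact
with energies `Uaa`, `Uab`, `Ubb`.  Because the total number of sites
is fixed, inserting an a-molecule removes a b-molecule: the natural
ensemble is semi-grand canonical, controlled by the relative chemical
potential `dmu = mu_a - mu_b`.

The model is equivalent to the 2D Ising model with two dimensionless
parameters,

* reduced temperature `Tbar = kBT / J` with coupling
  `J = (2 Uab - Uaa - Ubb) / 4` (a demixing transition requires
  `J > 0`), and
* ordering field `Hbar = [dmu/2 - (Uaa - Ubb)] / kBT`.

At `Hbar = 0`, i.e. at the transition chemical potential
`mu_alphabeta = 2 (Uaa - Ubb)`, the mixture demixes for
`Tbar < Tbar_c = 2 / ln(1 + sqrt(2)) = 2.269`.  The coexisting
compositions are set by the exact spontaneous order parameter

```
Upsilon(Tbar) = [1 - sinh(2/Tbar)^-4]^(1/8),
x_beta = 1/2 - Upsilon/2,   x_alpha = 1/2 + Upsilon/2.
```

```{r}
ising_tc()
exact_binodals(2.0)
```

Each adhering segment S[m] adds a per-site field
`(dU[m] - dmu) n_i`, where the relative affinity
`dU[m] = Ua[m] - Ub[m]` compares how strongly the environment attracts
the two species (attractive potentials are negative; an unbound segment
has `dU = 0`).  A segment therefore undergoes its transition at the
*shifted* chemical potential `mu_alphabeta + dU[m]`: two segments with
different affinities have two distinct transitions.  Only the
*affinity contrast* `dU21 = dU[2] - dU[1]` matters for the coupled
equilibrium.

## Two thermodynamic backends

Composition is the experimental control variable, so the theory needs
the equation of state `dmu = G(X)`; we work with the shifted, reduced
form `dG(X) = [G(X) - mu_alphabeta] / kBT`, which vanishes on the
coexistence interval and increases strictly outside it.

* **exact-limit**: the 2D Ising model has no closed-form equation of
  state in a finite field, so this backend knows `dG` only on
  coexistence.  Off-coexistence spectator compositions are taken in the
  two limits the theory pins down exactly: for *small* contrast the
  spectator sits at the adjacent binodal, for *large* contrast it
  saturates at 0 or 1.  Which limit applies is an explicit `regime`
  flag, not a numeric threshold, because the theory provides only the
  asymptotic statements.
* **meanfield**: the Bragg--Williams closure of the same Hamiltonian.
  Differentiating the per-site free energy
  `f = kBT [X ln X + (1-X) ln(1-X)] + (z/2)[Uaa X^2 + 2 Uab X(1-X) +
  Ubb (1-X)^2]` gives, after subtracting `mu_alphabeta`,

  ```
  dG(X) = ln(X/(1-X)) - (2z/Tbar)(2X - 1),
  ```

  which reproduces `G(1/2) = mu_alphabeta` exactly and has its critical
  point at `Tbar_c^mf = z = 4`.  The van der Waals loop is
  Maxwell-flattened (by odd symmetry the equal-area rule reduces to the
  outer zeros of the loop), making `dG` globally non-decreasing as
  thermodynamic stability requires.

Temperatures in diagrams are always normalized by each backend's *own*
critical temperature; mixing the two normalizations would misalign the
backends.

## Segment equilibrium and phase diagrams

Two relations close the problem at overall composition `Xa`, area
fraction `q1` and contrast `dU21` (per kBT):

```
q1 * Xa1 + (1 - q1) * Xa2 = Xa        (lever rule / partitioning)
dG(Xa1) = dG(Xa2) + dU21              (chemical equilibrium)
```

If one segment phase separates, its `dG` is pinned to zero and the
other segment becomes a uniform *spectator* phase with
`dG(x) = -dU21` (segment 1 separating) or `+dU21` (segment 2
separating).  Inserting the binodal interval and the spectator value
into the lever rule maps each segment's coexistence region into overall
composition; `solve_state()` classifies any `(Xa, q1, dU21)` point and
`build_diagram()` assembles the full `(Xa, T/Tc)` diagram:

```{r}
eos <- membrane_eos("exact-limit", t_over_tc = 0.88)
solve_state(0.3, q1 = 0.7, du21 = 50, eos, regime = "large")
pd <- build_diagram(seq(0.3, 1, length.out = 40), q1 = 0.7, du21 = 50,
                    backend = "exact-limit", regime = "large")
head(as.data.frame(pd), 3)
```

Structural properties the implementation asserts rather than assumes:
the two windows have disjoint interiors for any nonzero contrast (in
the exact small-contrast *limit* the intermediate one-phase gap
collapses to a shared endpoint -- its width is first order in the
contrast); the windows are closed intervals, with boundary points
classified as coexistence; at `dU21 = 0` the whole membrane coexists
over the uni-env window; and solutions map onto themselves under the
relabeling `(dU21, Xa) -> (-dU21, 1 - Xa)` with `X -> 1 - X`.

Under the exact-limit backend the one-phase segment compositions are
reported as `NA`: without an off-coexistence equation of state they are
genuinely undetermined, and fabricating them would misrepresent the
backend.  The mean-field backend solves the full two-equation system.

## Adhesion geometry

In the strong-adhesion regime a vesicle is a spherical cap with
effective contact angle `theta_eff`.  From the cap formulas
`A1 = 2 pi R^2 (1 - cos theta)`, `A2 = pi (R sin theta)^2` and
`V = (pi/3) h^2 (3R - h)` with `h = R (1 - cos theta)` follow

* `q1 = 2 / (3 + cos theta)`, increasing from 1/2 (flat pancake)
  through 2/3 (hemisphere) to 1 (free sphere), and
* the reduced volume `v = 3V/(4 pi) / (A/4 pi)^{3/2}`, strictly
  increasing in `theta`, so `v` determines `q1` uniquely
  (`q1_from_reduced_volume()` inverts it numerically).

Strong adhesion itself is quantified by the contact curvature radius
`Rco = sqrt(kappa / 2|W|)`; the regime requires `Rco` much below the
vesicle scale, encoded as `|W| >= factor * 2 pi kappa / A` with a
configurable separation factor (default 10).  For optical microscopy
(`Lstar = 0.5 um`) and `kappa = 1e-19 J` the threshold adhesion
strength is `|W|* = kappa / (2 Lstar^2) = 2e-4 mJ/m^2`, about
`0.5 kBT / (100 nm)^2` at 25 C (fixed at `To = 298.15 K` for all
thermal conversions).

```{r}
cap_geometry(pi / 2)
strong_adhesion_threshold(1e-19, 0.5e-6) * 1e3  # mJ/m^2
```

## Monte Carlo validation

`metropolis_run()` simulates the two-sublattice Hamiltonian directly:
an `L x L` periodic lattice split into column strips (`q1 = c/L`,
restricted to multiples of `1/L`), single-site species flips accepted
with `min(1, exp(-dE/kBT))`.  Design choices:

* **Cross-boundary bonds are included by default** -- the membrane is
  physically contiguous, so the simulation necessarily contains the
  domain-boundary energy that the analytic large-membrane limit drops.
  A flag excludes them to mimic fully decoupled segments.  This is a
  finite-size effect of order (boundary length)/(segment area).
* **Reduced gauge.** Given only `(Tbar, dmu/kBT, dU/kBT)` the pair
  energies are fixed to `Uaa = Ubb = 0`, `Uab = 2J`, which leaves `J`
  and `Tbar` unchanged and puts `mu_alphabeta = 0`, `Hbar = dmu/2`.
  Raw energies are also accepted.
* **Determinism.** The simulator carries its own xorshift64* stream;
  identical seed and parameters give a bit-identical trajectory,
  independent of R's RNG state.  Standard errors are blocked (up to 32
  blocks of consecutive measurements).
* **Initialization** is `random`, `all_a` or `all_b`; ordered starts
  are the right choice when measuring a spontaneously broken state.

Two oracles validate the simulator.  First, `enumerate_exact()`
computes the exact semi-grand partition sum for lattices of up to 16
sites (log-sum-exp stabilized); MC means must agree within blocked
standard errors, across temperatures, fields and affinities.  Deep in
the ordered regime a tiny lattice is effectively a two-state system
whose basins exchange rarely under single-site flips, so those
comparisons use run lengths scaled to the basin-hopping time (millions
of sweeps -- still fractions of a second at 9 sites).  Second, on a
uniform `64 x 64` lattice at `Tbar = 2.0` the simulated order parameter
`<2n - 1>` must reproduce the closed-form `Upsilon(2.0) = 0.9113`.
This is measured in the `Hbar -> 0+` prescription: a weak
branch-selecting field `Hbar = 0.001` from an ordered start.  A
stronger field (e.g. `Hbar = 0.01`) visibly biases the magnetization by
`chi * Hbar`, which at this temperature exceeds the statistical
resolution of a few-thousand-sweep run -- the standard weak-field
caveat of spontaneous-magnetization measurements.

Problem sizes used in the shipped test suite: enumeration oracles on
2x2 and 3x3 lattices; MC/oracle cross-checks on a 12-point parameter
grid; the Onsager check on `L = 64` with 6400 sweeps.  These sizes make
the suite complete in well under a minute while leaving every
comparison statistically meaningful.

## Numerical choices

* Root searches run on strictly monotone branches with guaranteed
  brackets; compositions are solved in log-odds (logit) space so that
  spectator fractions exponentially close to 0 or 1 (large contrasts,
  low temperatures) retain full relative precision.
* Solver tolerances: 1e-12 in the root variable, epsilon margins 1e-9
  at the composition interval ends; lever-rule residuals are exact by
  construction, chemical-equilibrium residuals below 1e-8.
* `Upsilon` evaluates `1 - sinh(2/Tbar)^-4` via `expm1` to avoid
  cancellation near `Tbar_c`, and is clamped to exactly 0 above
  `Tbar_c` (the closed form would be complex there).
* Mean-field binodals within 1e-8 of the critical point are reported
  as the critical composition 1/2; the window width there is below
  numerical resolution.
* Ties at window boundaries classify as coexistence (closed
  intervals).

## Limitations

* The analytic backends describe infinite, homogeneous segments: no
  domain-boundary tension, no metastability or spinodals, no
  finite-size shifts of the coexistence windows.  The MC module is the
  only place where finite-size and boundary effects appear.
* The exact-limit backend cannot produce one-phase segment
  compositions or finite-contrast spectator values; those require the
  mean-field backend.
* Both lipid species occupy the same molecular area (one lattice
  constant); unequal areas, triangular lattices, more than two
  components or more than two environments are out of scope.
* The spherical-cap geometry idealizes the contact line as sharp; the
  smoothly curved contact zone of a real vesicle is below the
  resolution this geometry targets.
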