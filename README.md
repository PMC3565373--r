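# memphase

Phase behavior of two-component lipid membranes segmented by adhesion.

## The problem

A two-component fluid membrane — e.g. a cholesterol/phospholipid
bilayer that demixes into liquid-ordered (α) and liquid-disordered (β)
phases — is split by adhesion into two segments exposed to different
environments: the unbound cap S1 and the bound contact zone S2 of an
adhering vesicle, or the pore-spanning and supported parts of a
solid-supported membrane. The environments attract the two lipid
species differently, and this *affinity contrast* reshapes the phase
diagram: the single coexistence region of the membrane in a uniform
environment splits into two coexistence regions — one per segment —
separated by an intermediate one-phase region where demixing is
suppressed. `memphase` implements the underlying lattice theory and a
Monte Carlo simulator that validates it, for membrane biophysicists who
want quantitative phase diagrams of adhering membranes and vesicles.

## The model in brief

The membrane is a lattice binary mixture on a square lattice
(occupation `n_i ∈ {0,1}`, nearest-neighbor energies `Uaa, Uab, Ubb`),
equivalent to the 2D Ising model with reduced temperature
`T̄ = kBT/J`, `J = (2Uab − Uaa − Ubb)/4`, and ordering field
`H̄ = [Δμ/2 − (Uaa − Ubb)]/kBT`. The uniform mixture demixes for
`T̄ < T̄c = 2/ln(1+√2) ≈ 2.269` at `Δμ = μαβ = 2(Uaa − Ubb)`, with
binodals `x_{β,α} = 1/2 ∓ Υ(T̄)/2` set by the exact spontaneous order
parameter `Υ = [1 − sinh(2/T̄)^{−4}]^{1/8}`.

Each adhering segment S[m] adds a per-site field
`(ΔU[m] − Δμ) n_i`, where `ΔU[m] = Ua[m] − Ub[m]` is the segment's
relative affinity; its transition shifts to `μαβ + ΔU[m]`. At fixed
overall composition the two segment compositions solve

```
q1·Xa1 + (1−q1)·Xa2 = Xa            (lever rule)
ΔG(Xa1) = ΔG(Xa2) + ΔU21            (chemical equilibrium)
```

with `ΔG(X) = [G(X) − μαβ]/kBT` and the affinity contrast
`ΔU21 = ΔU[2] − ΔU[1]`. When one segment phase separates the other is
a uniform *spectator* phase; projecting the separating segment's
binodal interval through the lever rule yields that segment's
coexistence window in overall composition. Two backends supply
`ΔG`: the exact Ising limit (spectator values at the small/large
contrast limits) and a Bragg–Williams mean-field closure
`ΔG(X) = ln(X/(1−X)) − (2z/T̄)(2X−1)` with `z = 4`.

## Worked example

Classify an adhering vesicle membrane at 88% of the demixing critical
temperature, with 70% of its area unbound (`q1 = 0.7`) and a large
positive affinity contrast (b-molecules strongly recruited to the bound
segment):

```r
library(memphase)

eos <- membrane_eos("exact-limit", t_over_tc = 0.88)
eos
#> Equation of state [exact-limit]: Tbar = 1.99688 (T/Tc = 0.8800)
#>   binodals: x_beta = 0.043830, x_alpha = 0.956170

solve_state(0.3, q1 = 0.7, du21 = 50, eos, regime = "large")
#> Membrane state at Xa = 0.3, q1 = 0.7, dU21/kBT = 50
#>   phase: coex_segment_1
#>   Xa[1] = 0.4285714, Xa[2] = 0
#>   spectator: segment 2 at Xa,* = 0.000000
```

At overall composition `Xa = 0.3` only the unbound segment demixes:
its composition `Xa1 = 0.3/0.7 = 0.4286` lies between the binodals
(0.0438, 0.9562), so it holds coexisting α/β domains, while the bound
segment is a uniform spectator completely depleted of a-molecules
(`Xa2 = 0` in the large-contrast limit). `build_diagram()` repeats
this over a temperature grid and returns both segments' coexistence
windows plus the uni-env reference binodals; `plot()` renders them.

Geometry of a strongly adhering hemispherical vesicle:

```r
cap_geometry(pi / 2)
#> Spherical cap: theta_eff = 1.5708 rad, q1 = 0.666667, v = 0.769800
#>   A1/A = 0.666667, A2/A = 0.333333 (R = 1)
```

Monte Carlo recovery of the exact order parameter on a uniform 64×64
lattice at `T̄ = 2` (weak branch-selecting field, ordered start):

```r
sp <- lattice_spec(64, 0)
pp <- mc_params(tbar = 2, dmu = 0.002, sweeps = 6400, burnin = 400,
                init = "all_a")
metropolis_run(sp, pp)
#> MC result (L = 64, c = 0, Tbar = 2, seed = 12345)
#>   <n>1 = NA +- NA, <n>2 = 0.9556802 +- 0.0003721335
#>   <2n-1> = 0.91136, <e>/site = 0.12485, acceptance = 0.079
spontaneous_order(2)
#> [1] 0.9113194
```

The simulated `⟨2n−1⟩ = 0.91136` agrees with the closed form within
one standard error.

A thin command-line front end covers the same operations
(`binodal`, `diagram`, `classify`, `geometry`, `adhesion`, `mc`,
`fixtures`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "memphase.R", package = "memphase"))')" \
  classify --xa 0.5 --t-over-tc 0.88 --q1 0.7 --du21 0 --backend meanfield
```

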