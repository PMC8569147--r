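# mbpef

Many-body expansions and data-driven potential energy functions (PEFs)
for water, in R.

The package is built for people who study molecular interactions through
the many-body expansion (MBE): the exact rewriting of an N-molecule
cluster's energy as

    E_N = sum_i eps1B(i) + sum_{i<j} eps2B(i,j) + sum_{i<j<k} eps3B(i,j,k) + ...

where `eps1B` is each monomer's distortion energy and every higher term
is the part of a subset's energy not attributable to any proper subset.
On top of the exact decomposition engine it implements the full
"many-body PEF" construction used by modern data-driven water models: a
monomer surface, short-range 2-body and 3-body permutationally invariant
polynomials (PIPs) fitted to reference n-body energies, permanent
electrostatics, damped dispersion, a fixed repulsive core, and
self-consistent induced-dipole polarization supplying all higher orders —
plus a minimal molecular dynamics engine (NVE / Langevin NVT / Monte
Carlo barostat NPT) and the liquid-state observables used to validate
such models (radial distribution functions, Green–Kubo self-diffusion
from the center-of-mass velocity autocorrelation, density curves and the
temperature of maximum density, isothermal compressibility, enthalpy of
vaporization). Density-corrected DFT energy combinators
(`E_DC = E_HF + E_XC[n_HF] - E_X^HF`, functional/density error split)
and benchmark error statistics (MUE, per-molecule errors, distance
binning) round out the toolkit.

Because ab initio reference energies are expensive, the package ships a
deterministic polarizable **toy water backend** (SPC/E-flavored charges
and Lennard-Jones, Thole-screened electrostatics, optional induction
with genuine three-body content). Every stage — decomposition, fitting,
simulation, analysis — is testable end to end against it without any
quantum chemistry.

## Worked example

```r
library(mbpef)

toy <- toy_water_model()          # polarizable reference backend
bk  <- toy_backend(toy)

# exact many-body decomposition of a random hexamer
hex <- sample_clusters(6, 1, seed = 1, r_min = 2.5, r_max = 4.0)[[1]]
dec <- nbody_decompose(hex, bk)
round(dec$order_sums, 4)
#>      1B      2B      3B      4B      5B      6B
#>  4.3023  7.5005  0.2195 -0.0458  0.0018  0.0000
abs(dec$total_reconstructed - toy_energy(hex, toy))
#> [1] 1.78e-15
```

This randomly sampled (not energy-minimized) hexamer is net repulsive,
but the order sums still show the expected hierarchy: monomer distortion
and pair terms of a few kcal/mol, a polarization-driven 3-body
contribution an order of magnitude smaller, and rapidly vanishing higher
orders; the full sum reconstructs the backend energy to machine
precision.

```r
# fit a degree-4 2B PIP to the backend and check held-out accuracy
b2  <- build_pip_basis(2, 4, rin = 3.2, rout = 4.5)
fit <- fit_pip_term(sample_clusters(2, 500, seed = 33, r_min = 2.2, r_max = 5.0),
                    bk, pef_model(), 2, b2)
fit$report
#>      subset  n        mue       rmse
#> 1       all 48 0.07024335 0.29631651
#> 2 |E| <= 25 46 0.02742674 0.06900479
```

A held-out mean unsigned error of ~0.03 kcal/mol on low-energy dimer 2-body
energies is chemical accuracy for this reference. The fitted model can
then drive liquid MD (`pef_force_field()`, `run_simulation()`) and the
observable estimators; the package's acceptance workflow does exactly
that and checks that the fitted PEF reproduces its own reference's NPT
density to within a fraction of a percent.

A thin command-line front end is installed at
`inst/scripts/mbpef` (e.g. `mbpef decompose --xyz hexamer.xyz --backend
toy`, `mbpef md --init box.xyz --model fitted.mbpef --ensemble npt`).

The methods vignette (`vignettes/many-body-pef.Rmd`) documents the
model, its parameters and defaults, the numerical choices, and what the
desk-scale validation does and does not demonstrate.

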