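---
title: "Many-body expansions and data-driven potential energy functions for water"
author: "mbpef"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Many-body expansions and data-driven potential energy functions for water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbpef)
```

## The many-body formalism

The total energy of a system of $N$ water molecules can be rewritten
exactly as a sum over monomer subsets,

$$E_N = \sum_i \epsilon^{1B}(i) + \sum_{i<j} \epsilon^{2B}(i,j)
      + \sum_{i<j<k} \epsilon^{3B}(i,j,k) + \dots + \epsilon^{NB},$$

where $\epsilon^{1B}(i)$ is the distortion energy of molecule $i$ relative
to the relaxed free molecule and every higher term is the part of the
subset energy not attributable to any proper subset. `nbody_decompose()`
computes all terms bottom-up by the recursion
$\epsilon(S) = E(S) - \sum_{T \subsetneq S}\epsilon(T)$ over a pluggable
energy backend; an independent inclusion-exclusion evaluation
(`nbody_inclusion_exclusion()`) is kept in the package as a cross-check,
and the two agree term by term to $10^{-10}$ kcal/mol in the test suite.
Subset energies are evaluated at the cluster's frozen geometry (the
supermolecular convention) and no basis-set-superposition machinery is
involved: the backends here are analytic, and the package takes no
position on counterpoise corrections of ab initio data it might be fed
through `table_backend()`.

Interaction energy (total minus frozen monomers) and binding energy
(total minus relaxed monomers) are derived quantities with their own
independent code paths, which the tests exploit:
binding = interaction + total 1-body distortion must hold to $10^{-10}$.

The decomposition cost grows as $2^N$; a guard refuses clusters beyond
$N = 12$ unless explicitly overridden.

## Density-corrected DFT combinators

For benchmarking functionals the package provides the density-corrected
energy assembly

$$E^{\mathrm{DC}} = E^{\mathrm{HF}}
  + \left(E_{\mathrm{XC}}^{\mathrm{approx}}[n^{\mathrm{HF}}]
  - E_X^{\mathrm{HF}}\right),$$

the exact split of a functional's total error into functional-driven and
density-driven parts, and the error statistics used in cluster
benchmarks: mean unsigned error (MUE), per-molecule errors, maximum
unsigned error (sign preserved, ties first-wins), and distance-binned
MUEs with half-open bins plus cumulative values up to each bin edge.
Component energies are consumed in kcal/mol; a hartree flag converts with
1 Eh = 627.509474 kcal/mol. Statistics are kept at full precision
internally and rounded only for display. Note that published tables of
per-molecule errors sometimes disagree in the last digit with values
recomputed from the printed columns (rounding artifacts); this package
always reports its own full-precision value.

## The potential energy function

The PEF follows the many-body blueprint of data-driven water models:
explicit 1B, 2B and 3B terms plus classical $N$-body polarization for
everything beyond.

* **1B**: a pluggable monomer surface. The default is a Morse stretch
  ($D = 116.09$ kcal/mol, $a = 2.287$ A$^{-1}$, $r_e = 0.9572$ A) plus a
  harmonic bend ($k_\theta = 75.90$ kcal/mol/rad$^2$,
  $\theta_e = 104.52^\circ$), zero at the reference geometry. (A
  published spectroscopic monomer surface could be substituted through
  the same interface; differences in the 1B representation are known to
  matter little for liquid properties.)
* **2B/3B short range**: permutationally invariant polynomials (PIPs) in
  exponentially transformed intermolecular distances
  $\xi = e^{-k d}$ ($k = 0.8$ A$^{-1}$ for all pair types by default),
  symmetrized as orbit sums over the full group (H exchange within each
  monomer and whole-monomer exchange; order 8 for dimers, 48 for
  trimers), smoothly switched off on the O-O distance(s): quintic switch,
  2B window (5.5, 7.0) A by default, 3B as a product of pairwise
  switches with a (2.5, 4.5) A window. 3B monomials that do not couple
  all three monomers are dropped by default (their content is 2-body).
* **Permanent electrostatics**: fixed atomic charges (SPC/E values by
  default), with Thole exponential screening of *all* electrostatic
  interactions, including charge-charge. The charge-charge screening is
  a deliberate design choice: with bare Coulomb, an H site penetrating
  toward a neighboring O is a genuine $-1/r$ singularity that no O-O
  repulsion can fence off, and energy minimization will find it. The
  screening removes the singularity while leaving the physics at
  hydrogen-bonding distances essentially untouched.
* **Dispersion**: Tang-Toennies-damped $-C_6/r^6$ per pair type.
* **Repulsive core**: a fixed (non-fitted) Born-Mayer wall
  $A e^{-b r}$ per pair type. The O-O core approximates the reference's
  short-range wall; the O-H and H-H cores are made very steep
  ($b = 14$ A$^{-1}$) so they are negligible ($< 0.3$ kcal/mol) at any
  distance the training set samples yet dominate below ~1.1 A. This is
  the package's answer to the classic failure mode of polynomial PIPs:
  extrapolation holes at penetration geometries that liquid MD will
  eventually find. The core enters the fitting residual like
  electrostatics and dispersion, so the PIPs only represent what the
  fixed physics misses.
* **Polarization**: self-consistent induced point dipoles on the O
  sites (Jacobi iteration, 0.7 mixing, tolerance $10^{-8}$ D, warm
  limit 200 iterations), Thole-damped ($a = 0.426$), supplying all
  interaction orders beyond three. The induction energy
  $-\tfrac12\sum_i \boldsymbol\mu_i\cdot\mathbf E_i^{\mathrm{perm}}$ is
  non-positive for any geometry, and forces use the variational
  (envelope) gradient, so a converged solution gives exact analytic
  forces.

For periodic cubic boxes all intermolecular terms use molecule-based
minimum images (the partner molecule is shifted as a rigid unit by the
lattice vector minimizing the O-O distance) and each molecule pair's
electrostatics/dispersion/core energy is tapered by a quintic switch
ending at the cutoff, which must stay below $L/2$. There is no Ewald
summation: cutoff electrostatics with a smooth taper is a deliberate
desk-scale simplification, adequate for the internal-consistency studies
the package targets but not for quantitative dielectric properties.

## The synthetic reference backend

Quantum-chemistry reference energies are emulated by a deterministic
polarizable toy water model: Morse/bend intramolecular terms (zero for
the relaxed monomer), O-O Lennard-Jones ($\varepsilon = 0.1554$
kcal/mol, $\sigma = 3.1656$ A), SPC/E fixed charges
($q_H = +0.4238$ e) with the same Thole-screened Coulomb as the PEF, and
optional induced dipoles on O ($\alpha = 1.0$ A$^3$). With polarization
off the model is strictly pairwise additive — the property that makes
many-body truncation tests exact; with polarization on it has genuine
$\geq 3$-body content. Two parameter choices deviate from a plain
"SPC/E + polarizability" reading and were fixed once, early, for
physical reasons: full SPC/E charges (1.5x-stronger variants overbind
the dimer to $-10.4$ kcal/mol and collapse the liquid) and
$\alpha = 1.0$ A$^3$ rather than the gas-phase 1.44 (SPC/E charges
already contain average polarization; the reduced value keeps the
liquid stable and water-like, about $-12.5$ kcal/mol cohesion per
molecule at a 4.5 A cutoff). The backend doubles as an MD-capable force
field, which the engine tests use.

Geometry generators cover the protocols the analyses need: rigid
unrelaxed dimer scans along the donor O-H axis, seeded random cluster
samples (uniform orientations by random quaternion, uniform O-O
distances, overlap rejection, small intramolecular jitter so 1B terms
are exercised), simple-cubic liquid boxes filled in checkerboard order
(partial occupancies keep neighbors apart), and dimer extraction from
boxes by strict minimum-image O-O cutoff with rigid unwrapping.

## Fitting

2B and 3B PIP coefficients are obtained by weighted linear least
squares. Targets are short-range residuals: the backend's $n$-body
energy (from the exact decomposition) minus the model's $n$-body energy
with the PIP of that order removed. Weights
$w = (\Delta E_w/(E - E_{\min} + \Delta E_w))^2$ with
$\Delta E_w = 25$ kcal/mol emphasize the low-energy region. The solver
column-equilibrates the weighted design matrix and uses an SVD with
ridge $\lambda$ scaled by the mean squared design entry
($\lambda = 10^{-6}$ by default; $\lambda = 0$ requests an exact
least-squares solution and errors out on rank deficiency). A fitted term
whose predictions never exceed $10^{-8}$ kcal/mol is collapsed to exact
zeros — this happens, by construction, for the 3B fit against the toy
backend: the toy's $\geq 3$-body physics *is* the model's polarization
term, so the 3B residual is numerically zero and the honest fit is the
null polynomial. The machinery is exercised anyway (synthetic 3B
coefficients are recovered to $10^{-8}$ relative in the tests), and a
reference with genuinely different 3B physics would produce a nonzero
fit through the identical code path.

Train/held-out splitting is seeded and stratified by target-energy
quartile (90/10 by default); reports give MUE and RMSE overall and for
the $|E| \leq 25$ kcal/mol window.

## Molecular dynamics and observables

The engine implements velocity-Verlet NVE, BAOAB Langevin NVT (reducing
bit-identically to NVE at $\gamma = 0$), and NPT via Langevin plus an
isotropic Monte Carlo barostat (ln-volume moves, molecular
center-of-mass scaling, acceptance
$\min(1, e^{-[\Delta U + P\Delta V - (N+1)k_BT\ln(V'/V)]/k_BT})$, with
1 atm A$^3$ = 1.4584e-5 kcal/mol). A single seeded RNG stream drives
thermostat and barostat in fixed order, so checkpointed runs continue
bit-exactly. Induced dipoles are re-converged every step. A damped
steepest-descent minimizer relieves bad contacts in generated boxes
before dynamics. Instantaneous temperature is reported with
$3N - 3$ degrees of freedom; note the Langevin thermostat also
thermalizes the center of mass, so for free particles the mean kinetic
energy corresponds to $3N$ degrees of freedom and the reported
temperature reads correspondingly high for very small systems.

Observables: minimum-image RDFs normalized per frame by ideal-gas shell
counts (intramolecular pairs excluded); center-of-mass velocity
autocorrelation over all time origins and the Green-Kubo diffusion
coefficient $D = \tfrac13\int_0^{t_{\max}} C(t)\,dt$ by trapezoid, with
$t_{\max}$ defaulting to the first time $|C|$ stays below 1% of $C(0)$
for 1 ps, and block-averaged errors from 5 trajectory segments;
density-vs-temperature curves with a degree-5 polynomial fit and the
temperature of maximum density located by derivative root-finding on
the closed data interval (boundary maxima are flagged, never reported
as interior); isothermal compressibility from NPT volume fluctuations;
and the enthalpy of vaporization under the ideal-gas-vapor
approximation with the liquid $PV$ term neglected (the assumptions are
part of the return value). The default burn-in discards the first 20%
of every record.

## Scales, checks, and what they do (not) show

The package validates itself at desk scale: clusters up to hexamers,
liquid boxes of 32-100 molecules, simulations of 10-20 ps with a
0.2 fs time step, interaction cutoffs of 4.5 A with a 1 A taper, and
PIP fits of ~650 dimers (degree 4) and ~800 trimers (degree 3). These
are study conditions chosen so that every stage — decomposition exactness,
fit recovery, energy conservation (NVE drift below $10^{-4}$
kcal/mol/molecule/ps), equipartition, the ideal-gas barostat law, the
free-particle Green-Kubo limit, and the end-to-end
fit-then-simulate consistency of density and structure — is checked
quantitatively against analytic oracles or internal cross-paths.

What passing these checks shows: the algebra, gradients, samplers,
integrators and estimators are correct, and the fitting pipeline
faithfully transfers the reference's energetics into a simulable model.
What it does not show: anything about real water. The toy reference is
far simpler than an ab initio surface (its 2B residual beyond the fixed
physics is purely radial, its 3B residual is exactly the model's own
polarization), the cutoff is short, boxes are small, nuclear quantum
effects are absent, and no attempt is made to reproduce experimental
densities, diffusion coefficients or temperatures of maximum density.
With its 4.5 A cutoff the toy liquid equilibrates near 1.3 g/cm$^3$ —
denser than real water, as expected for a compressed-attraction model —
and the fitted PEF tracks it to well within a percent, which is the
property under test.

## Worked example

```{r example, eval = FALSE}
# reference backend and base model
toy <- toy_water_model()
bk  <- toy_backend(toy)

# exact many-body decomposition of a random hexamer
hex <- sample_clusters(6, 1, seed = 1, r_min = 2.5, r_max = 4)[[1]]
dec <- nbody_decompose(hex, bk)
dec$order_sums

# fit a 2B PIP to the backend and simulate the liquid
b2  <- build_pip_basis(2, 4, rin = 3.2, rout = 4.5)
fit <- fit_pip_term(sample_clusters(2, 500, seed = 2, r_min = 2.2,
                                    r_max = 5),
                    bk, pef_model(), 2, b2)
fit$report

box <- generate_liquid_box(32, 0.997, seed = 3)
ff  <- pef_force_field(fit$model, cutoff = 4.5)
st  <- minimize_energy(md_state(box), ff)
st$vel <- maxwell_velocities(st$masses, 298)
res <- run_simulation(st, ff,
                      md_config(dt_fs = 0.2, temperature = 298,
                                pressure = 1, cutoff = 4.5),
                      "npt", 5000)
mean(res$thermo$rho_gcm3)
```
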