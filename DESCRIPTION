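Package: mbpef
Title: Many-Body Expansion and Data-Driven Potential Energy Functions for Water
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for many-body analyses of molecular clusters and for building
    data-driven many-body potential energy functions (PEFs) for water. Provides
    an exact n-body energy decomposition over pluggable energy backends,
    density-corrected DFT energy combinators and the associated error
    statistics, construction and linear fitting of permutationally invariant
    polynomial (PIP) two- and three-body terms combined with permanent
    electrostatics, damped dispersion and self-consistent induced-dipole
    polarization, a minimal classical molecular dynamics engine (NVE, Langevin
    NVT, Monte Carlo barostat NPT), and liquid-state observables (radial
    distribution functions, velocity-autocorrelation self-diffusion, density
    curves and the temperature of maximum density, isothermal compressibility,
    enthalpy of vaporization). A deterministic polarizable toy water model with
    genuine three-body (induction) content serves as the reference energy
    backend so that every stage is testable without quantum chemistry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
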