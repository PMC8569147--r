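# A small but complete model with random (finite) PIP coefficients is
# enough to exercise every term and its gradient.
make_full_model <- function(seed = 1, deg2 = 3, deg3 = 2) {
  b2 <- build_pip_basis(2, deg2)
  b3 <- build_pip_basis(3, deg3)
  set.seed(seed)
  m <- pef_model(pip2b = list(basis = b2, coef = rnorm(b2$norbit, 0, 0.3)),
                 pip3b = list(basis = b3, coef = rnorm(b3$norbit, 0, 0.1)))
  m
}

test_that("single relaxed monomer has exactly zero energy", {
  m <- pef_model()
  expect_identical(pef_energy(cluster(reference_monomer()), m), 0)
})

test_that("breakdown sums to the total and couplings switch off cleanly", {
  mod <- make_full_model()
  hex <- sample_clusters(4, 1, seed = 3, r_min = 2.5, r_max = 4)[[1]]
  bd <- pef_energy(hex, mod, breakdown = TRUE)
  expect_equal(sum(bd$terms), bd$energy, tolerance = 1e-12)
  # all couplings off: dimer beyond every range -> pure 1-body sum
  bare <- pef_model(charges = c(O = 0, H = 0), c6 = c(OO = 0, OH = 0, HH = 0),
                    core = list(A = c(OO = 0, OH = 0, HH = 0),
                                b = c(OO = 1, OH = 1, HH = 1)),
                    polarization = list(alpha = 0, adampO = 1, adampH = 0.3,
                                        thole_a = 0.426, tol_debye = 1e-8,
                                        maxit = 200L, mix = 0.7,
                                        enabled = FALSE))
  far <- shifted_dimer(c(0, 0, 9.0))
  d1 <- nbody_decompose(far, pef_backend(bare))
  expect_equal(pef_energy(far, bare), sum(d1$terms[d1$order == 1]),
               tolerance = 1e-12)
})

test_that("analytic forces match central finite differences (gas phase)", {
  mod <- make_full_model()
  hex <- sample_clusters(6, 1, seed = 5, r_min = 2.5, r_max = 4.2)[[1]]
  pf <- pef_forces(hex, mod)
  gfd <- numeric_gradient(function(p) pef_energy(cluster(p), mod),
                          hex$coords)
  expect_lt(max(abs(pf$forces + gfd)), 1e-6)
})

test_that("net force and torque vanish for an isolated cluster", {
  mod <- make_full_model()
  # the variational induction force is exact at convergence; converge the
  # dipoles tightly so the test isolates the analytic-gradient property
  mod$polarization$tol_debye <- 1e-12
  hex <- sample_clusters(5, 1, seed = 6, r_min = 2.5, r_max = 4.2)[[1]]
  pf <- pef_forces(hex, mod)
  expect_lt(max(abs(colSums(pf$forces))), 1e-9)
  xc <- sweep(hex$coords, 2, colMeans(hex$coords))
  tq <- colSums(cbind(
    xc[, 2] * pf$forces[, 3] - xc[, 3] * pf$forces[, 2],
    xc[, 3] * pf$forces[, 1] - xc[, 1] * pf$forces[, 3],
    xc[, 1] * pf$forces[, 2] - xc[, 2] * pf$forces[, 1]))
  expect_lt(max(abs(tq)), 1e-8)
})

test_that("periodic forces match finite differences and images wrap", {
  # switching windows sized for a small box (ranges must stay below L/2)
  bs2 <- build_pip_basis(2, 2, rin = 2.2, rout = 3.1)
  bs3 <- build_pip_basis(3, 2, rin = 2.0, rout = 3.0)
  set.seed(1)
  mod <- pef_model(pip2b = list(basis = bs2, coef = rnorm(bs2$norbit, 0, 0.3)),
                   pip3b = list(basis = bs3, coef = rnorm(bs3$norbit, 0, 0.1)))
  box <- generate_liquid_box(8, 0.8, seed = 4)
  rc <- 0.45 * box$box$L
  pf <- pef_forces(box, mod, cutoff = rc)
  gfd <- numeric_gradient(function(p)
    pef_energy(cluster(p, box = box$box), mod, cutoff = rc), box$coords,
    rows = 1:12)
  expect_lt(max(abs((pf$forces + gfd)[1:12, ])), 1e-6)
  # translating one molecule by a lattice vector leaves the energy alone
  shifted <- box
  shifted$coords[4:6, ] <- shifted$coords[4:6, ] +
    matrix(rep(c(box$box$L, 0, 0), each = 3), 3, 3)
  expect_equal(pef_energy(shifted, mod, cutoff = rc),
               pef_energy(box, mod, cutoff = rc), tolerance = 1e-12)
  expect_error(pef_energy(box, mod, cutoff = box$box$L), "L/2")
})

test_that("full-model energy is invariant under the physical symmetries", {
  mod <- make_full_model()
  cl <- sample_clusters(3, 1, seed = 8, r_min = 2.5, r_max = 3.8)[[1]]
  e0 <- pef_energy(cl, mod)
  # intra-monomer H swap and monomer relabeling
  expect_equal(pef_energy(cluster(cl$coords[c(1, 3, 2, 4:9), ]), mod), e0,
               tolerance = 1e-10)
  expect_equal(pef_energy(cluster(cl$coords[c(4:6, 1:3, 7:9), ]), mod), e0,
               tolerance = 1e-10)
  # rigid translation and rotation
  expect_equal(pef_energy(cluster(sweep(cl$coords, 2, c(3, -7, 11), `+`)),
                          mod), e0, tolerance = 1e-10)
  th <- 0.73
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(pef_energy(cluster(cl$coords %*% t(R)), mod), e0,
               tolerance = 1e-10)
})

test_that("MBE of the polarization-free PEF matches term bookkeeping", {
  mod <- make_full_model()
  mod$polarization$enabled <- FALSE
  tri <- sample_clusters(3, 1, seed = 13, r_min = 2.6, r_max = 3.8)[[1]]
  dec <- nbody_decompose(tri, pef_backend(mod))
  bd <- pef_energy(tri, mod, breakdown = TRUE)
  # 3-body term is exactly the 3B PIP; 2-body collects the pair terms
  expect_equal(dec$order_sums[["3B"]], bd$terms[["pip3b"]],
               tolerance = 1e-9)
  expect_equal(dec$order_sums[["2B"]],
               bd$terms[["pip2b"]] + bd$terms[["elec"]] +
                 bd$terms[["dispersion"]] + bd$terms[["core"]],
               tolerance = 1e-9)
  # with polarization back on, the >= 4-body content is nonzero in general
  # but absent here (trimer); quadramer 4B vanishes without polarization
  quad <- sample_clusters(4, 1, seed = 14, r_min = 2.6, r_max = 3.8)[[1]]
  dq <- nbody_decompose(quad, pef_backend(mod))
  expect_lt(abs(dq$order_sums[["4B"]]), 1e-9)
})

test_that("dimer energy approaches the 1-body sum at long range", {
  # neutral monomers interact dipole-dipole (~ 2 f mu^2 / r^3, about
  # 1.6e-7 kcal/mol at 1000 Angstrom for this monomer dipole)
  mod <- make_full_model()
  dfar <- shifted_dimer(c(0, 0, 1000))
  e1 <- sum(nbody_decompose(dfar, pef_backend(mod))$terms[1:2])
  expect_lt(abs(pef_energy(dfar, mod) - e1), 1e-6)
  # and the decay is monotone past the switch region
  e50 <- abs(pef_energy(shifted_dimer(c(0, 0, 50)), mod) - e1)
  e200 <- abs(pef_energy(shifted_dimer(c(0, 0, 200)), mod) - e1)
  expect_lt(e200, e50)
})

test_that("induction energy is non-positive and matches closed forms", {
  # one polarizable site in the field of one distant charge: mu = alpha E
  r <- 5
  res <- solve_induced_dipoles(rbind(c(0, 0, 0), c(r, 0, 0)),
                               charges = c(0, 1), alpha = c(1.44, 0),
                               group = c(1, 2))
  f <- mbpef_constants$coulomb
  # field of a positive charge at +x points toward -x at the origin
  E <- -f * 1 / r^2          # Thole screening is ~1 at this distance
  expect_equal(res$energy, -0.5 * (1.44 / f) * E^2, tolerance = 1e-6)
  mu_eA <- res$dipoles[1, 1] * mbpef_constants$debye_to_eA
  expect_equal(mu_eA, (1.44 / f) * E, tolerance = 1e-6)
  # zero charges -> zero dipoles and energy
  z <- solve_induced_dipoles(rbind(c(0, 0, 0), c(3, 0, 0)),
                             charges = c(0, 0), alpha = c(1, 1))
  expect_equal(z$energy, 0)
  expect_true(all(z$dipoles == 0))
  # two mutually polarizing sites against the direct 2x2 linear solve
  alpha <- 0.8; d <- 3.0; q <- 0.7; rq <- 9.0
  sites <- rbind(c(0, 0, 0), c(d, 0, 0), c(rq, 0, 0))
  res2 <- solve_induced_dipoles(sites, charges = c(0, 0, q),
                                alpha = c(alpha, alpha, 0),
                                group = c(1, 2, 3), tol_debye = 1e-12)
  # axial components: mu_i = (alpha/f) (E0_i + T mu_j), T = 2 f l5 / d^3
  u <- d / (alpha * alpha)^(1/6)
  w <- 0.426 * u^3
  l3 <- 1 - exp(-w); l5 <- 1 - (1 + w) * exp(-w)
  Tdd <- f * (3 * l5 - l3) / d^3
  # the charge sits on the +x side, so both permanent fields point to -x
  E01 <- -f * q / rq^2; E02 <- -f * q / (rq - d)^2
  A <- matrix(c(f / alpha, -Tdd, -Tdd, f / alpha), 2, 2)
  mu <- solve(A, c(E01, E02))
  expect_equal(res2$dipoles[1:2, 1] * mbpef_constants$debye_to_eA, mu,
               tolerance = 1e-8)
  expect_equal(res2$energy, -0.5 * sum(mu * c(E01, E02)), tolerance = 1e-8)
  # induction energy non-positive on random clusters
  mod <- pef_model()
  for (s in 1:5) {
    cl <- sample_clusters(4, 1, seed = 60 + s, r_min = 2.5, r_max = 4)[[1]]
    bd <- pef_energy(cl, mod, breakdown = TRUE)
    expect_lte(bd$terms[["induction"]], 0)
  }
})

test_that("polarization catastrophe is reported, not silently wrong", {
  expect_error(
    solve_induced_dipoles(rbind(c(0, 0, 0), c(0.8, 0, 0)),
                          charges = c(0.5, -0.5), alpha = c(25, 25),
                          adamp = c(25, 25), thole_a = 8, maxit = 50),
    "converge")
})

test_that("Tang-Toennies dispersion limits and series expansion", {
  # large damping -> bare -C6/r^6
  expect_equal(dispersion_energy(3, 100, delta = 50), -100 / 3^6,
               tolerance = 1e-10)
  # short range: damping converts the r^-6 divergence into a linear zero,
  # E -> -C6 delta^7 r / 5040
  r0 <- 1e-3
  expect_equal(dispersion_energy(r0, 100, delta = 2),
               -100 * 2^7 * r0 / 5040, tolerance = 5e-3)
  expect_lt(abs(dispersion_energy(1e-6, 100, delta = 2)), 1e-3)
  # f6 at x = 2 against term-by-term series evaluation
  x <- 2
  f6_series <- 1 - exp(-x) * sum(x^(0:6) / factorial(0:6))
  r <- x / 2  # delta = 2
  expect_equal(dispersion_energy(r, 1, delta = 2), -f6_series / r^6,
               tolerance = 1e-12)
})

test_that("model serialization round-trips losslessly and checks versions", {
  mod <- make_full_model(seed = 4, deg2 = 2, deg3 = 2)
  tmp <- withr::local_tempfile(fileext = ".mbpef")
  write_pef_model(mod, tmp)
  back <- read_pef_model(tmp)
  hex <- sample_clusters(3, 1, seed = 77, r_min = 2.5, r_max = 4)[[1]]
  expect_identical(pef_energy(hex, back), pef_energy(hex, mod))
  expect_identical(back$pip2b$coef, mod$pip2b$coef)
  # unknown format version rejected
  lines <- readLines(tmp)
  lines[grep("^format_version", lines)] <- "format_version 99"
  writeLines(lines, tmp)
  expect_error(read_pef_model(tmp), "format_version")
})
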