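kB <- mbpef_constants$kB

make_uniform_traj <- function(n_mol, L, n_frames, seed) {
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(f) {
    coords <- matrix(NA_real_, 3 * n_mol, 3)
    for (m in seq_len(n_mol)) {
      o <- runif(3, 0, L)
      coords[(3 * m - 2):(3 * m), ] <- sweep(reference_monomer(), 2, o, `+`)
    }
    list(cluster = cluster(coords, box = periodic_box(L)),
         time = (f - 1) * 0.1)
  })
  trajectory(frames)
}

test_that("RDF of uniform random configurations is flat at 1", {
  traj <- make_uniform_traj(40, 14, 60, seed = 1)
  rdf <- compute_rdf(traj, "OO", bin_width = 0.5)
  sel <- rdf$r > 2          # skip the first (low-count) bins
  counts_per_bin <- rdf$g[sel] * 1  # relative noise ~ 1/sqrt(n)
  expect_true(all(abs(rdf$g[sel] - 1) < 0.25))
  expect_lt(abs(mean(rdf$g[sel]) - 1), 0.03)
  expect_error(compute_rdf(traj, "OO", r_max = 8), "L/2")
})

test_that("two fixed particles give a single occupied RDF bin", {
  coords <- rbind(reference_monomer(),
                  sweep(reference_monomer(), 2, c(0, 0, 3.17), `+`))
  traj <- trajectory(list(list(cluster = cluster(coords,
                                                 box = periodic_box(12)))))
  rdf <- compute_rdf(traj, "OO", bin_width = 0.1)
  occ <- which(rdf$g > 0)
  expect_length(occ, 1)
  expect_true(rdf$r[occ] > 3.05 && rdf$r[occ] < 3.25)
})

test_that("RDF normalization integral reproduces direct neighbor counts", {
  traj <- make_uniform_traj(32, 12, 40, seed = 2)
  rdf <- compute_rdf(traj, "OO", bin_width = 0.2, r_max = 5)
  rho <- (32 - 1) / 12^3    # partner density per O, excluding self-molecule
  coordination <- sum(rho * rdf$g * 4 * pi * rdf$r^2 * rdf$bin_width)
  # direct count of neighbors within r_max, averaged over frames and sites
  direct <- mean(sapply(traj$frames, function(f) {
    O <- f$cluster$coords[seq(1, 96, 3), ]
    cnt <- 0
    for (i in 1:31) for (j in (i + 1):32) {
      d <- O[j, ] - O[i, ]
      d <- d - 12 * round(d / 12)
      if (sqrt(sum(d^2)) < 5) cnt <- cnt + 2
    }
    cnt / 32
  }))
  expect_lt(abs(coordination - direct) / direct, 0.02)
})

test_that("VACF closed forms: constant velocities and direct arithmetic", {
  coords <- rbind(reference_monomer(),
                  sweep(reference_monomer(), 2, c(0, 0, 5), `+`))
  v <- matrix(rep(c(0.3, -0.1, 0.2), each = 6), 6, 3)
  frames <- lapply(0:9, function(i)
    list(cluster = cluster(coords + i * 0.01 * v), velocities = v,
         time = i * 0.1))
  vac <- compute_vacf(trajectory(frames), max_lag = 5)
  expect_equal(vac$C, rep(sum(c(0.3, -0.1, 0.2)^2), 6), tolerance = 1e-12)
  # single molecule, varying velocity: hand-computed dot products
  vs <- lapply(1:4, function(i) matrix(i * 0.1, 3, 3))
  frames2 <- lapply(1:4, function(i)
    list(cluster = cluster(reference_monomer()), velocities = vs[[i]],
         time = i * 0.1))
  vac2 <- compute_vacf(trajectory(frames2), max_lag = 2)
  # COM velocity equals the (uniform) atom velocity (i*0.1 per component)
  c1_hand <- mean(sapply(1:3, function(t0)
    sum((0.1 * t0) * (0.1 * (t0 + 1)) * 3)))
  expect_equal(vac2$C[2], c1_hand, tolerance = 1e-12)
  expect_error(compute_vacf(trajectory(list(list(
    cluster = cluster(reference_monomer()))))), "velocities")
})

test_that("Green-Kubo integral closed forms and input validation", {
  vac <- structure(list(t = seq(0, 3, 0.1), C = rep(2, 31)),
                   class = "mbpef_vacf")
  expect_equal(diffusion_from_vacf(vac, 3)$D, 2 * 3 / 3)
  vac0 <- structure(list(t = seq(0, 3, 0.1), C = rep(0, 31)),
                    class = "mbpef_vacf")
  expect_equal(diffusion_from_vacf(vac0)$D, 0)
  expect_error(diffusion_from_vacf(vac, 5), "beyond")
})

test_that("free Langevin molecules diffuse at kBT/(m gamma)", {
  nul <- null_force_field()
  st <- md_state(generate_liquid_box(100, 0.05, seed = 5))
  res <- run_simulation(st, nul,
                        md_config(dt_fs = 2, temperature = 300, gamma = 1,
                                  seed = 16), "nvt", 52500,
                        thermo_every = 5000, traj_every = 25)
  traj <- res$trajectory
  traj$frames <- traj$frames[-(1:100)]   # velocity thermalization
  vac <- compute_vacf(traj, max_lag = 140)   # 7 ps of 0.05 ps frames
  M <- mbpef_constants$molar_mass_water
  expect_equal(vac$C[1], 3 * kB * 300 * 418.4 / M, tolerance = 0.05)
  di <- diffusion_from_trajectory(traj, t_max = 6.5)
  Dexp <- kB * 300 * 418.4 / (M * 1)
  expect_lt(abs(di$D - Dexp) / Dexp, 0.05)
  expect_true(is.finite(di$stderr) && di$stderr > 0)
})

test_that("density curve recovers a constructed maximum exactly and under
           noise, and flags boundary maxima", {
  T <- seq(250, 320, 10)
  rho <- 0.997 - 4e-6 * (T - 280)^2
  dc <- density_curve(T, rho)
  expect_equal(dc$tmd, 280, tolerance = 1e-6)
  expect_false(dc$tmd_boundary)
  # under sigma = 0.001 g/cm^3 noise the degree-5 estimator is noisy but
  # bounded: the Monte-Carlo oracle for this grid gives sd ~7.6 K with
  # every replicate inside the data interval (frozen from the oracle run)
  set.seed(31)
  tmds <- replicate(100, {
    density_curve(T, rho + rnorm(length(T), 0, 0.001))$tmd
  })
  expect_lt(sd(tmds), 12)
  expect_true(all(tmds >= min(T) & tmds <= max(T)))
  # at sigma = 5e-5 (the noise level the Monte-Carlo oracle shows is
  # needed for +-2 K with this curvature) every replicate is within 2 K
  set.seed(32)
  tmds2 <- replicate(100, {
    density_curve(T, rho + rnorm(length(T), 0, 5e-5))$tmd
  })
  expect_true(all(abs(tmds2 - 280) <= 2))
  # strictly increasing density -> boundary flag
  inc <- density_curve(T, 0.9 + 1e-4 * (T - 250))
  expect_true(inc$tmd_boundary)
  expect_error(density_curve(T[1:4], rho[1:4]), "at least")
})

test_that("isothermal compressibility: ideal-gas 1/P, degenerate and
           scaling cases", {
  nul <- null_force_field()
  st <- md_state(generate_liquid_box(64, 0.3, seed = 6))
  P <- 200
  res <- run_simulation(st, nul,
                        md_config(dt_fs = 1, temperature = 300, pressure = P,
                                  gamma = 5, seed = 17, max_lnV_step = 0.15,
                                  barostat_every = 2), "npt", 60000,
                        thermo_every = 20)
  k <- isothermal_compressibility(res$thermo, 300)
  expect_lt(abs(k$kappa_T - 1 / P) * P, 0.05)
  # constant volume -> zero
  const <- data.frame(V_A3 = rep(1000, 100))
  expect_equal(isothermal_compressibility(const, 300)$kappa_T, 0)
  # doubling volumes doubles kappa (variance x4, mean x2)
  th <- res$thermo
  th2 <- th; th2$V_A3 <- 2 * th$V_A3
  expect_equal(isothermal_compressibility(th2, 300)$kappa_T,
               2 * k$kappa_T, tolerance = 1e-10)
  nv <- data.frame(V_A3 = rep(NA_real_, 10))
  expect_error(isothermal_compressibility(nv, 300), "NPT")
})

test_that("enthalpy of vaporization arithmetic", {
  r <- enthalpy_of_vaporization(-10, 0, 298)
  expect_equal(r$dH_vap, 10 + kB * 298)
  expect_equal(round(r$dH_vap, 3), 10.592)
  expect_equal(enthalpy_of_vaporization(-5, -5, 298)$dH_vap, kB * 298)
  expect_equal(enthalpy_of_vaporization(-7, -3, 0)$dH_vap, 4)
  expect_error(enthalpy_of_vaporization(-10, NA, 298), "required")
  th <- data.frame(epot = rep(-320, 50))
  r2 <- enthalpy_of_vaporization(th, 0, 298, n_molecules = 32)
  expect_equal(r2$dH_vap, 10 + kB * 298)
})
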