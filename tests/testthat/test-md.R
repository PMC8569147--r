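kB <- mbpef_constants$kB

test_that("velocity Verlet: free flight, momentum conservation, dt^2 error
           scaling on a harmonic mode", {
  nul <- null_force_field()
  cl <- shifted_dimer(c(0, 0, 6))
  st <- md_state(cl)
  st$vel <- matrix(rep(c(0.1, -0.2, 0.3), each = 6), 6, 3)
  s1 <- st
  for (i in 1:100) s1 <- velocity_verlet_step(s1, nul, 1.0)
  expect_equal(s1$pos, st$pos + 0.1 * st$vel, tolerance = 1e-12)
  # momentum conserved with interacting forces
  tm <- toy_water_model()
  ff <- toy_force_field(tm)
  st2 <- md_state(shifted_dimer(c(0, 0, 2.9)))
  set.seed(1); st2$vel <- maxwell_velocities(st2$masses, 100)
  p0 <- colSums(st2$vel * st2$masses)
  for (i in 1:200) st2 <- velocity_verlet_step(st2, ff, 0.2)
  expect_lt(max(abs(colSums(st2$vel * st2$masses) - p0)), 1e-10)
  # 1D harmonic oscillator via a quadratic force field: energy error ~ dt^2
  kspr <- 500
  hff <- function(pos, L, forces = TRUE)
    list(energy = 0.5 * kspr * sum(pos[1, ]^2), forces = rbind(-kspr * pos[1, ],
         matrix(0, nrow(pos) - 1, 3)))
  osc_err <- sapply(c(0.5, 1.0), function(dt) {
    s <- md_state(cluster(reference_monomer()))
    s$pos[1, ] <- c(0.2, 0, 0)
    emax <- 0
    e0 <- NULL
    for (i in 1:400) {
      s <- velocity_verlet_step(s, hff, dt)
      ek <- 0.5 * s$masses[1] * sum(s$vel[1, ]^2) / 418.4
      et <- s$epot + ek
      if (is.null(e0)) e0 <- et
      emax <- max(emax, abs(et - e0))
    }
    emax
  })
  expect_gt(osc_err[2] / osc_err[1], 2.5)   # ~4 expected for dt doubling
  expect_lt(osc_err[2] / osc_err[1], 6)
})

test_that("Langevin reduces to velocity Verlet at gamma = 0 and has the
           exact OU velocity variance", {
  tm <- toy_water_model()
  ff <- toy_force_field(tm)
  st <- md_state(shifted_dimer(c(0, 0, 2.9)))
  set.seed(5); st$vel <- maxwell_velocities(st$masses, 200)
  a <- st; b <- st
  for (i in 1:50) {
    a <- velocity_verlet_step(a, ff, 0.2)
    b <- langevin_step(b, ff, 0.2, 298, 0)
  }
  expect_identical(a$pos, b$pos)
  expect_identical(a$vel, b$vel)
  expect_error(langevin_step(st, ff, 0.2, 298, -1), ">= 0")
  # O-step variance from v = 0 after one step: (1 - e^{-2 gamma dt}) kBT/m
  nul <- null_force_field()
  gamma <- 50; dt_fs <- 1; T0 <- 300
  st0 <- md_state(generate_liquid_box(27, 0.2, seed = 2))
  set.seed(42)
  nrep <- 300
  vsq <- matrix(0, nrep, 2)
  for (r in 1:nrep) {
    s <- st0   # zero velocities
    s <- langevin_step(s, nul, dt_fs, T0, gamma)
    vo <- s$vel[seq(1, 81, 3), ]
    vh <- s$vel[-seq(1, 81, 3), ]
    vsq[r, ] <- c(mean(vo^2), mean(vh^2))
  }
  c1 <- exp(-gamma * dt_fs * 1e-3)
  for (j in 1:2) {
    m <- c(15.999, 1.008)[j]
    expect_equal(mean(vsq[, j]), (1 - c1^2) * kB * T0 * 418.4 / m,
                 tolerance = 0.03)
  }
})

test_that("long-run Langevin kinetic energy satisfies equipartition", {
  nul <- null_force_field()
  st <- md_state(generate_liquid_box(27, 0.3, seed = 3))
  res <- run_simulation(st, nul,
                        md_config(dt_fs = 1, temperature = 300, gamma = 20,
                                  seed = 6), "nvt", 20000,
                        thermo_every = 10)
  ek <- res$thermo$ekin[-(1:200)]
  # Langevin thermalizes all 3N degrees of freedom
  expect_n <- 0.5 * (3 * 81) * kB * 300
  blocks <- split(ek, cut(seq_along(ek), 10, labels = FALSE))
  bm <- sapply(blocks, mean)
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(ek) - expect_n), 3 * se + 0.02 * expect_n)
})

test_that("MC barostat: guaranteed acceptance, bit-exact rejection, and the
           ideal-gas volume law", {
  nul <- null_force_field()
  st <- md_state(generate_liquid_box(27, 0.3, seed = 4))
  # zero-size move has acceptance probability 1
  set.seed(8)
  s2 <- mc_barostat_move(st, nul, pressure = 1, temperature = 300,
                         max_lnV_step = 0)
  expect_gt(s2$barostat_accepts, 0)
  # rejection restores the state bit-exactly (shrink below 2*cutoff)
  set.seed(9)
  s3 <- mc_barostat_move(st, nul, 1, 300, max_lnV_step = 0.5,
                         cutoff = st$L)   # any L' < 2L is "too small"
  expect_identical(s3$pos, st$pos)
  expect_identical(s3$L, st$L)
  expect_equal(s3$barostat_cutoff_rejects, 1L)
  # ideal-gas <V> = (N + 1) kB T / P
  st4 <- md_state(generate_liquid_box(64, 0.3, seed = 5))
  res <- run_simulation(st4, nul,
                        md_config(dt_fs = 1, temperature = 300, pressure = 100,
                                  gamma = 5, seed = 10, max_lnV_step = 0.05,
                                  barostat_every = 5), "npt", 40000,
                        thermo_every = 20)
  Vexp <- (64 + 1) * kB * 300 / (100 * mbpef_constants$atmA3_to_kcal)
  Vobs <- mean(res$thermo$V_A3[-(1:400)])
  expect_lt(abs(Vobs - Vexp) / Vexp, 0.02)
})

test_that("time reversibility at gamma = 0", {
  tm <- toy_water_model()
  ff <- toy_force_field(tm)
  st <- md_state(shifted_dimer(c(0, 0, 2.9)))
  set.seed(11); st$vel <- maxwell_velocities(st$masses, 150)
  fwd <- st
  for (i in 1:200) fwd <- velocity_verlet_step(fwd, ff, 0.2)
  fwd$vel <- -fwd$vel
  fwd$forces <- NULL
  back <- fwd
  for (i in 1:200) back <- velocity_verlet_step(back, ff, 0.2)
  expect_lt(max(abs(back$pos - st$pos)), 1e-8)
})

test_that("checkpoint/restart reproduces an uninterrupted run bit-exactly", {
  tm <- toy_water_model()
  ff <- toy_force_field(tm, cutoff = 3.9, taper = 1)
  box <- generate_liquid_box(8, 0.9, seed = 7)
  st <- md_state(box)
  cfg <- md_config(dt_fs = 0.5, temperature = 250, gamma = 2, seed = 13)
  full <- run_simulation(st, ff, cfg, "nvt", 200, thermo_every = 50)
  # same run in two halves through a checkpoint
  half1 <- run_simulation(st, ff, cfg, "nvt", 100, thermo_every = 50)
  ck <- checkpoint_state(half1$state)
  st2 <- restore_checkpoint(ck)
  cfg2 <- cfg; cfg2$seed <- NULL
  half2 <- run_simulation(st2, ff, cfg2, "nvt", 100, thermo_every = 50)
  expect_identical(half2$state$pos, full$state$pos)
  expect_identical(half2$state$vel, full$state$vel)
})

test_that("energy minimization relieves bad contacts", {
  tm <- toy_water_model()
  ff <- toy_force_field(tm, cutoff = 4.5, taper = 1)
  box <- generate_liquid_box(27, 0.997, seed = 8)
  st0 <- md_state(box)
  st <- minimize_energy(st0, ff, n_steps = 150)
  e_before <- ff(st0$pos, st0$L, forces = FALSE)$energy
  expect_lt(st$epot, e_before)
  expect_true(all(is.finite(st$forces)))
})
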