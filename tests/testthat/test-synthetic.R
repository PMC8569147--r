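test_that("toy backend reference properties: zero at the relaxed monomer,
           decay at separation, smooth forces", {
  tm <- toy_water_model()
  expect_identical(toy_energy(cluster(reference_monomer()), tm), 0)
  far <- shifted_dimer(c(0, 0, 5000))
  expect_lt(abs(toy_energy(far, tm)), 1e-8)
  cl <- sample_clusters(3, 1, seed = 2, r_min = 2.6, r_max = 3.8)[[1]]
  tf <- toy_forces(cl, tm)
  gfd <- numeric_gradient(function(p) toy_energy(cluster(p), tm), cl$coords)
  expect_lt(max(abs(tf$forces + gfd)), 1e-6)
  expect_error(toy_water_model(qO = -1, qH = 0.4), "neutral")
})

test_that("dimer scans hit the requested O..H distances with rigid
           monomers and increasing O..O", {
  grid <- seq(1.5, 3.5, 0.25)
  scan <- generate_dimer_scan(grid)
  roo <- numeric(length(scan))
  for (i in seq_along(scan)) {
    cl <- scan[[i]]
    # O(acceptor) ... H1(donor) distance equals the grid value exactly
    d <- sqrt(sum((cl$coords[4, ] - cl$coords[2, ])^2))
    expect_equal(d, grid[i], tolerance = 1e-10)
    # internal O-H distances identical across frames (rigid monomers)
    for (m in 0:1) {
      o <- cl$coords[3 * m + 1, ]
      expect_equal(sqrt(sum((cl$coords[3 * m + 2, ] - o)^2)), 0.9572,
                   tolerance = 1e-10)
    }
    roo[i] <- attr(cl, "tags")$r_oo
  }
  expect_true(all(diff(roo) > 0))
  expect_error(generate_dimer_scan(c(0.3, 1)), "0.5")
  expect_error(generate_dimer_scan(c(2, 1)), "increasing")
})

test_that("cluster sampling is seeded, overlap-free and covers the O-O
           range uniformly", {
  a <- sample_clusters(2, 20, seed = 42, r_min = 2.4, r_max = 6)
  b <- sample_clusters(2, 20, seed = 42, r_min = 2.4, r_max = 6)
  expect_identical(lapply(a, `[[`, "coords"), lapply(b, `[[`, "coords"))
  # all interatomic distances respect the overlap floor
  for (cl in sample_clusters(3, 10, seed = 43, r_min = 2.4, r_max = 5)) {
    d <- as.matrix(dist(cl$coords))
    diag(d) <- Inf
    # intramolecular O-H ~0.96 is expected; check intermolecular pairs
    mol <- rep(1:3, each = 3)
    inter <- outer(mol, mol, `!=`)
    expect_gte(min(d[inter]), 1.2)
  }
  # empirical O-O histogram consistent with uniform sampling (no
  # intramolecular jitter, so the drawn distance is realized exactly)
  roo <- vapply(sample_clusters(2, 2000, seed = 44, r_min = 2.5,
                                r_max = 6.5, jitter_sd = 0),
                function(cl) sqrt(sum((cl$coords[4, ] - cl$coords[1, ])^2)),
                numeric(1))
  h <- hist(roo, breaks = seq(2.5, 6.5, 0.5), plot = FALSE)$counts
  expect_gt(chisq.test(h)$p.value, 0.01)
  expect_error(sample_clusters(2, 5, r_min = 1.0), "unphysical")
})

test_that("liquid boxes have the requested density and scale correctly", {
  box <- generate_liquid_box(256, 0.997, seed = 1)
  expect_equal(box$box$L, 19.73, tolerance = 0.01)
  # doubling density divides L by 2^(1/3)
  box2 <- generate_liquid_box(256, 2 * 0.997, seed = 1)
  expect_equal(box2$box$L, box$box$L / 2^(1 / 3), tolerance = 1e-9)
  # reproducible
  expect_identical(generate_liquid_box(32, 1, seed = 9)$coords,
                   generate_liquid_box(32, 1, seed = 9)$coords)
  expect_error(generate_liquid_box(32, -1), "positive")
  # density bookkeeping: mass / volume matches the request
  M <- mbpef_constants$molar_mass_water
  rho <- 32 * M / (0.602214076 * generate_liquid_box(32, 1.1, seed = 2)$box$L^3)
  expect_equal(rho, 1.1, tolerance = 1e-9)
})

test_that("dimer extraction honors the strict O-O cutoff and unwraps
           molecules", {
  # 2-molecule boxes with controlled separations
  mk <- function(sep) {
    L <- 12
    coords <- rbind(sweep(reference_monomer(), 2, c(0.5, 6, 6), `+`),
                    sweep(reference_monomer(), 2, c(0.5 + sep, 6, 6), `+`))
    cluster(coords, box = periodic_box(L))
  }
  expect_length(extract_dimers(mk(6.0), 5.5), 0)
  expect_length(extract_dimers(mk(5.5), 5.5), 0)    # boundary excluded
  got <- extract_dimers(mk(5.4), 5.5)
  expect_length(got, 1)
  expect_equal(attr(got[[1]], "tags")$distance, 5.4, tolerance = 1e-9)
  # a pair split across the boundary is unwrapped whole
  L <- 12
  coords <- rbind(sweep(reference_monomer(), 2, c(11.5, 6, 6), `+`),
                  sweep(reference_monomer(), 2, c(1.5, 6, 6), `+`))
  wrap <- cluster(coords, box = periodic_box(L))
  dimers <- extract_dimers(wrap, 5.5)
  expect_length(dimers, 1)
  d <- dimers[[1]]
  expect_equal(attr(d, "tags")$distance, 2.0, tolerance = 1e-9)
  # unwrapped: actual O-O distance in the extracted gas-phase dimer matches
  expect_equal(sqrt(sum((d$coords[4, ] - d$coords[1, ])^2)), 2.0,
               tolerance = 1e-9)
  # count matches a brute-force 27-image enumeration on a random box
  box <- generate_liquid_box(27, 0.9, seed = 6)
  got2 <- extract_dimers(box, 5.0)
  cnt <- 0
  O <- box$coords[seq(1, 81, 3), ]
  for (i in 1:26) for (j in (i + 1):27)
    if (brute_min_image(O[i, ], O[j, ], box$box$L) < 5.0) cnt <- cnt + 1
  expect_length(got2, cnt)
})

test_that("polarization gives the toy model genuine 3-body content with the
           right distance decay", {
  tmp <- toy_water_model()
  tm0 <- toy_water_model(polarization = FALSE)
  tri <- sample_clusters(3, 1, seed = 7, r_min = 2.6, r_max = 3.4)[[1]]
  e3_pol <- nbody_decompose(tri, toy_backend(tmp))$terms[["0-1-2"]]
  e3_off <- nbody_decompose(tri, toy_backend(tm0))$terms[["0-1-2"]]
  expect_lt(abs(e3_off), 1e-9)
  expect_gt(abs(e3_pol), 1e-3)
})
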