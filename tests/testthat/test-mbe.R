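tm_pol <- toy_water_model()
tm_pair <- toy_water_model(polarization = FALSE)

test_that("subcluster enumeration, evaluation counts and caching", {
  tri <- sample_clusters(3, 1, seed = 2, r_min = 2.6, r_max = 4)[[1]]
  bk <- counting_backend(toy_backend(tm_pair))
  cache <- new.env(parent = emptyenv())
  E <- subcluster_energies(tri, bk, 3, cache)
  expect_length(E, 7)                       # 2^3 - 1
  expect_equal(bk$counter$n, 7L)
  # repeated call with the same cache performs no new evaluations
  E2 <- subcluster_energies(tri, bk, 3, cache)
  expect_equal(bk$counter$n, 7L)
  expect_identical(E, E2)
  # N = 6, max_order = 2 -> 6 + 15 evaluations
  hex <- sample_clusters(6, 1, seed = 3, r_min = 2.6, r_max = 4.5)[[1]]
  bk2 <- counting_backend(toy_backend(tm_pair))
  subcluster_energies(hex, bk2, 2)
  expect_equal(bk2$counter$n, 21L)
  expect_error(subcluster_energies(hex, bk2, 7), "between 1 and")
})

test_that("recursive decomposition agrees with inclusion-exclusion and
           reconstructs the total energy", {
  bk <- toy_backend(tm_pol)
  for (n in 2:5) {
    cl <- sample_clusters(n, 1, seed = 10 + n, r_min = 2.5, r_max = 4.2)[[1]]
    cache <- new.env(parent = emptyenv())
    dec <- nbody_decompose(cl, bk, cache = cache)
    ie <- nbody_inclusion_exclusion(cl, bk, cache = cache)
    expect_equal(max(abs(dec$terms - ie[names(dec$terms)])), 0,
                 tolerance = 1e-10)
    etot <- bk$evaluate(cl)
    expect_equal(dec$total_reconstructed, etot,
                 tolerance = 1e-10 * max(1, abs(etot)))
  }
})

test_that("pairwise-additive backend has zero n >= 3 terms; polarization
           switches genuine 3-body content on", {
  bk0 <- toy_backend(tm_pair)
  bk1 <- toy_backend(tm_pol)
  tri <- sample_clusters(3, 1, seed = 5, r_min = 2.6, r_max = 3.6)[[1]]
  d0 <- nbody_decompose(tri, bk0)
  expect_lt(abs(d0$terms[["0-1-2"]]), 1e-9)
  d1 <- nbody_decompose(tri, bk1)
  expect_gt(abs(d1$terms[["0-1-2"]]), 1e-4)
  # 3-body magnitude decays under uniform dilation
  e3 <- sapply(c(1, 1.5, 2), function(s) {
    scaled <- tri
    # scale monomer centers away from the centroid, rigid internals
    ctr <- colMeans(scaled$coords)
    for (m in 1:3) {
      rows <- (3 * m - 2):(3 * m)
      o <- scaled$coords[rows[1], ]
      scaled$coords[rows, ] <- scaled$coords[rows, ] +
        matrix(rep((s - 1) * (o - ctr), each = 3), 3, 3)
    }
    abs(nbody_decompose(scaled, bk1)$terms[["0-1-2"]])
  })
  expect_true(all(diff(e3) < 0))
})

test_that("widely separated monomers have negligible interaction terms", {
  # neutral monomers keep a dipole-dipole tail ~ 2 f mu^2 / r^3, so the
  # 1e-9 kcal/mol floor needs several thousand Angstrom of separation
  far <- cluster(rbind(reference_monomer(),
                       sweep(reference_monomer(), 2, c(8000, 0, 0), `+`),
                       sweep(reference_monomer(), 2, c(0, 8000, 0), `+`)))
  dec <- nbody_decompose(far, toy_backend(tm_pol))
  expect_lt(abs(dec$order_sums[["2B"]]), 1e-9)
  expect_lt(abs(dec$order_sums[["3B"]]), 1e-9)
})

test_that("interaction and binding energies obey their defining identities", {
  bk <- toy_backend(tm_pol)
  # dimer: interaction energy equals the 2-body term exactly
  dim <- sample_clusters(2, 1, seed = 8, r_min = 2.6, r_max = 3.4)[[1]]
  dec <- nbody_decompose(dim, bk)
  expect_equal(interaction_energy(dim, bk), dec$terms[["0-1"]],
               tolerance = 1e-12)
  # hexamer: binding = interaction + sum of 1B distortions (two code paths)
  hex <- sample_clusters(6, 1, seed = 9, r_min = 2.5, r_max = 4.2)[[1]]
  dech <- nbody_decompose(hex, bk, max_order = 1)
  expect_equal(binding_energy(hex, bk),
               interaction_energy(hex, bk) + dech$order_sums[["1B"]],
               tolerance = 1e-10)
  # single relaxed monomer binds nothing
  expect_equal(binding_energy(cluster(reference_monomer()), bk), 0,
               tolerance = 1e-12)
  nobk <- energy_backend(function(cl) 0)
  expect_error(binding_energy(dim, nobk), "reference energy")
})

test_that("truncated reconstruction converges through the orders", {
  bk <- toy_backend(tm_pol)
  hex <- sample_clusters(6, 1, seed = 21, r_min = 2.5, r_max = 3.8)[[1]]
  dec <- nbody_decompose(hex, bk)
  etot <- bk$evaluate(hex)
  expect_equal(truncated_reconstruction(dec, 6), etot, tolerance = 1e-10)
  err <- sapply(1:4, function(n)
    abs(truncated_reconstruction(dec, n) - etot))
  expect_lt(err[3], err[2])   # 3B truncation beats 2B
  expect_error(truncated_reconstruction(dec, 7), "exceeds")
})

test_that("decomposition is invariant under monomer relabeling", {
  bk <- toy_backend(tm_pol)
  cl <- sample_clusters(4, 1, seed = 31, r_min = 2.5, r_max = 4)[[1]]
  perm <- c(3L, 1L, 4L, 2L)
  rows <- as.vector(vapply(perm, function(i) (3 * i - 2):(3 * i),
                           integer(3)))
  clp <- cluster(cl$coords[rows, ])
  d1 <- nbody_decompose(cl, bk)
  d2 <- nbody_decompose(clp, bk)
  expect_equal(d1$order_sums, d2$order_sums, tolerance = 1e-12)
  # individual terms map through the permutation of monomer labels
  inv <- order(perm) - 1L   # old index -> new index, 0-based
  for (key in names(d1$terms)) {
    old <- as.integer(strsplit(key, "-")[[1]])
    newkey <- paste(sort(inv[old + 1L]), collapse = "-")
    expect_equal(d1$terms[[key]], d2$terms[[newkey]], tolerance = 1e-11)
  }
})

test_that("table backend decomposes externally supplied energies", {
  tri <- sample_clusters(3, 1, seed = 41, r_min = 2.6, r_max = 3.6)[[1]]
  bk <- toy_backend(tm_pol)
  E <- subcluster_energies(tri, bk, 3)
  tab <- data.frame(subset = names(E), energy_kcal_mol = as.numeric(E))
  tbk <- table_backend(tab, tri, monomer_reference_energy = 0)
  dec_t <- nbody_decompose(tri, tbk)
  dec_d <- nbody_decompose(tri, bk)
  expect_equal(dec_t$terms, dec_d$terms, tolerance = 1e-12)
  # missing subset reported by key
  tab2 <- tab[tab$subset != "0-2", ]
  tbk2 <- table_backend(tab2, tri)
  expect_error(nbody_decompose(tri, tbk2), "0-2")
})
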