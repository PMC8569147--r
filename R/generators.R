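# Geometry generators: the reference monomer, unrelaxed dimer scans along
# the hydrogen-bond axis, randomly oriented cluster samples for training
# sets, liquid-like periodic boxes, and dimer extraction from boxes by an
# O...O cutoff. All generators are bit-reproducible per seed.

#' Reference (relaxed) water monomer geometry
#'
#' O at the origin, H1 on the x axis at the equilibrium bond length, H2 in
#' the xy plane at the equilibrium angle.
#'
#' @param re equilibrium O-H length, Angstrom.
#' @param thetae equilibrium H-O-H angle, rad.
#' @return A 3x3 coordinate matrix (rows O, H, H).
#' @export
reference_monomer <- function(re = 0.9572, thetae = 104.52 * pi / 180) {
  rbind(c(0, 0, 0),
        c(re, 0, 0),
        c(re * cos(thetae), re * sin(thetae), 0))
}

random_rotation <- function() {
  # uniform rotation via a normalized random quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

place_monomer <- function(origin, rot, jitter_sd = 0) {
  ref <- reference_monomer()
  if (jitter_sd > 0)
    ref <- ref + matrix(stats::rnorm(9, sd = jitter_sd), 3, 3)
  sweep(ref %*% t(rot), 2, origin, `+`)
}

#' Unrelaxed water-dimer scan along the hydrogen-bond axis
#'
#' The donor monomer is fixed at the reference geometry; the acceptor
#' monomer (also rigid at the reference internal geometry) is translated
#' along the donor O-H1 unit vector so that the O(acceptor)...H1(donor)
#' distance equals each grid value exactly. Internal geometries are never
#' altered across the scan.
#'
#' @param r_grid strictly increasing O...H distances, Angstrom (all >= 0.5).
#' @return List of dimer \code{mbpef_cluster}s, each tagged (attribute
#'   \code{tags}) with \code{r_oh} and the resulting \code{r_oo}.
#' @export
generate_dimer_scan <- function(r_grid) {
  if (any(r_grid < 0.5)) stop("scan distances below 0.5 A are not physical")
  if (is.unsorted(r_grid, strictly = TRUE))
    stop("scan grid must be strictly increasing")
  donor <- reference_monomer()
  u <- c(1, 0, 0)                       # donor O-H1 unit vector
  # acceptor: reference monomer rotated so its HOH bisector points along +x
  # (H atoms pointing away from the donor), O at the controlled position
  acc0 <- reference_monomer()
  bis <- (acc0[2, ] + acc0[3, ]) / 2
  bis <- bis / sqrt(sum(bis^2))
  # rotation taking bis -> +x within the xy plane
  ang <- atan2(bis[2], bis[1])
  R <- matrix(c(cos(-ang), -sin(-ang), 0, sin(-ang), cos(-ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  acc0 <- acc0 %*% t(R)
  lapply(r_grid, function(r) {
    oacc <- donor[2, ] + r * u
    cl <- cluster(rbind(donor, sweep(acc0, 2, oacc, `+`)),
                  label = sprintf("scan_r%.3f", r))
    attr(cl, "tags") <- list(r_oh = r,
                             r_oo = sqrt(sum((oacc - donor[1, ])^2)))
    cl
  })
}

#' Sample random water clusters
#'
#' Monomers are placed rigidly with uniform random orientations (random
#' quaternions); each monomer after the first sits at an O-O distance drawn
#' uniformly in \code{[r_min, r_max]} from a randomly chosen anchor monomer.
#' Configurations with any interatomic distance below \code{overlap} are
#' rejected and redrawn. Internal geometries are perturbed by seeded
#' Gaussian displacements (sd \code{jitter_sd}) so 1-body distortion is
#' exercised.
#'
#' @param n_monomers monomers per cluster.
#' @param count number of clusters.
#' @param seed RNG seed.
#' @param r_min,r_max O-O distance bounds, Angstrom (\code{r_min >= 1.5}).
#' @param jitter_sd intramolecular Gaussian jitter, Angstrom.
#' @param overlap minimum allowed interatomic distance, Angstrom.
#' @return List of \code{mbpef_cluster}s.
#' @export
sample_clusters <- function(n_monomers, count, seed = 1L,
                            r_min = 2.4, r_max = 7.0,
                            jitter_sd = 0.02, overlap = 1.2) {
  if (r_min < 1.5) stop("r_min below 1.5 A O-O is unphysical")
  if (r_max <= r_min) stop("r_max must exceed r_min")
  set.seed(seed)
  out <- vector("list", count)
  attempts <- 0L
  made <- 0L
  while (made < count) {
    attempts <- attempts + 1L
    if (attempts > 100L * count + 1000L)
      stop("rejection rate too high; widen [r_min, r_max] or reduce overlap")
    coords <- place_monomer(c(0, 0, 0), random_rotation(), jitter_sd)
    ok <- TRUE
    if (n_monomers > 1) for (i in 2:n_monomers) {
      anchor <- sample.int(i - 1L, 1L)
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      d <- stats::runif(1, r_min, r_max)
      origin <- coords[3 * (anchor - 1L) + 1L, ] + d * dir
      mono <- place_monomer(origin, random_rotation(), jitter_sd)
      d2 <- outer(rowSums(mono^2), rowSums(coords^2), `+`) -
        2 * mono %*% t(coords)
      dmin <- sqrt(max(min(d2), 0))
      if (!is.finite(dmin) || dmin < overlap) { ok <- FALSE; break }
      coords <- rbind(coords, mono)
    }
    if (!ok) next
    made <- made + 1L
    out[[made]] <- cluster(coords, label = sprintf("sample%04d", made))
  }
  out
}

#' Build a liquid-like periodic box of water molecules
#'
#' Molecules are placed at (a subset of) simple-cubic lattice sites with
#' random orientations and a small positional jitter; the box edge follows
#' from the molecule count and the requested mass density.
#'
#' @param n_molecules number of molecules.
#' @param density mass density, g/cm^3.
#' @param seed RNG seed.
#' @param jitter_sd lattice jitter, Angstrom.
#' @return An \code{mbpef_cluster} with a periodic box.
#' @export
generate_liquid_box <- function(n_molecules, density = 0.997, seed = 1L,
                                jitter_sd = 0.1) {
  if (density <= 0) stop("density must be positive")
  set.seed(seed)
  M <- mbpef_constants$molar_mass_water
  V <- n_molecules * M / (0.602214076 * density)   # Angstrom^3
  L <- V^(1 / 3)
  m <- ceiling(n_molecules^(1 / 3))
  # fill sites in checkerboard (parity) order so partial occupancy keeps
  # the nearest-neighbor spacing as large as possible
  grid <- expand.grid(i = 0:(m - 1L), j = 0:(m - 1L), k = 0:(m - 1L))
  grid <- grid[order((grid$i + grid$j + grid$k) %% 2L), ]
  a <- L / m
  coords <- matrix(NA_real_, 3 * n_molecules, 3)
  for (i in seq_len(n_molecules)) {
    ijk <- as.numeric(grid[i, ])
    origin <- (ijk + 0.5) * a + stats::rnorm(3, sd = jitter_sd)
    coords[(3 * i - 2):(3 * i), ] <- place_monomer(origin, random_rotation())
  }
  cluster(coords, label = sprintf("box%d_rho%.3f", n_molecules, density),
          box = periodic_box(L))
}

#' Extract dimers from a periodic box by O...O cutoff
#'
#' Every molecule pair with minimum-image O...O distance strictly below the
#' cutoff is returned as a gas-phase dimer, with the partner molecule
#' unwrapped (shifted by the minimum-image lattice vector as a rigid unit,
#' so no molecule is split across the boundary).
#'
#' @param box_cluster an \code{mbpef_cluster} with a periodic box.
#' @param cutoff O...O cutoff, Angstrom (strict \code{<}).
#' @return List of dimer \code{mbpef_cluster}s; each carries a \code{tags}
#'   attribute with the O...O \code{distance} and the monomer indices.
#' @export
extract_dimers <- function(box_cluster, cutoff = 5.5) {
  if (is.null(box_cluster$box)) stop("extract_dimers needs a periodic box")
  L <- box_cluster$box$L
  n <- box_cluster$n_monomers
  out <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    oi <- box_cluster$coords[3 * (i - 1L) + 1L, ]
    oj <- box_cluster$coords[3 * (j - 1L) + 1L, ]
    d <- oj - oi
    shift <- -L * floor(d / L + 0.5)
    dmin <- sqrt(sum((d + shift)^2))
    if (dmin < cutoff) {
      mi <- box_cluster$coords[(3 * i - 2):(3 * i), ]
      mj <- sweep(box_cluster$coords[(3 * j - 2):(3 * j), ], 2, shift, `+`)
      cl <- cluster(rbind(mi, mj), label = sprintf("dimer_%d_%d", i, j))
      attr(cl, "tags") <- list(distance = dmin, i = i, j = j)
      out[[length(out) + 1L]] <- cl
    }
  }
  out
}
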