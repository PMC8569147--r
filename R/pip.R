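# Permutationally invariant polynomial (PIP) bases for the short-range 2B
# and 3B terms of the potential. Variables are transformed intermolecular
# distances xi_ab = exp(-k * d_ab); the basis is the set of orbit-sums of
# monomials under the full symmetry group (H exchange within each monomer
# and exchange of whole monomers), so every basis function is invariant by
# construction.

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in permutations_of(n - 1L))
    for (pos in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

# all atom-index permutations (1-based, length 3m) of the PIP group
pip_group_elements <- function(m) {
  perms <- permutations_of(m)
  out <- list()
  for (p in perms) {
    for (mask in 0:(2^m - 1)) {
      g <- integer(3 * m)
      for (i in seq_len(m)) {
        swap <- bitwAnd(mask, bitwShiftL(1L, i - 1L)) != 0L
        site_map <- if (swap) c(1L, 3L, 2L) else c(1L, 2L, 3L)
        for (s in 1:3) g[3 * (i - 1L) + s] <- 3L * (p[i] - 1L) + site_map[s]
      }
      out[[length(out) + 1L]] <- g
    }
  }
  out
}

# nondecreasing integer sequences of length 1..degree from 1..nvar
enumerate_multisets <- function(nvar, degree) {
  out <- vector("list", 0)
  rec <- function(prefix, start, left) {
    if (length(prefix) > 0) out[[length(out) + 1L]] <<- prefix
    if (left == 0) return()
    for (v in start:nvar) rec(c(prefix, v), v, left - 1L)
  }
  rec(integer(0), 1L, degree)
  out
}

#' Build a permutationally invariant polynomial basis
#'
#' Constructs the symmetrized polynomial basis for the short-range 2-body
#' (two monomers) or 3-body (three monomers) term. Each variable is an
#' exponentially transformed distance \code{exp(-k d)} between an
#' intermolecular atom pair (intramolecular pairs optionally included);
#' monomials up to the requested total degree are grouped into orbits under
#' the full permutation group (H swap within each monomer plus whole-monomer
#' exchange; group order 8 for two monomers, 48 for three), and each basis
#' function is the orbit sum.
#'
#' @param n_monomers 2 or 3.
#' @param degree maximum total degree of the monomials (>= 1).
#' @param k named numeric vector of range parameters (1/Angstrom) for pair
#'   types \code{OO}, \code{OH}, \code{HH}.
#' @param include_intra include intramolecular pairs as variables.
#' @param purify for 3-body bases, drop monomials that do not couple all
#'   three monomers (their content is 2-body and already representable);
#'   ignored for 2-body bases.
#' @param rin,rout switching window on the oxygen-oxygen distance(s),
#'   Angstrom: the term is at full strength below \code{rin} and zero above
#'   \code{rout}. For 3-body bases the switch is the product of the three
#'   pairwise switches.
#' @return An object of class \code{mbpef_pip_basis}; the number of basis
#'   functions is \code{$norbit}.
#' @export
build_pip_basis <- function(n_monomers, degree,
                            k = c(OO = 0.8, OH = 0.8, HH = 0.8),
                            include_intra = FALSE,
                            purify = n_monomers == 3,
                            rin = if (n_monomers == 2) 5.5 else 2.5,
                            rout = if (n_monomers == 2) 7.0 else 4.5) {
  if (!n_monomers %in% c(2L, 3L)) stop("n_monomers must be 2 or 3")
  if (degree < 1) stop("degree must be >= 1")
  if (rin >= rout || rin <= 0) stop("switch window must satisfy 0 < rin < rout")
  m <- as.integer(n_monomers)
  natom <- 3L * m
  mon_of <- rep(seq_len(m), each = 3L)
  site_of <- rep(1:3, m)                 # 1 = O, 2/3 = H
  # variables: atom pairs
  va <- integer(0); vb <- integer(0)
  for (a in 1:(natom - 1L)) for (b in (a + 1L):natom) {
    inter <- mon_of[a] != mon_of[b]
    if (inter || include_intra) { va <- c(va, a); vb <- c(vb, b) }
  }
  nvar <- length(va)
  nH <- (site_of[va] > 1) + (site_of[vb] > 1)
  ptype <- c("OO", "OH", "HH")[nH + 1L]
  kvec <- unname(k[ptype])
  if (anyNA(kvec)) stop("k must be named with entries OO, OH, HH")
  var_idx <- matrix(0L, natom, natom)
  for (v in seq_len(nvar)) {
    var_idx[va[v], vb[v]] <- v
    var_idx[vb[v], va[v]] <- v
  }
  # group action on variables
  group <- pip_group_elements(m)
  vperm <- lapply(group, function(g) {
    vapply(seq_len(nvar), function(v) {
      w <- var_idx[g[va[v]], g[vb[v]]]
      if (w == 0L) stop("group element maps a variable outside the set")
      w
    }, integer(1))
  })
  # monomials
  monos <- enumerate_multisets(nvar, degree)
  if (purify && m == 3L) {
    keep <- vapply(monos, function(mn) {
      touched <- unique(c(mon_of[va[mn]], mon_of[vb[mn]]))
      length(touched) == m
    }, logical(1))
    monos <- monos[keep]
  }
  if (length(monos) == 0) stop("no monomials survive; increase degree")
  # orbit identification via canonical (lexicographically smallest) image
  canon <- character(length(monos))
  for (i in seq_along(monos)) {
    best <- NULL
    for (vp in vperm) {
      img <- sort(vp[monos[[i]]])
      key <- paste(sprintf("%03d", img), collapse = ",")
      if (is.null(best) || key < best) best <- key
    }
    canon[i] <- best
  }
  orbit_ids <- match(canon, unique(canon))
  # CSR monomial arrays (0-based for C++)
  mono_var <- integer(0); mono_pow <- integer(0)
  mono_ptr <- integer(length(monos) + 1L)
  for (i in seq_along(monos)) {
    tb <- table(monos[[i]])
    mono_var <- c(mono_var, as.integer(names(tb)) - 1L)
    mono_pow <- c(mono_pow, as.integer(tb))
    mono_ptr[i + 1L] <- length(mono_var)
  }
  structure(list(
    nmon = m, nvar = nvar, norbit = max(orbit_ids),
    var_a = va - 1L, var_b = vb - 1L, k = kvec, pair_type = ptype,
    mono_ptr = mono_ptr, mono_var = mono_var, mono_pow = mono_pow,
    orbit = orbit_ids - 1L, degree = as.integer(degree),
    include_intra = include_intra, purify = purify && m == 3L,
    rin = rin, rout = rout,
    group = group, group_order = length(group),
    n_monomials = length(monos)),
    class = "mbpef_pip_basis")
}

#' @export
print.mbpef_pip_basis <- function(x, ...) {
  cat(sprintf(
    "<mbpef_pip_basis: %dB, degree %d, %d variables, %d monomials, %d basis functions, switch (%.2f, %.2f) A>\n",
    x$nmon, x$degree, x$nvar, x$n_monomials, x$norbit, x$rin, x$rout))
  invisible(x)
}

#' Transformed-distance variables for a dimer/trimer geometry
#'
#' @param basis an \code{mbpef_pip_basis}.
#' @param coords local coordinate matrix (6x3 or 9x3, atoms O,H,H per
#'   monomer).
#' @return Numeric vector of \code{exp(-k d)} values, one per variable.
#' @export
pip_xi <- function(basis, coords) {
  a <- basis$var_a + 1L
  b <- basis$var_b + 1L
  d <- sqrt(rowSums((coords[a, , drop = FALSE] -
                     coords[b, , drop = FALSE])^2))
  exp(-basis$k * d)
}

#' Evaluate every symmetrized basis function at a geometry
#'
#' No switching function is applied; this is the raw orbit-sum value used
#' for invariance checks and design matrices.
#'
#' @param basis an \code{mbpef_pip_basis}.
#' @param coords local coordinate matrix (rows O,H,H per monomer).
#' @return Numeric vector of length \code{basis$norbit}.
#' @export
pip_basis_values <- function(basis, coords) {
  as.numeric(pip_orbit_values_cpp(pip_xi(basis, coords), basis))
}

#' Switch factor of a PIP term at a geometry
#'
#' For 2-body bases the quintic switch on the O-O distance; for 3-body
#' bases the product of the three pairwise O-O switches.
#'
#' @param basis an \code{mbpef_pip_basis}.
#' @param coords local coordinates.
#' @return A single switch value in [0, 1].
#' @export
pip_switch <- function(basis, coords) {
  oidx <- 3L * (seq_len(basis$nmon) - 1L) + 1L
  s <- 1
  for (i in seq_len(basis$nmon - 1L))
    for (j in (i + 1L):basis$nmon) {
      r <- sqrt(sum((coords[oidx[i], ] - coords[oidx[j], ])^2))
      s <- s * switching_function(r, basis$rin, basis$rout)$value
    }
  s
}

#' Numerical rank of a PIP basis on random geometries
#'
#' Evaluates the basis at random variable vectors and reports the rank of
#' the resulting design matrix, as a linear-independence diagnostic.
#'
#' @param basis an \code{mbpef_pip_basis}.
#' @param n_points number of random points (default 2x the basis size).
#' @param seed RNG seed.
#' @return List with \code{rank}, \code{norbit} and \code{condition} (ratio
#'   of extreme singular values).
#' @export
pip_basis_rank <- function(basis, n_points = 2L * basis$norbit, seed = 1L) {
  set.seed(seed)
  xis <- matrix(stats::runif(n_points * basis$nvar, 0.05, 0.9),
                n_points, basis$nvar)
  Phi <- pip_design_cpp(xis, basis)
  d <- svd(Phi, nu = 0, nv = 0)$d
  list(rank = sum(d > max(d) * 1e-10), norbit = basis$norbit,
       condition = max(d) / min(d))
}

#' Quintic switching function
#'
#' s(x) = 1 - 10x^3 + 15x^4 - 6x^5 with x = (R - R_in)/(R_out - R_in),
#' clamped to 1 below R_in and 0 above R_out; C^2 at both ends.
#'
#' @param R distance(s), Angstrom.
#' @param R_in,R_out switching window, \code{0 < R_in < R_out}.
#' @return List with vectors \code{value} and \code{derivative} (d s/d R).
#' @export
switching_function <- function(R, R_in, R_out) {
  if (R_in >= R_out) stop("R_in must be smaller than R_out")
  x <- pmin(pmax((R - R_in) / (R_out - R_in), 0), 1)
  s <- 1 - 10 * x^3 + 15 * x^4 - 6 * x^5
  ds <- (-30 * x^2 + 60 * x^3 - 30 * x^4) / (R_out - R_in)
  list(value = s, derivative = ds)
}
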