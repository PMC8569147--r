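# Exact many-body expansion (MBE) of cluster energies over a pluggable
# energy backend. The total energy of an N-monomer system is rewritten as
#   E_N = sum_i eps1B(i) + sum_{i<j} eps2B(i,j) + ... + epsNB(1..N)
# where eps1B(i) is the distortion energy of monomer i relative to the
# relaxed free monomer and every higher term is the part of E(S) not
# attributable to any proper subset of S. Terms are computed bottom-up by
# the recursion eps(S) = E(S) - sum_{T subset S} eps(T); the independent
# inclusion-exclusion form is kept as a cross-check.

#' Construct an energy backend
#'
#' An energy backend is a pure function of geometry evaluating a cluster's
#' total energy, together with the energy of a relaxed isolated monomer
#' (used to convert 1-body terms to distortion energies and total energies
#' to binding energies).
#'
#' @param evaluate function(cluster) returning an energy in kcal/mol.
#' @param monomer_reference_energy energy of a relaxed isolated monomer,
#'   kcal/mol.
#' @param deterministic logical; TRUE if repeated evaluation of the same
#'   geometry is bit-identical.
#' @param label free text.
#' @return An object of class \code{mbpef_backend}.
#' @export
energy_backend <- function(evaluate, monomer_reference_energy = NA_real_,
                           deterministic = TRUE, label = "backend") {
  stopifnot(is.function(evaluate))
  structure(list(evaluate = evaluate,
                 monomer_reference_energy = monomer_reference_energy,
                 deterministic = deterministic, label = label),
            class = "mbpef_backend")
}

#' @export
print.mbpef_backend <- function(x, ...) {
  cat(sprintf("<mbpef_backend '%s', reference monomer energy %s kcal/mol>\n",
              x$label, format(x$monomer_reference_energy)))
  invisible(x)
}

subset_key <- function(idx0) paste(sort(idx0), collapse = "-")

# combn treats a scalar first argument as seq_len(x); guard against that
combn_safe <- function(x, k) {
  if (length(x) == 1L) { if (k == 1L) return(list(x)) else return(list()) }
  utils::combn(x, k, simplify = FALSE)
}

all_subsets <- function(n, max_order) {
  out <- list()
  for (k in seq_len(max_order))
    out <- c(out, utils::combn(n, k, simplify = FALSE))
  out
}

#' Energies of all sub-clusters up to a given order
#'
#' Evaluates the backend once for every non-empty monomer subset of size at
#' most \code{max_order}, at the cluster's fixed geometry (no relaxation).
#' Results are memoised in \code{cache}, so repeated calls with the same
#' cache perform no new evaluations.
#'
#' @param cl an \code{mbpef_cluster}.
#' @param backend an \code{mbpef_backend}.
#' @param max_order highest subset size to evaluate (1..N).
#' @param cache an environment used as a memo table (keys are 0-based sorted
#'   index strings such as \code{"0-2-5"}).
#' @param n_max guard against the 2^N explosion; override deliberately for
#'   larger clusters.
#' @return Named numeric vector of subset energies (kcal/mol).
#' @export
subcluster_energies <- function(cl, backend, max_order = cl$n_monomers,
                                cache = new.env(parent = emptyenv()),
                                n_max = 12L) {
  n <- cl$n_monomers
  if (max_order < 1 || max_order > n)
    stop("max_order must be between 1 and the number of monomers")
  if (n > n_max)
    stop(sprintf("cluster has %d monomers; raise n_max to override the 2^N guard", n))
  subs <- all_subsets(n, max_order)
  out <- numeric(length(subs))
  names(out) <- vapply(subs, function(s) subset_key(s - 1L), character(1))
  for (i in seq_along(subs)) {
    key <- names(out)[i]
    if (!is.null(cache[[key]])) { out[i] <- cache[[key]]; next }
    e <- tryCatch(backend$evaluate(subcluster(cl, subs[[i]])),
                  error = function(err)
                    stop(sprintf("backend failed on subset {%s}: %s", key,
                                 conditionMessage(err)), call. = FALSE))
    cache[[key]] <- e
    out[i] <- e
  }
  out
}

#' Exact n-body decomposition of a cluster energy
#'
#' Computes every n-body term eps^{nB}(S) up to \code{max_order} by the
#' bottom-up recursion; 1-body terms are reported as distortion energies
#' (monomer energy at the cluster geometry minus the relaxed-monomer
#' reference energy of the backend).
#'
#' @inheritParams subcluster_energies
#' @return An object of class \code{mbpef_mbe} with elements \code{terms}
#'   (named numeric, keys as in \code{\link{subcluster_energies}}),
#'   \code{order} (subset size per term), \code{order_sums},
#'   \code{total_reconstructed}, \code{n_monomers}, \code{max_order} and
#'   \code{monomer_reference_energy}.
#' @export
nbody_decompose <- function(cl, backend, max_order = cl$n_monomers,
                            cache = new.env(parent = emptyenv()),
                            n_max = 12L) {
  n <- cl$n_monomers
  E <- subcluster_energies(cl, backend, max_order, cache, n_max)
  subs <- all_subsets(n, max_order)
  keys <- names(E)
  ord <- lengths(subs)
  eps <- numeric(length(subs))   # recursion uses absolute 1-body energies
  names(eps) <- keys
  for (i in order(ord)) {
    s <- subs[[i]]
    if (length(s) == 1L) { eps[i] <- E[i]; next }
    acc <- E[i]
    for (k in seq_len(length(s) - 1L))
      for (t in combn_safe(s, k))
        acc <- acc - eps[[subset_key(t - 1L)]]
    eps[i] <- acc
  }
  ref <- backend$monomer_reference_energy
  if (is.na(ref)) ref <- 0
  eps[ord == 1L] <- eps[ord == 1L] - ref
  order_sums <- vapply(seq_len(max_order),
                       function(k) sum(eps[ord == k]), numeric(1))
  names(order_sums) <- paste0(seq_len(max_order), "B")
  structure(list(terms = eps, order = ord, order_sums = order_sums,
                 total_reconstructed = sum(eps) + n * ref,
                 n_monomers = n, max_order = max_order,
                 monomer_reference_energy = ref),
            class = "mbpef_mbe")
}

#' @export
print.mbpef_mbe <- function(x, ...) {
  cat(sprintf("<mbpef_mbe: N = %d, max order %d>\n", x$n_monomers,
              x$max_order))
  print(round(x$order_sums, 6))
  cat(sprintf("reconstructed total: %.8f kcal/mol\n", x$total_reconstructed))
  invisible(x)
}

#' Inclusion-exclusion n-body terms (independent cross-check)
#'
#' Computes every term directly as
#' eps(S) = sum_{T subseteq S} (-1)^{|S|-|T|} E(T), an arithmetic path
#' independent of the recursion in \code{\link{nbody_decompose}}.
#'
#' @inheritParams subcluster_energies
#' @return Named numeric vector of n-body terms (1-body as distortion).
#' @export
nbody_inclusion_exclusion <- function(cl, backend,
                                      max_order = cl$n_monomers,
                                      cache = new.env(parent = emptyenv()),
                                      n_max = 12L) {
  n <- cl$n_monomers
  E <- subcluster_energies(cl, backend, max_order, cache, n_max)
  subs <- all_subsets(n, max_order)
  eps <- numeric(length(subs))
  names(eps) <- names(E)
  for (i in seq_along(subs)) {
    s <- subs[[i]]
    acc <- 0
    for (k in seq_len(length(s))) {
      sgn <- (-1)^(length(s) - k)
      for (t in combn_safe(s, k))
        acc <- acc + sgn * E[[subset_key(t - 1L)]]
    }
    eps[i] <- acc
  }
  ref <- backend$monomer_reference_energy
  if (is.na(ref)) ref <- 0
  eps[lengths(subs) == 1L] <- eps[lengths(subs) == 1L] - ref
  eps
}

#' Interaction energy of a cluster
#'
#' The total energy minus the energies of the isolated monomers frozen at
#' their in-cluster geometries; equals the sum of all n >= 2 terms of the
#' many-body expansion. For a dimer it equals the 2-body energy exactly.
#'
#' @inheritParams subcluster_energies
#' @return Energy in kcal/mol.
#' @export
interaction_energy <- function(cl, backend) {
  etot <- backend$evaluate(cl)
  e1 <- vapply(seq_len(cl$n_monomers),
               function(i) backend$evaluate(subcluster(cl, i)), numeric(1))
  etot - sum(e1)
}

#' Binding energy of a cluster
#'
#' The total energy minus N times the relaxed-monomer reference energy;
#' equals the interaction energy plus the sum of 1-body distortion energies.
#'
#' @inheritParams subcluster_energies
#' @return Energy in kcal/mol.
#' @export
binding_energy <- function(cl, backend) {
  ref <- backend$monomer_reference_energy
  if (is.na(ref))
    stop("backend has no relaxed-monomer reference energy; binding energy undefined")
  backend$evaluate(cl) - cl$n_monomers * ref
}

#' Partial (truncated) reconstruction of the total energy
#'
#' Sums the many-body expansion through order \code{n} and adds N reference
#' monomer energies, so that \code{n = N} returns the full total energy.
#'
#' @param mbe an \code{mbpef_mbe} from \code{\link{nbody_decompose}}.
#' @param n truncation order.
#' @return Energy in kcal/mol.
#' @export
truncated_reconstruction <- function(mbe, n) {
  if (n > mbe$max_order)
    stop(sprintf("truncation order %d exceeds decomposition max_order %d",
                 n, mbe$max_order))
  sum(mbe$order_sums[seq_len(n)]) +
    mbe$n_monomers * mbe$monomer_reference_energy
}

#' Backend serving externally computed subset energies from a table
#'
#' Decomposes energies computed elsewhere (for example by a quantum-chemistry
#' code): the table maps monomer-subset keys of a parent cluster to energies,
#' and sub-clusters are recognised by matching their oxygen coordinates
#' against the parent's.
#'
#' @param table data frame with columns \code{subset} (sorted 0-based indices
#'   joined by "-", e.g. \code{"0-2-5"}) and \code{energy_kcal_mol}.
#' @param parent an \code{mbpef_cluster} the subsets refer to.
#' @param monomer_reference_energy relaxed-monomer energy, kcal/mol.
#' @return An \code{mbpef_backend}.
#' @export
table_backend <- function(table, parent,
                          monomer_reference_energy = NA_real_) {
  lut <- stats::setNames(table$energy_kcal_mol, table$subset)
  pO <- parent$coords[3 * (seq_len(parent$n_monomers) - 1) + 1, ,
                      drop = FALSE]
  energy_backend(function(cl) {
    idx0 <- vapply(seq_len(cl$n_monomers), function(i) {
      o <- cl$coords[3 * (i - 1) + 1, ]
      j <- which(colSums(abs(t(pO) - o)) < 1e-8)
      if (length(j) != 1)
        stop("sub-cluster monomer not found in the parent cluster")
      j - 1L
    }, integer(1))
    key <- subset_key(idx0)
    if (is.null(lut[[key]]) || is.na(lut[[key]]))
      stop(sprintf("no tabulated energy for subset {%s}", key))
    unname(lut[[key]])
  }, monomer_reference_energy, TRUE, "table")
}
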