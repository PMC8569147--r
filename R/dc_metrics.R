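# Density-corrected DFT energy assembly and the error statistics used for
# benchmarking functionals against coupled-cluster references.
#
# The density-corrected energy evaluates an approximate exchange-correlation
# (XC) functional on the Hartree-Fock density:
#   E_DC = E_HF + (E_XC^approx[n_HF] - E_X^HF)
# and the total error of an approximate functional splits exactly into a
# functional-driven part (approximate vs exact functional on the exact
# density) and a density-driven part (approximate functional on the
# approximate vs exact density).

#' Bundle the component energies entering the DC-DFT combinators
#'
#' All energies in kcal/mol unless \code{hartree = TRUE}, in which case every
#' supplied component is converted with 1 Eh = 627.509474 kcal/mol.
#'
#' @param e_hf Hartree-Fock total energy.
#' @param e_x_hf Hartree-Fock exchange energy.
#' @param e_xc_approx_on_hf approximate XC energy evaluated on the HF density.
#' @param e_xc_approx_on_exact,e_xc_exact_on_exact,e_xc_approx_on_approx
#'   optional XC energies for the error split.
#' @param hartree logical; convert inputs from hartree.
#' @return An object of class \code{mbpef_components}.
#' @export
energy_components <- function(e_hf = NA_real_, e_x_hf = NA_real_,
                              e_xc_approx_on_hf = NA_real_,
                              e_xc_approx_on_exact = NA_real_,
                              e_xc_exact_on_exact = NA_real_,
                              e_xc_approx_on_approx = NA_real_,
                              hartree = FALSE) {
  x <- list(e_hf = e_hf, e_x_hf = e_x_hf,
            e_xc_approx_on_hf = e_xc_approx_on_hf,
            e_xc_approx_on_exact = e_xc_approx_on_exact,
            e_xc_exact_on_exact = e_xc_exact_on_exact,
            e_xc_approx_on_approx = e_xc_approx_on_approx)
  if (hartree) x <- lapply(x, function(v) v * mbpef_constants$hartree_to_kcal)
  structure(x, class = "mbpef_components")
}

need_fields <- function(components, fields) {
  for (f in fields)
    if (is.null(components[[f]]) || is.na(components[[f]]))
      stop(sprintf("component energy '%s' is required but missing", f))
}

#' Density-corrected DFT energy
#'
#' @param components an \code{mbpef_components} (or plain named list) with
#'   \code{e_hf}, \code{e_xc_approx_on_hf} and \code{e_x_hf}.
#' @return Energy in kcal/mol.
#' @export
dc_energy <- function(components) {
  need_fields(components, c("e_hf", "e_xc_approx_on_hf", "e_x_hf"))
  components$e_hf + (components$e_xc_approx_on_hf - components$e_x_hf)
}

#' Functional-driven / density-driven error split
#'
#' Returns the functional-driven error (approximate minus exact functional,
#' both on the exact density), the density-driven error (approximate
#' functional on approximate minus exact density) and their sum, which is
#' the total error by construction (the identity holds exactly, with no
#' floating-point rearrangement).
#'
#' @param components an \code{mbpef_components} with
#'   \code{e_xc_approx_on_exact}, \code{e_xc_exact_on_exact} and
#'   \code{e_xc_approx_on_approx}.
#' @return Named numeric vector \code{c(dE_F, dE_D, dE)} in kcal/mol.
#' @export
error_split <- function(components) {
  need_fields(components, c("e_xc_approx_on_exact", "e_xc_exact_on_exact",
                            "e_xc_approx_on_approx"))
  dEF <- components$e_xc_approx_on_exact - components$e_xc_exact_on_exact
  dED <- components$e_xc_approx_on_approx - components$e_xc_approx_on_exact
  c(dE_F = dEF, dE_D = dED, dE = dEF + dED)
}

#' Construct an error table
#'
#' A table of signed deviations from reference values, one row per system,
#' optionally carrying the molecule count (for per-molecule errors) and a
#' distance descriptor (for distance-binned statistics).
#'
#' @param label character vector of system labels.
#' @param error signed errors, kcal/mol.
#' @param n_molecules integer molecule counts (default 1).
#' @param distance optional numeric descriptor (e.g. O...O distance, Angstrom).
#' @return A data frame of class \code{mbpef_errtab}.
#' @export
error_table <- function(label, error, n_molecules = 1L, distance = NA_real_) {
  if (length(error) < 1) stop("error table needs at least one row")
  if (any(!is.finite(error))) stop("errors must be finite")
  n_molecules <- as.integer(rep_len(n_molecules, length(error)))
  if (any(n_molecules < 1)) stop("n_molecules must be >= 1")
  out <- data.frame(label = as.character(rep_len(label, length(error))),
                    error = as.numeric(error),
                    n_molecules = n_molecules,
                    distance = rep_len(as.numeric(distance), length(error)),
                    stringsAsFactors = FALSE)
  class(out) <- c("mbpef_errtab", class(out))
  out
}

as_errtab <- function(x) {
  if (is.data.frame(x)) {
    if (!"error" %in% names(x))
      stop("error table must have an 'error' column")
    if (nrow(x) == 0) stop("error table is empty")
    return(x)
  }
  error_table(label = paste0("row", seq_along(x)), error = x)
}

#' Mean unsigned error
#'
#' @param tab an error table (from \code{\link{error_table}}) or a numeric
#'   vector of signed errors.
#' @return MUE in kcal/mol.
#' @export
mue <- function(tab) {
  tab <- as_errtab(tab)
  mean(abs(tab$error))
}

#' Per-molecule errors and their MUE
#'
#' @param tab an error table with \code{n_molecules} set.
#' @return List with \code{per_molecule} (signed errors divided by molecule
#'   count, in row order) and \code{mue} (their mean unsigned value).
#' @export
error_per_molecule <- function(tab) {
  tab <- as_errtab(tab)
  if (any(tab$n_molecules == 0)) stop("n_molecules must be nonzero")
  pm <- tab$error / tab$n_molecules
  list(per_molecule = stats::setNames(pm, tab$label), mue = mean(abs(pm)))
}

#' Maximum unsigned error
#'
#' Returns the row with the largest absolute error, reported with its
#' original sign; ties are broken by first occurrence.
#'
#' @param tab an error table or numeric vector.
#' @return List with \code{label} and \code{error}.
#' @export
max_unsigned_error <- function(tab) {
  tab <- as_errtab(tab)
  i <- which.max(abs(tab$error))
  list(label = tab$label[i], error = tab$error[i])
}

#' Distance-binned error statistics
#'
#' Rows are assigned to half-open bins [e_i, e_{i+1}) of the distance
#' descriptor; rows outside every bin are collected in an overflow bin. Both
#' the per-bin MUE and the cumulative MUE up to each right edge (all rows
#' with distance below that edge) are reported.
#'
#' @param tab an error table with the \code{distance} column set.
#' @param bin_edges increasing numeric vector of bin edges, Angstrom.
#' @return Data frame with columns \code{lower}, \code{upper}, \code{n},
#'   \code{mue}, \code{cumulative_n}, \code{cumulative_mue}; the final row is
#'   the overflow bin (upper edge Inf, no cumulative statistics).
#' @export
bin_errors_by_distance <- function(tab, bin_edges) {
  tab <- as_errtab(tab)
  if (any(is.na(tab$distance)))
    stop("every row needs a distance descriptor for binning")
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  nb <- length(bin_edges) - 1L
  lower <- c(bin_edges[seq_len(nb)], bin_edges[nb + 1L])
  upper <- c(bin_edges[-1L], Inf)
  idx <- findInterval(tab$distance, bin_edges, left.open = FALSE)
  # findInterval: 0 below first edge -> overflow; nb+1 at/above last edge
  inbin <- idx >= 1L & idx <= nb
  bin <- ifelse(inbin, idx, nb + 1L)
  bin[tab$distance < bin_edges[1L]] <- nb + 1L
  out <- data.frame(lower = lower, upper = upper, n = 0L, mue = NA_real_,
                    cumulative_n = NA_integer_, cumulative_mue = NA_real_)
  for (b in seq_len(nb + 1L)) {
    rows <- which(bin == b)
    out$n[b] <- length(rows)
    if (length(rows)) out$mue[b] <- mean(abs(tab$error[rows]))
    if (b <= nb) {
      crows <- which(tab$distance >= bin_edges[1L] &
                     tab$distance < bin_edges[b + 1L])
      out$cumulative_n[b] <- length(crows)
      if (length(crows)) out$cumulative_mue[b] <- mean(abs(tab$error[crows]))
    }
  }
  out
}
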