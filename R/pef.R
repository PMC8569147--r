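# The many-body potential energy function (PEF): a pluggable one-body
# monomer surface, short-range 2B/3B PIP terms with switching, permanent
# point-charge electrostatics, Tang-Toennies-damped dispersion, and
# self-consistent Thole-damped induced-dipole polarization supplying all
# n > 3 interaction orders.

PEF_FORMAT_VERSION <- 1L

#' Construct a many-body PEF model
#'
#' Defaults give a complete long-range model (charges, dispersion,
#' polarization) with no PIP terms; fitted 2B/3B PIP terms are attached with
#' \code{\link{set_pip_term}}. The one-body surface is a Morse stretch plus
#' harmonic bend with its minimum (energy zero) at the reference monomer
#' geometry.
#'
#' @param oneb list with Morse well depth \code{D} (kcal/mol), range
#'   \code{a} (1/Angstrom), equilibrium bond length \code{re} (Angstrom),
#'   bend constant \code{ktheta} (kcal/mol/rad^2) and equilibrium angle
#'   \code{thetae} (rad).
#' @param charges named vector \code{c(O=, H=)} of fixed atomic charges, e.
#' @param c6 named vector \code{c(OO=, OH=, HH=)} of dispersion
#'   coefficients, kcal Angstrom^6 / mol.
#' @param delta Tang-Toennies damping scale, 1/Angstrom.
#' @param core fixed (non-fitted) Born-Mayer repulsive core
#'   \code{A exp(-b r)} per pair type: list with named vectors \code{A}
#'   (kcal/mol) and \code{b} (1/Angstrom). The core keeps close-approach
#'   geometries steeply repulsive so the short-range PIP terms are never
#'   evaluated outside the region they were trained on.
#' @param polarization list with O-site polarizability \code{alpha}
#'   (Angstrom^3), damping polarizabilities \code{adampO}, \code{adampH}
#'   (Angstrom^3, used only in the Thole screening lengths), Thole parameter
#'   \code{thole_a}, dipole convergence tolerance \code{tol_debye} (Debye),
#'   \code{maxit}, Jacobi mixing \code{mix}, and \code{enabled}.
#' @param pip2b,pip3b \code{NULL} or lists \code{list(basis =, coef =)} with
#'   an \code{mbpef_pip_basis} and its coefficient vector.
#' @param label free text.
#' @return An object of class \code{mbpef_model}.
#' @export
pef_model <- function(oneb = list(D = 116.09, a = 2.287, re = 0.9572,
                                  ktheta = 75.90,
                                  thetae = 104.52 * pi / 180),
                      charges = c(O = -0.8476, H = 0.4238),
                      c6 = c(OO = 4 * 0.1554 * 3.1656^6, OH = 0, HH = 0),
                      delta = 3.0,
                      core = list(A = c(OO = 2.3e7, OH = 4.0e8, HH = 1.0e8),
                                  b = c(OO = 6.0, OH = 14.0, HH = 14.0)),
                      polarization = list(alpha = 1.0, adampO = 1.0,
                                          adampH = 0.294, thole_a = 0.426,
                                          tol_debye = 1e-8, maxit = 200L,
                                          mix = 0.7, enabled = TRUE),
                      pip2b = NULL, pip3b = NULL, label = "pef") {
  if (polarization$alpha < 0) stop("polarizability must be >= 0")
  for (p in list(pip2b, pip3b))
    if (!is.null(p)) {
      if (!inherits(p$basis, "mbpef_pip_basis"))
        stop("pip terms need an mbpef_pip_basis")
      if (length(p$coef) != p$basis$norbit)
        stop("coefficient length does not match basis size")
      if (any(!is.finite(p$coef))) stop("PIP coefficients must be finite")
    }
  structure(list(format_version = PEF_FORMAT_VERSION, label = label,
                 oneb = oneb, charges = charges, c6 = c6, delta = delta,
                 core = core, polarization = polarization,
                 pip2b = pip2b, pip3b = pip3b),
            class = "mbpef_model")
}

#' @export
print.mbpef_model <- function(x, ...) {
  cat(sprintf("<mbpef_model '%s': q_O = %.3f e, alpha_O = %.3f A^3%s%s%s>\n",
              x$label, x$charges[["O"]], x$polarization$alpha,
              if (!x$polarization$enabled) " (polarization off)" else "",
              if (!is.null(x$pip2b))
                sprintf(", 2B PIP (%d funcs)", x$pip2b$basis$norbit) else "",
              if (!is.null(x$pip3b))
                sprintf(", 3B PIP (%d funcs)", x$pip3b$basis$norbit) else ""))
  invisible(x)
}

#' Attach a fitted PIP term to a model
#'
#' @param model an \code{mbpef_model}.
#' @param order 2 or 3.
#' @param basis the \code{mbpef_pip_basis} the coefficients refer to.
#' @param coef coefficient vector (kcal/mol).
#' @return The updated model.
#' @export
set_pip_term <- function(model, order, basis, coef) {
  term <- list(basis = basis, coef = as.numeric(coef))
  if (order == 2) model$pip2b <- term
  else if (order == 3) model$pip3b <- term
  else stop("order must be 2 or 3")
  pef_model(oneb = model$oneb, charges = model$charges, c6 = model$c6,
            delta = model$delta, core = model$core,
            polarization = model$polarization,
            pip2b = model$pip2b, pip3b = model$pip3b, label = model$label)
}

# --- internal: flatten model for the C++ evaluator ------------------------

model_for_cpp <- function(model) {
  pol <- model$polarization
  list(oneb = model$oneb,
       qO = unname(model$charges[["O"]]), qH = unname(model$charges[["H"]]),
       c6 = unname(model$c6[c("OO", "OH", "HH")]),
       delta = model$delta,
       coreA = unname(model$core$A[c("OO", "OH", "HH")]),
       coreB = unname(model$core$b[c("OO", "OH", "HH")]),
       pol = list(enabled = isTRUE(pol$enabled), alpha = pol$alpha,
                  adampO = pol$adampO, adampH = pol$adampH,
                  thole_a = pol$thole_a,
                  tol = pol$tol_debye * mbpef_constants$debye_to_eA,
                  maxit = as.integer(pol$maxit), mix = pol$mix),
       pip2b = if (is.null(model$pip2b)) NULL else
         list(basis = unclass(model$pip2b$basis), coef = model$pip2b$coef),
       pip3b = if (is.null(model$pip3b)) NULL else
         list(basis = unclass(model$pip3b$basis), coef = model$pip3b$coef))
}

resolve_cutoff <- function(cl, model, cutoff, taper) {
  if (is.null(cl$box)) return(list(L = -1, rc = -1, tw = taper))
  L <- cl$box$L
  rc <- if (is.null(cutoff)) min(9.0, 0.49 * L) else cutoff
  reach <- rc
  if (!is.null(model$pip2b)) reach <- max(reach, model$pip2b$basis$rout)
  if (!is.null(model$pip3b)) reach <- max(reach, model$pip3b$basis$rout)
  if (reach >= L / 2)
    stop(sprintf("cutoff %.3f A must be < L/2 = %.3f A", reach, L / 2))
  list(L = L, rc = rc, tw = taper)
}

#' Evaluate the PEF energy of a cluster or periodic box
#'
#' @param cl an \code{mbpef_cluster} (periodic if it carries a box).
#' @param model an \code{mbpef_model}.
#' @param cutoff electrostatics/dispersion cutoff for periodic systems,
#'   Angstrom (must be < L/2; default \code{min(9, 0.49 L)}); ignored for
#'   gas-phase clusters, which use no cutoff.
#' @param taper width of the smooth taper ending at the cutoff, Angstrom.
#' @param breakdown if TRUE, return the per-term breakdown as well.
#' @return Energy in kcal/mol, or (with \code{breakdown}) a list with
#'   \code{energy}, \code{terms} (1B, 2B-PIP, 3B-PIP, electrostatics,
#'   dispersion, induction) and \code{ind_iterations}.
#' @export
pef_energy <- function(cl, model, cutoff = NULL, taper = 1.0,
                       breakdown = FALSE) {
  geo <- resolve_cutoff(cl, model, cutoff, taper)
  res <- pef_eval_cpp(cl$coords, model_for_cpp(model), geo$L, geo$rc, geo$tw,
                      FALSE)
  if (breakdown) res[c("energy", "terms", "ind_iterations")] else res$energy
}

#' Analytic forces of the PEF
#'
#' @inheritParams pef_energy
#' @return List with \code{energy} (kcal/mol) and \code{forces}
#'   (3N x 3 matrix, kcal/mol/Angstrom; minus the energy gradient).
#' @export
pef_forces <- function(cl, model, cutoff = NULL, taper = 1.0) {
  geo <- resolve_cutoff(cl, model, cutoff, taper)
  res <- pef_eval_cpp(cl$coords, model_for_cpp(model), geo$L, geo$rc, geo$tw,
                      TRUE)
  list(energy = res$energy, forces = res$forces, terms = res$terms)
}

#' Use a PEF model as an energy backend
#'
#' The relaxed-monomer reference energy is exactly zero by construction of
#' the one-body surface.
#'
#' @param model an \code{mbpef_model}.
#' @return An \code{mbpef_backend}.
#' @export
pef_backend <- function(model) {
  energy_backend(function(cl) pef_energy(cl, model),
                 monomer_reference_energy = 0, deterministic = TRUE,
                 label = model$label)
}

#' Tang-Toennies damped dispersion energy
#'
#' E = -sum f6(delta r) C6 / r^6 over the supplied pairs, with
#' f6(x) = 1 - e^{-x} sum_{k=0..6} x^k/k!.
#'
#' @param r distances, Angstrom.
#' @param C6 dispersion coefficients per pair, kcal Angstrom^6/mol
#'   (recycled).
#' @param delta damping scale, 1/Angstrom.
#' @return Total dispersion energy, kcal/mol.
#' @export
dispersion_energy <- function(r, C6, delta) {
  x <- delta * r
  f6 <- 1 - exp(-x) * vapply(x, function(xx) sum(xx^(0:6) / factorial(0:6)),
                             numeric(1))
  sum(-f6 * rep_len(C6, length(r)) / r^6)
}

#' Solve for self-consistent induced dipoles
#'
#' Point polarizable sites in a fixed-charge field, with Thole exponential
#' damping of both the charge-dipole and dipole-dipole interactions.
#' Interactions within the same exclusion group are omitted. The induction
#' energy is -1/2 sum mu_i . E_i^perm, which is non-positive for any
#' geometry.
#'
#' @param sites n x 3 matrix of site positions, Angstrom.
#' @param charges length-n fixed charges, e.
#' @param alpha length-n polarizabilities, Angstrom^3 (0 = not polarizable).
#' @param adamp length-n damping polarizabilities for the Thole screening
#'   length (defaults to \code{alpha} where positive, else 0.294).
#' @param thole_a Thole exponential parameter.
#' @param group integer exclusion-group id per site (e.g. molecule id);
#'   sites sharing a group do not interact.
#' @param tol_debye convergence tolerance on the dipole change, Debye.
#' @param maxit,mix Jacobi iteration controls.
#' @return List with \code{dipoles} (n x 3, Debye), \code{energy}
#'   (kcal/mol), \code{iterations} and \code{converged}.
#' @export
solve_induced_dipoles <- function(sites, charges, alpha, adamp = NULL,
                                  thole_a = 0.426,
                                  group = seq_len(nrow(sites)),
                                  tol_debye = 1e-8, maxit = 200L,
                                  mix = 0.7) {
  sites <- as.matrix(sites)
  n <- nrow(sites)
  if (is.null(adamp)) adamp <- ifelse(alpha > 0, alpha, 0.294)
  res <- induction_generic_cpp(sites, as.numeric(charges), as.numeric(alpha),
                               as.numeric(adamp), as.integer(group), thole_a,
                               tol_debye * mbpef_constants$debye_to_eA,
                               as.integer(maxit), mix)
  if (!res$converged)
    stop(sprintf(paste0("induced-dipole iteration did not converge in %d ",
                        "iterations; reduce alpha or increase Thole damping"),
                 res$iterations))
  list(dipoles = res$dipoles_eA / mbpef_constants$debye_to_eA,
       energy = res$energy, iterations = res$iterations,
       converged = res$converged)
}

# --- model serialization ---------------------------------------------------

flatten_model <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(v) && !is.null(names(v))) out <- c(out, flatten_model(v, key))
    else if (is.null(v)) out[[key]] <- NULL
    else out[[key]] <- v
  }
  out
}

#' Write a PEF model to a structured text file
#'
#' The \code{.mbpef} format is a flat key-value text document: one key per
#' line, numeric arrays space-separated, nested names joined with dots, and
#' a leading \code{format_version} line. Serialization is lossless for all
#' numeric content (values are written with full double precision).
#'
#' @param model an \code{mbpef_model}.
#' @param path output path (conventionally \code{*.mbpef}).
#' @return Invisibly, \code{path}.
#' @export
write_pef_model <- function(model, path) {
  x <- unclass(model)
  x$charges <- as.list(x$charges)
  x$c6 <- as.list(x$c6)
  x$core <- list(A = as.list(x$core$A), b = as.list(x$core$b))
  x$pip2b <- if (is.null(x$pip2b)) NULL else
    c(list(present = 1), basis = list(serializable_basis(x$pip2b$basis)),
      coef = list(x$pip2b$coef))
  x$pip3b <- if (is.null(x$pip3b)) NULL else
    c(list(present = 1), basis = list(serializable_basis(x$pip3b$basis)),
      coef = list(x$pip3b$coef))
  fl <- flatten_model(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(fl)) {
    v <- fl[[key]]
    if (is.character(v)) writeLines(sprintf("%s %s", key, v), con)
    else if (is.logical(v))
      writeLines(sprintf("%s %d", key, as.integer(v)), con)
    else writeLines(paste(key, paste(sprintf("%.17g", v), collapse = " ")),
                    con)
  }
  invisible(path)
}

serializable_basis <- function(b) {
  list(nmon = b$nmon, degree = b$degree,
       include_intra = b$include_intra, purify = b$purify,
       k_OO = b$k[b$pair_type == "OO"][1],
       k_OH = if (any(b$pair_type == "OH")) b$k[b$pair_type == "OH"][1] else 0,
       k_HH = if (any(b$pair_type == "HH")) b$k[b$pair_type == "HH"][1] else 0,
       rin = b$rin, rout = b$rout)
}

#' Read a PEF model written by \code{\link{write_pef_model}}
#'
#' PIP bases are reconstructed deterministically from their defining
#' parameters (monomer count, degree, k, flags), so the round trip is exact.
#' Files with an unknown \code{format_version} are rejected.
#'
#' @param path path to a \code{.mbpef} file.
#' @return An \code{mbpef_model}.
#' @export
read_pef_model <- function(path) {
  lines <- readLines(path)
  kv <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    sp <- regexpr(" ", ln, fixed = TRUE)
    key <- substr(ln, 1, sp - 1)
    val <- substr(ln, sp + 1, nchar(ln))
    num <- suppressWarnings(as.numeric(strsplit(val, "\\s+")[[1]]))
    kv[[key]] <- if (anyNA(num)) val else num
  }
  if (is.null(kv$format_version) || kv$format_version != PEF_FORMAT_VERSION)
    stop(sprintf("unknown model format_version '%s'",
                 paste(kv$format_version, collapse = " ")))
  read_pip <- function(pfx) {
    if (is.null(kv[[paste0(pfx, ".present")]])) return(NULL)
    g <- function(s) kv[[paste0(pfx, ".basis.", s)]]
    basis <- build_pip_basis(
      n_monomers = g("nmon"), degree = g("degree"),
      k = c(OO = g("k_OO"), OH = g("k_OH"), HH = g("k_HH")),
      include_intra = g("include_intra") != 0, purify = g("purify") != 0,
      rin = g("rin"), rout = g("rout"))
    coef <- kv[[paste0(pfx, ".coef")]]
    if (length(coef) != basis$norbit)
      stop("stored coefficients do not match the reconstructed basis")
    list(basis = basis, coef = coef)
  }
  pef_model(
    oneb = list(D = kv$oneb.D, a = kv$oneb.a, re = kv$oneb.re,
                ktheta = kv$oneb.ktheta, thetae = kv$oneb.thetae),
    charges = c(O = kv$charges.O, H = kv$charges.H),
    c6 = c(OO = kv$c6.OO, OH = kv$c6.OH, HH = kv$c6.HH),
    delta = kv$delta,
    core = list(A = c(OO = kv$core.A.OO, OH = kv$core.A.OH,
                      HH = kv$core.A.HH),
                b = c(OO = kv$core.b.OO, OH = kv$core.b.OH,
                      HH = kv$core.b.HH)),
    polarization = list(alpha = kv$polarization.alpha,
                        adampO = kv$polarization.adampO,
                        adampH = kv$polarization.adampH,
                        thole_a = kv$polarization.thole_a,
                        tol_debye = kv$polarization.tol_debye,
                        maxit = as.integer(kv$polarization.maxit),
                        mix = kv$polarization.mix,
                        enabled = kv$polarization.enabled != 0),
    pip2b = read_pip("pip2b"), pip3b = read_pip("pip3b"),
    label = if (is.null(kv$label)) "pef" else as.character(kv$label))
}
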