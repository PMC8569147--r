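# The synthetic reference backend: a deterministic polarizable toy water
# model standing in for an ab initio energy provider. Intramolecular Morse
# stretches and a harmonic bend give a nonzero 1-body (distortion) energy;
# O-O Lennard-Jones plus fixed point charges give pairwise interactions;
# optional self-consistent induced dipoles on the O sites supply genuine
# >= 3-body content. With polarization off the model is strictly pairwise
# additive, which makes many-body truncation tests exact.

#' Construct a toy polarizable water model
#'
#' Parameters are SPC/E-flavoured fixed charges and O-O Lennard-Jones plus
#' a physically scaled O polarizability; the relaxed monomer energy is
#' exactly zero.
#'
#' @param polarization logical; include self-consistent induction.
#' @param D,a,re Morse well depth (kcal/mol), range (1/Angstrom) and
#'   equilibrium O-H length (Angstrom).
#' @param ktheta,thetae harmonic bend constant (kcal/mol/rad^2) and
#'   equilibrium angle (rad).
#' @param qO,qH atomic charges, e (the monomer must be neutral).
#' @param eps,sigma O-O Lennard-Jones parameters (kcal/mol, Angstrom).
#' @param alpha O polarizability, Angstrom^3.
#' @param thole_a Thole exponential damping parameter.
#' @param adampH damping polarizability assigned to H sites for the Thole
#'   screening length, Angstrom^3.
#' @param tol_debye,maxit,mix induced-dipole solver controls.
#' @return An object of class \code{mbpef_toy_model}.
#' @export
toy_water_model <- function(polarization = TRUE,
                            D = 116.09, a = 2.287, re = 0.9572,
                            ktheta = 75.90, thetae = 104.52 * pi / 180,
                            qO = -0.8476, qH = 0.4238,
                            eps = 0.1554, sigma = 3.1656,
                            alpha = 1.0, thole_a = 0.426, adampH = 0.294,
                            tol_debye = 1e-8, maxit = 200L, mix = 0.7) {
  if (abs(qO + 2 * qH) > 1e-12) stop("monomer must be neutral: qO + 2 qH = 0")
  structure(list(polarization = polarization, D = D, a = a, re = re,
                 ktheta = ktheta, thetae = thetae, qO = qO, qH = qH,
                 eps = eps, sigma = sigma, alpha = alpha, thole_a = thole_a,
                 adampO = alpha, adampH = adampH,
                 tol = tol_debye * mbpef_constants$debye_to_eA,
                 maxit = as.integer(maxit), mix = mix),
            class = "mbpef_toy_model")
}

#' @export
print.mbpef_toy_model <- function(x, ...) {
  cat(sprintf("<mbpef_toy_model: qO = %.2f e, LJ eps = %.4f, polarization %s>\n",
              x$qO, x$eps, if (x$polarization) "on" else "off"))
  invisible(x)
}

#' Toy-model energy of a cluster
#'
#' @param cl an \code{mbpef_cluster} (periodic if it carries a box).
#' @param model an \code{mbpef_toy_model}.
#' @param cutoff interaction cutoff for periodic systems (Angstrom, < L/2;
#'   default \code{min(9, 0.49 L)}); gas-phase clusters use no cutoff.
#' @param taper taper width, Angstrom.
#' @param breakdown return the term breakdown too.
#' @return Energy in kcal/mol (or a list when \code{breakdown = TRUE}).
#' @export
toy_energy <- function(cl, model = toy_water_model(), cutoff = NULL,
                       taper = 1.0, breakdown = FALSE) {
  geo <- toy_geo(cl, cutoff, taper)
  res <- toy_eval_cpp(cl$coords, unclass(model), geo$L, geo$rc, geo$tw, FALSE)
  if (breakdown) res[c("energy", "terms", "ind_iterations")] else res$energy
}

#' Toy-model analytic forces
#'
#' @inheritParams toy_energy
#' @return List with \code{energy} and \code{forces} (3N x 3,
#'   kcal/mol/Angstrom).
#' @export
toy_forces <- function(cl, model = toy_water_model(), cutoff = NULL,
                       taper = 1.0) {
  geo <- toy_geo(cl, cutoff, taper)
  res <- toy_eval_cpp(cl$coords, unclass(model), geo$L, geo$rc, geo$tw, TRUE)
  list(energy = res$energy, forces = res$forces, terms = res$terms)
}

toy_geo <- function(cl, cutoff, taper) {
  if (is.null(cl$box)) return(list(L = -1, rc = -1, tw = taper))
  L <- cl$box$L
  rc <- if (is.null(cutoff)) min(9.0, 0.49 * L) else cutoff
  if (rc >= L / 2)
    stop(sprintf("cutoff %.3f A must be < L/2 = %.3f A", rc, L / 2))
  list(L = L, rc = rc, tw = taper)
}

#' Use the toy model as an energy backend
#'
#' @param model an \code{mbpef_toy_model}.
#' @return An \code{mbpef_backend} with reference monomer energy 0.
#' @export
toy_backend <- function(model = toy_water_model()) {
  energy_backend(function(cl) toy_energy(cl, model),
                 monomer_reference_energy = 0, deterministic = TRUE,
                 label = if (model$polarization) "toy-polarizable"
                 else "toy-pairwise")
}
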