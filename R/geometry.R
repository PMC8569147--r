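#' Construct a water monomer
#'
#' A monomer is three atoms in the fixed order O, H, H with Cartesian
#' coordinates in Angstrom.
#'
#' @param coords 3x3 numeric matrix of coordinates (rows O, H, H).
#' @param index integer identity of the monomer within a cluster (0-based).
#' @return An object of class \code{mbpef_monomer}.
#' @export
monomer <- function(coords, index = 0L) {
  coords <- as.matrix(coords)
  if (!all(dim(coords) == c(3L, 3L)) || !is.numeric(coords))
    stop("monomer coordinates must be a 3x3 numeric matrix (rows O,H,H)")
  structure(list(coords = coords, index = as.integer(index)),
            class = "mbpef_monomer")
}

#' Check whether a monomer is physically admissible
#'
#' Both O-H distances must lie in (0.5, 2.0) Angstrom. Violations are
#' reported, not fatal: badly distorted monomers are still representable.
#'
#' @param mon an \code{mbpef_monomer}.
#' @return Logical; attribute \code{"oh_distances"} carries the distances.
#' @export
monomer_is_admissible <- function(mon) {
  d <- c(sqrt(sum((mon$coords[2, ] - mon$coords[1, ])^2)),
         sqrt(sum((mon$coords[3, ] - mon$coords[1, ])^2)))
  ok <- all(d > 0.5 & d < 2.0)
  attr(ok, "oh_distances") <- d
  ok
}

#' Construct a cubic periodic box
#'
#' @param L box edge length in Angstrom; must be positive.
#' @return An object of class \code{mbpef_box}.
#' @export
periodic_box <- function(L) {
  L <- as.numeric(L)
  if (length(L) != 1 || !is.finite(L) || L <= 0)
    stop("box edge length must be a single positive number")
  structure(list(L = L), class = "mbpef_box")
}

#' Construct a cluster of water monomers
#'
#' @param coords numeric matrix (3N x 3) of coordinates, atoms grouped into
#'   O,H,H triplets, or a list of \code{mbpef_monomer} objects.
#' @param label free-text label.
#' @param box optional \code{mbpef_box} (or a single number, taken as the
#'   cubic edge length in Angstrom).
#' @return An object of class \code{mbpef_cluster}.
#' @export
cluster <- function(coords, label = "", box = NULL) {
  if (is.list(coords) && !is.matrix(coords))
    coords <- do.call(rbind, lapply(coords, function(m) m$coords))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3 || nrow(coords) %% 3 != 0 || nrow(coords) < 3)
    stop("cluster coordinates must be a (3N x 3) matrix, N >= 1")
  if (!is.null(box) && !inherits(box, "mbpef_box")) box <- periodic_box(box)
  structure(list(coords = coords, n_monomers = nrow(coords) %/% 3L,
                 label = label, box = box),
            class = "mbpef_cluster")
}

#' @export
print.mbpef_cluster <- function(x, ...) {
  cat(sprintf("<mbpef_cluster: %d water monomer%s%s%s>\n", x$n_monomers,
              if (x$n_monomers == 1) "" else "s",
              if (!is.null(x$box)) sprintf(", cubic box L = %.4f A", x$box$L)
              else "",
              if (nzchar(x$label)) paste0(", '", x$label, "'") else ""))
  invisible(x)
}

#' Extract one monomer from a cluster
#'
#' @param cl an \code{mbpef_cluster}.
#' @param i monomer index, 1-based.
#' @return An \code{mbpef_monomer} (with 0-based \code{index} field).
#' @export
get_monomer <- function(cl, i) {
  if (i < 1 || i > cl$n_monomers) stop("monomer index out of range")
  monomer(cl$coords[(3 * (i - 1) + 1):(3 * i), , drop = FALSE],
          index = i - 1L)
}

#' Build a sub-cluster from a subset of monomer indices
#'
#' Monomer order follows the order of \code{idx}; the box is dropped
#' (sub-cluster energies are evaluated in the gas phase at fixed geometry).
#'
#' @param cl an \code{mbpef_cluster}.
#' @param idx 1-based monomer indices.
#' @return An \code{mbpef_cluster}.
#' @export
subcluster <- function(cl, idx) {
  rows <- as.vector(vapply(idx, function(i) (3 * (i - 1) + 1):(3 * i),
                           integer(3)))
  cluster(cl$coords[rows, , drop = FALSE], label = cl$label)
}

#' Minimum-image displacement in a cubic box
#'
#' Each component of \code{r2 - r1} is wrapped into [-L/2, L/2).
#'
#' @param r1,r2 numeric length-3 vectors (Angstrom).
#' @param box an \code{mbpef_box} or edge length.
#' @return Length-3 displacement vector.
#' @export
min_image_displacement <- function(r1, r2, box) {
  L <- if (inherits(box, "mbpef_box")) box$L else as.numeric(box)
  d <- r2 - r1
  d - L * floor(d / L + 0.5)
}

#' Oxygen-oxygen distance between two monomers
#'
#' @param monomer_a,monomer_b \code{mbpef_monomer} objects.
#' @param box optional \code{mbpef_box}; if given, the minimum-image
#'   convention is applied.
#' @return Distance in Angstrom.
#' @export
oo_distance <- function(monomer_a, monomer_b, box = NULL) {
  a <- monomer_a$coords[1, ]
  b <- monomer_b$coords[1, ]
  if (is.null(box)) sqrt(sum((a - b)^2))
  else sqrt(sum(min_image_displacement(a, b, box)^2))
}

#' Construct a trajectory
#'
#' @param frames list of frames; each frame is a list with elements
#'   \code{cluster} (an \code{mbpef_cluster}), optional \code{velocities}
#'   (3N x 3 matrix, Angstrom/ps), optional \code{time} (ps) and arbitrary
#'   scalar tags.
#' @return An object of class \code{mbpef_trajectory}.
#' @export
trajectory <- function(frames) {
  if (length(frames) == 0) stop("trajectory needs at least one frame")
  n <- frames[[1]]$cluster$n_monomers
  for (f in frames)
    if (f$cluster$n_monomers != n)
      stop("all trajectory frames must have the same monomer count")
  structure(list(frames = frames, n_monomers = n),
            class = "mbpef_trajectory")
}

#' @export
print.mbpef_trajectory <- function(x, ...) {
  cat(sprintf("<mbpef_trajectory: %d frames, %d monomers>\n",
              length(x$frames), x$n_monomers))
  invisible(x)
}
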