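# Readers/writers for standard and extended (tagged comment line) XYZ.
# Tags recognised on the comment line: key=value pairs, e.g. energy (kcal/mol),
# box (Angstrom, cubic edge), time (ps). Atoms are grouped into O,H,H triplets
# in file order; H atoms are never re-ordered.

parse_tags <- function(line) {
  out <- list()
  if (!nzchar(trimws(line))) return(out)
  for (tok in strsplit(trimws(line), "\\s+")[[1]]) {
    if (!grepl("=", tok, fixed = TRUE)) next
    kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) next
    val <- suppressWarnings(as.numeric(kv[2]))
    out[[kv[1]]] <- if (is.na(val)) kv[2] else val
  }
  out
}

format_tags <- function(tags) {
  if (length(tags) == 0) return("")
  paste(vapply(names(tags), function(k) {
    v <- tags[[k]]
    if (is.numeric(v)) sprintf("%s=%.10g", k, v) else sprintf("%s=%s", k, v)
  }, character(1)), collapse = " ")
}

#' Read clusters from an (extended) XYZ file
#'
#' Multi-frame files are supported; atoms are grouped into water monomers as
#' consecutive O,H,H triplets in file order. The comment line may carry
#' \code{key=value} tags; \code{box} is interpreted as a cubic box edge and
#' attached to the cluster, all tags are returned as frame metadata.
#'
#' @param path file path.
#' @param water_mode if TRUE (default), require the atom count of every frame
#'   to be divisible by 3 and each triplet to be O,H,H.
#' @return A list of \code{mbpef_cluster} objects; each has a \code{tags}
#'   attribute with the parsed comment-line tags.
#' @export
read_xyz <- function(path, water_mode = TRUE) {
  lines <- readLines(path)
  # drop trailing blank lines
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) == 0) stop("no frames in XYZ file '", path, "'")
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    frame <- frame + 1L
    if (is.na(nat) || nat <= 0)
      stop(sprintf("line %d: expected an atom count, got '%s'", i, lines[i]))
    if (water_mode && nat %% 3 != 0)
      stop(sprintf("frame %d: atom count %d not divisible by 3", frame, nat))
    if (i + 1L + nat > length(lines))
      stop(sprintf("frame %d: truncated (expected %d atom lines)", frame, nat))
    tags <- parse_tags(lines[i + 1L])
    coords <- matrix(NA_real_, nat, 3)
    elems <- character(nat)
    for (a in seq_len(nat)) {
      ln <- i + 1L + a
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(tok) < 4)
        stop(sprintf("line %d: malformed atom row '%s'", ln, lines[ln]))
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(xyz))
        stop(sprintf("line %d: non-numeric coordinate in '%s'", ln, lines[ln]))
      elems[a] <- tok[1]
      coords[a, ] <- xyz
    }
    if (water_mode) {
      el <- toupper(substr(elems, 1, 1))
      bad <- which(el != rep(c("O", "H", "H"), nat / 3))
      if (length(bad))
        stop(sprintf("frame %d: atom %d (line %d) breaks the O,H,H pattern",
                     frame, bad[1], i + 1L + bad[1]))
    }
    box <- if (!is.null(tags$box)) periodic_box(tags$box) else NULL
    cl <- cluster(coords, label = sprintf("frame%d", frame), box = box)
    attr(cl, "tags") <- tags
    out[[frame]] <- cl
    i <- i + 2L + nat
  }
  out
}

#' Write clusters to an (extended) XYZ file
#'
#' Coordinates are written with 6 decimal places; tags are serialised as
#' space-separated \code{key=value} pairs on the comment line. A cluster's
#' box is written as a \code{box=} tag automatically.
#'
#' @param clusters a single \code{mbpef_cluster} or a list of them.
#' @param path output file path.
#' @param tags a named list of tags applied to every frame, or a list of such
#'   lists (one per frame).
#' @return Invisibly, \code{path}.
#' @export
write_xyz <- function(clusters, path, tags = NULL) {
  if (inherits(clusters, "mbpef_cluster")) clusters <- list(clusters)
  if (length(clusters) == 0) stop("no clusters to write")
  per_frame <- !is.null(tags) && length(tags) == length(clusters) &&
    is.null(names(tags))
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_along(clusters)) {
    cl <- clusters[[fi]]
    tg <- if (per_frame) tags[[fi]] else tags
    if (is.null(tg)) tg <- list()
    if (!is.null(cl$box) && is.null(tg$box)) tg$box <- cl$box$L
    nat <- nrow(cl$coords)
    writeLines(as.character(nat), con)
    writeLines(format_tags(tg), con)
    el <- rep(c("O", "H", "H"), cl$n_monomers)
    writeLines(sprintf("%s %14.6f %14.6f %14.6f", el, cl$coords[, 1],
                       cl$coords[, 2], cl$coords[, 3]), con)
  }
  invisible(path)
}

#' Write a trajectory to extended XYZ
#'
#' Frame times are written as \code{time=} tags; per-frame scalar tags (for
#' example \code{energy}) are preserved.
#'
#' @param traj an \code{mbpef_trajectory}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_trajectory_xyz <- function(traj, path) {
  tags <- lapply(traj$frames, function(f) {
    tg <- f$tags
    if (is.null(tg)) tg <- list()
    if (!is.null(f$time)) tg$time <- f$time
    tg
  })
  write_xyz(lapply(traj$frames, `[[`, "cluster"), path, tags = tags)
}
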