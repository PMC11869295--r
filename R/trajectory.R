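## Particle-trajectory container and text-format readers/writers for the
## ensemble statistics. Coordinates are Angstrom; boxes are orthorhombic
## with the origin at the box center, so the membrane midplane sits at
## z = 0 by convention.

#' Construct a particle trajectory
#'
#' @param coords numeric array `n_atoms x 3 x n_frames` (a matrix is
#'   treated as a single frame).
#' @param species character vector of length `n_atoms` (atom/species
#'   labels).
#' @param box length-3 orthorhombic box dimensions, Angstrom.
#' @param axis membrane-normal axis: `"x"`, `"y"` or `"z"`.
#' @return a `particle_trajectory`.
#' @export
particle_trajectory <- function(coords, species, box, axis = "z") {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3,
            length(species) == dim(coords)[1])
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) stop("box must be positive length-3")
  axis <- match.arg(axis, c("x", "y", "z"))
  structure(list(coords = coords, species = as.character(species),
                 box = box, axis = axis),
            class = "particle_trajectory")
}

#' @export
print.particle_trajectory <- function(x, ...) {
  cat(sprintf("<particle_trajectory> %d atoms, %d frames, box %.1f x %.1f x %.1f A\n",
              dim(x$coords)[1], dim(x$coords)[3], x$box[1], x$box[2], x$box[3]))
  cat("  species:", paste(utils::head(unique(x$species), 6), collapse = " "),
      if (length(unique(x$species)) > 6) "..." else "", "\n")
  invisible(x)
}

.axis_index <- function(axis) match(axis, c("x", "y", "z"))

.select_species <- function(traj, species) {
  sel <- traj$species %in% species
  if (!any(sel)) stop("empty species selection: ", paste(species, collapse = ","))
  sel
}

## minimum-image displacement under an orthorhombic box
.min_image <- function(d, box) {
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' Read a multi-frame XYZ trajectory
#'
#' Plain-text XYZ: per frame an atom count line, a comment line, then
#' `species x y z` rows. All frames must contain the same atoms.
#'
#' @param file path.
#' @param box length-3 box dimensions (XYZ carries none).
#' @param axis membrane-normal axis.
#' @return a `particle_trajectory`.
#' @export
read_xyz <- function(file, box, axis = "z") {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  pos <- 1L
  frames <- list()
  species <- NULL
  while (pos <= length(lines)) {
    n <- as.integer(trimws(lines[pos]))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", pos)
    block <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    sp <- vapply(parts, `[[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(species)) species <- sp
    else if (!identical(sp, species)) stop("inconsistent atoms across frames")
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + n
  }
  coords <- array(unlist(frames), c(length(species), 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  particle_trajectory(coords, species, box, axis)
}

#' Write a trajectory as multi-frame XYZ
#' @param traj a `particle_trajectory`.
#' @param file output path.
#' @export
write_xyz <- function(traj, file) {
  con <- file(file, "w")
  on.exit(close(con))
  na <- dim(traj$coords)[1]
  for (f in seq_len(dim(traj$coords)[3])) {
    writeLines(c(as.character(na), sprintf("frame %d", f)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$species,
                       traj$coords[, 1, f], traj$coords[, 2, f],
                       traj$coords[, 3, f]), con)
  }
  invisible(file)
}

#' Read a (multi-model) PDB file as a particle trajectory
#'
#' Uses the standard PDB reader from bio3d; MODEL blocks become frames and
#' element/atom names become species labels.
#'
#' @param file path to a PDB file.
#' @param box length-3 box dimensions (taken from CRYST1 when present).
#' @param axis membrane-normal axis.
#' @return a `particle_trajectory`.
#' @export
read_pdb_frames <- function(file, box = NULL, axis = "z") {
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  xyz <- pdb$xyz
  n_frames <- nrow(xyz)
  na <- ncol(xyz) / 3
  coords <- array(NA_real_, c(na, 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  if (is.null(box)) {
    cr <- grep("^CRYST1", readLines(file), value = TRUE)
    if (length(cr)) {
      box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                          substr(cr[1], 25, 33)))
    } else {
      stop("no CRYST1 record; supply `box` explicitly")
    }
  }
  particle_trajectory(coords, pdb$atom$elety, box, axis)
}
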