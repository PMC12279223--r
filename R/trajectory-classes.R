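#' Secondary-structure trajectory
#'
#' A frames x residues matrix of single-character DSSP codes with the time
#' spacing between saved frames.  The DSSP alphabet is
#' `H G I E B T S C ~` (`~` being the coil synonym some tools emit).
#'
#' @param codes Character matrix (frames x residues) of single DSSP
#'   characters, or a character vector of per-frame strings.
#' @param frame_interval Time between saved frames, in ns.
#' @param trajectory_id Optional label.
#' @return An object of class `"ss_trajectory"`.
#' @export
ss_trajectory <- function(codes, frame_interval = 1, trajectory_id = "traj") {
  if (is.character(codes) && is.null(dim(codes))) {
    nc <- unique(nchar(codes))
    if (length(nc) != 1)
      stop("ragged frame strings: lengths ", paste(nc, collapse = ", "))
    codes <- do.call(rbind, strsplit(codes, ""))
  }
  stopifnot(is.matrix(codes), is.character(codes))
  if (nrow(codes) < 1) stop("trajectory must contain at least one frame")
  bad <- setdiff(unique(as.vector(codes)), DSSP_CODES)
  if (length(bad))
    stop("unknown DSSP code(s): ", paste(sQuote(bad), collapse = ", "))
  stopifnot(is.numeric(frame_interval), frame_interval > 0)
  structure(list(codes = unname(codes),
                 frame_interval = frame_interval,
                 trajectory_id = trajectory_id),
            class = "ss_trajectory")
}

#' @export
print.ss_trajectory <- function(x, ...) {
  cat(sprintf("ss_trajectory '%s': %d frames x %d residues, %g ns/frame\n",
              x$trajectory_id, nrow(x$codes), ncol(x$codes),
              x$frame_interval))
  invisible(x)
}

#' @export
dim.ss_trajectory <- function(x) dim(x$codes)

n_frames <- function(traj) nrow(traj$codes)
n_residues <- function(traj) ncol(traj$codes)

#' Coordinate ensemble
#'
#' Frames x atoms x 3 coordinates (nm) plus per-atom metadata.  Atom roles
#' (`backbone`/`sidechain`) and heavy-atom flags drive the contact,
#' hydrogen-bond and order-parameter analyses.
#'
#' @param coordinates Numeric array `frames x atoms x 3`, in nm.
#' @param atoms data.frame with one row per atom and columns `atom_name`,
#'   `residue_index` (1-based), `chain_id`, `element`, `is_heavy`, `role`
#'   (`"backbone"` or `"sidechain"`).  Missing `element`/`is_heavy`/`role`
#'   columns are derived from `atom_name`.
#' @return An object of class `"coord_ensemble"`.
#' @export
coord_ensemble <- function(coordinates, atoms) {
  if (length(dim(coordinates)) == 2)
    coordinates <- array(coordinates,
                         dim = c(1, nrow(coordinates), ncol(coordinates)))
  stopifnot(length(dim(coordinates)) == 3, dim(coordinates)[3] == 3)
  if (!all(is.finite(coordinates))) stop("coordinates must be finite")
  stopifnot(is.data.frame(atoms),
            all(c("atom_name", "residue_index", "chain_id") %in%
                  names(atoms)))
  if (nrow(atoms) != dim(coordinates)[2])
    stop("atom table has ", nrow(atoms), " rows but coordinates have ",
         dim(coordinates)[2], " atoms")
  if (is.null(atoms$element))
    atoms$element <- .element_from_name(atoms$atom_name)
  if (is.null(atoms$is_heavy)) atoms$is_heavy <- atoms$element != "H"
  if (is.null(atoms$role))
    atoms$role <- ifelse(atoms$atom_name %in% BACKBONE_ATOMS,
                         "backbone", "sidechain")
  stopifnot(all(atoms$role %in% c("backbone", "sidechain")),
            all(atoms$residue_index >= 1))
  structure(list(coordinates = coordinates, atoms = atoms),
            class = "coord_ensemble")
}

## Element inferred from a PDB-style atom name: strip digits/primes, take the
## leading letter (handles "CA", "NE2", "HE21", "1HG1").
.element_from_name <- function(name) {
  core <- sub("^[0-9']+", "", name)
  substr(core, 1, 1)
}

#' @export
print.coord_ensemble <- function(x, ...) {
  d <- dim(x$coordinates)
  cat(sprintf(
    "coord_ensemble: %d frame(s), %d atoms (%d heavy), chains %s\n",
    d[1], d[2], sum(x$atoms$is_heavy),
    paste(unique(x$atoms$chain_id), collapse = ",")))
  invisible(x)
}

#' @export
dim.coord_ensemble <- function(x) dim(x$coordinates)

#' Resolve an atom selection on a coordinate ensemble
#'
#' @param coords A [coord_ensemble()].
#' @param chain Chain id (or `NULL` for all chains).
#' @param residues Residue indices or a [region()] (or `NULL` for all).
#' @param heavy_only Keep heavy atoms only.
#' @param atom_names Optional atom-name filter (e.g. `"CA"`).
#' @return Integer vector of atom indices.
#' @export
atom_select <- function(coords, chain = NULL, residues = NULL,
                        heavy_only = TRUE, atom_names = NULL) {
  a <- coords$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain_id %in% chain
  if (!is.null(residues))
    keep <- keep & a$residue_index %in% region_residues(residues)
  if (heavy_only) keep <- keep & a$is_heavy
  if (!is.null(atom_names)) keep <- keep & a$atom_name %in% atom_names
  which(keep)
}
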