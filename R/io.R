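#' Read a secondary-structure matrix
#'
#' The canonical plain-text layout is one line per frame, one DSSP character
#' per residue.  A CSV dialect (one single-character cell per residue, no
#' header) is also accepted and auto-detected from the presence of commas.
#'
#' @param path Input file.
#' @param frame_interval Time between frames (ns).
#' @param trajectory_id Label; defaults to the file name.
#' @return An [ss_trajectory()].
#' @export
read_ss_matrix <- function(path, frame_interval = 1,
                           trajectory_id = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty secondary-structure file: ", path)
  if (any(grepl(",", lines, fixed = TRUE))) {
    rows <- strsplit(lines, ",", fixed = TRUE)
    rows <- lapply(rows, trimws)
  } else {
    rows <- strsplit(lines, "")
  }
  len <- lengths(rows)
  if (length(unique(len)) != 1)
    stop("ragged secondary-structure matrix in ", path, ": line(s) ",
         paste(which(len != len[1]), collapse = ", "),
         " differ in length from line 1")
  codes <- do.call(rbind, rows)
  bad <- which(!codes %in% DSSP_CODES)
  if (length(bad)) {
    ln <- ((bad[1] - 1) %% nrow(codes)) + 1
    stop("unknown DSSP code ", sQuote(codes[bad[1]]), " on line ", ln,
         " of ", path)
  }
  ss_trajectory(codes, frame_interval = frame_interval,
                trajectory_id = trajectory_id)
}

#' Write a secondary-structure matrix
#'
#' Plain-text layout accepted by [read_ss_matrix()] (one line per frame).
#'
#' @param traj An [ss_trajectory()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ss_matrix <- function(traj, path) {
  stopifnot(inherits(traj, "ss_trajectory"))
  writeLines(apply(traj$codes, 1, paste, collapse = ""), path)
  invisible(path)
}

#' Read a coordinate ensemble
#'
#' Multi-model PDB files are read through [bio3d::read.pdb()]; every MODEL
#' becomes one frame.  Coordinates are converted from Angstrom to nm on
#' read, so all package cutoffs (0.6 nm contacts, 0.35 nm hydrogen bonds)
#' apply directly.
#'
#' @param path Input file.
#' @param format Only `"pdb"` is built in; trajectory formats require
#'   conversion to multi-model PDB upstream.
#' @return A [coord_ensemble()].
#' @export
read_coordinates <- function(path, format = "pdb") {
  if (!identical(format, "pdb"))
    stop("unsupported coordinate format '", format,
         "'; convert to multi-model PDB")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  xyz <- pdb$xyz                      # models x 3N matrix, Angstrom
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_at <- nrow(at)
  n_fr <- nrow(xyz)
  coords <- array(NA_real_, dim = c(n_fr, n_at, 3))
  for (f in seq_len(n_fr)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    coords[f, , ] <- m / 10           # Angstrom -> nm
  }
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  ## residue_index: 1-based rank of (chain, resno) in file order
  key <- paste(chain, at$resno)
  resi <- match(key, unique(key))
  atoms <- data.frame(atom_name = at$elety,
                      residue_index = resi,
                      chain_id = chain,
                      stringsAsFactors = FALSE)
  coord_ensemble(coords, atoms)
}

#' Write a coordinate ensemble as a multi-model PDB
#'
#' Emits one MODEL block per frame with coordinates converted back to
#' Angstrom; the output is readable by [read_coordinates()] and standard
#' structure viewers.  Residues are written as UNK unless a sequence is
#' supplied.
#'
#' @param coords A [coord_ensemble()].
#' @param path Output PDB file.
#' @param sequence Optional amino-acid string giving residue identities.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(coords, path, sequence = NULL) {
  stopifnot(inherits(coords, "coord_ensemble"))
  a <- coords$atoms
  res3 <- rep("UNK", max(a$residue_index))
  if (!is.null(sequence)) {
    aa <- strsplit(toupper(sequence), "")[[1]]
    res3 <- bio3d::aa123(aa)
  }
  ## per-chain residue numbering restarting at 1
  resno <- stats::ave(a$residue_index, a$chain_id,
                      FUN = function(r) match(r, unique(r)))
  con <- file(path, "w")
  on.exit(close(con))
  nf <- dim(coords$coordinates)[1]
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL %8d", f), con)
    xyz <- coords$coordinates[f, , , drop = TRUE] * 10
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)),
      ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name), a$atom_name),
      res3[a$residue_index], a$chain_id, resno,
      xyz[, 1], xyz[, 2], xyz[, 3], a$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a chemical-shift table
#'
#' CSV with mandatory columns `residue_index`, `residue_type`, `delta_CA`,
#' `delta_CB` and optional `ssp_score`.  Shifts are in ppm; `delta_CB` may
#' be empty for glycine.
#'
#' @param path CSV file.
#' @return A data.frame of class `"shift_table"`, sorted by residue.
#' @export
read_shift_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue_index", "residue_type", "delta_CA", "delta_CB")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("shift table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$residue_index))
    stop("duplicate residue_index in ", path)
  df <- df[order(df$residue_index), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("shift_table", "data.frame")
  df
}

#' Read a hydrogen-bond event table
#'
#' CSV with columns `frame`, `donor_residue`, `donor_role`, `donor_atom`,
#' `hydrogen_atom`, `acceptor_residue`, `acceptor_role`, `acceptor_atom`.
#'
#' @param path CSV file.
#' @return A data.frame of class `"hbond_table"`.
#' @export
read_hbond_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "donor_residue", "donor_role", "donor_atom",
            "hydrogen_atom", "acceptor_residue", "acceptor_role",
            "acceptor_atom")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("hbond table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  ok <- df$donor_role %in% c("backbone", "sidechain") &
    df$acceptor_role %in% c("backbone", "sidechain")
  if (!all(ok))
    stop("invalid role on row(s) ", paste(which(!ok), collapse = ", "),
         " of ", path)
  class(df) <- c("hbond_table", "data.frame")
  df
}

#' Write an analysis result to disk
#'
#' Matrix-like results (SS-maps, contact maps, PMFs) are written as labeled
#' CSV matrices; tabular results as CSV; list-like results (Monte Carlo
#' summaries, association traces) as JSON.
#'
#' @param obj Result object.
#' @param path Output file.
#' @param ... Unused.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path, ...) UseMethod("write_results")

#' @export
write_results.ss_map <- function(obj, path, ...) {
  m <- obj$P
  dimnames(m) <- list(residue = paste0("res", seq_len(nrow(m))),
                      length = paste0("L", seq_len(ncol(m))))
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' @export
write_results.contact_map_result <- function(obj, path, ...) {
  m <- obj$P
  dimnames(m) <- list(paste0("res", seq_len(nrow(m))),
                      paste0("res", seq_len(ncol(m))))
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' @export
write_results.data.frame <- function(obj, path, ...) {
  utils::write.csv(obj, path, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.list <- function(obj, path, ...) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back an SS-map written by [write_results()]
#' @param path CSV file.
#' @return An object of class `"ss_map"` (probability matrix only).
#' @export
read_ss_map <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  structure(list(P = unname(m), n_frames = NA_integer_), class = "ss_map")
}
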