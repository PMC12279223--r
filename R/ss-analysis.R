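#' Per-residue secondary-structure fraction
#'
#' Fraction of frames in which each residue's DSSP code belongs to `codes`.
#' "Alpha-helical" defaults to DSSP `H` only (3-10 and pi helices are not
#' counted unless requested).
#'
#' @param traj An [ss_trajectory()].
#' @param codes DSSP codes counted as a match (default `"H"`).
#' @return Numeric vector, one fraction per residue.
#' @export
ss_fraction <- function(traj, codes = "H") {
  stopifnot(inherits(traj, "ss_trajectory"))
  if (!length(codes)) stop("empty code set")
  colMeans(matrix(traj$codes %in% codes, nrow = n_frames(traj)))
}

#' Mean helicity profile across an ensemble of trajectories
#'
#' Per-residue mean of the per-trajectory fractions and the standard error
#' of the mean across trajectories (the convention used when averaging over
#' independent simulation replicas).
#'
#' @param trajs List of [ss_trajectory()] objects with equal residue counts.
#' @param codes DSSP codes counted as a match (default `"H"`).
#' @return A data.frame of class `"helicity_profile"` with columns
#'   `residue`, `mean`, `sem`, and attribute `n_trajectories`.
#' @export
ss_fraction_ensemble <- function(trajs, codes = "H") {
  if (inherits(trajs, "ss_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1)
  nres <- vapply(trajs, n_residues, integer(1))
  if (length(unique(nres)) != 1)
    stop("trajectories have mismatched residue counts: ",
         paste(unique(nres), collapse = ", "))
  fr <- vapply(trajs, ss_fraction, numeric(nres[1]), codes = codes)
  fr <- matrix(fr, nrow = nres[1])
  m <- rowMeans(fr)
  if (ncol(fr) == 1) {
    warning("single trajectory: standard errors reported as 0")
    sem <- rep(0, nres[1])
  } else {
    sem <- apply(fr, 1, stats::sd) / sqrt(ncol(fr))
  }
  out <- data.frame(residue = seq_len(nres[1]), mean = m, sem = sem)
  attr(out, "n_trajectories") <- length(trajs)
  class(out) <- c("helicity_profile", "data.frame")
  out
}

#' Helical-segment cooperativity map (SS-map)
#'
#' For every frame, maximal contiguous runs of helical residues are
#' enumerated; `P[i, L]` is the fraction of frames in which residue `i`
#' belongs to a run of exactly length `L`.  Summing over `L` recovers each
#' residue's helical fraction exactly, which is the conservation law the
#' map is tested against.  With `cumulative = TRUE` the map instead reports
#' membership in runs of length at least `L`.
#'
#' @param trajs One [ss_trajectory()] or a list (frames are pooled).
#' @param codes DSSP codes treated as helical (default `"H"`).
#' @param cumulative Report P(run length >= L) instead of exact length.
#' @return An object of class `"ss_map"`: list with the `residues x lengths`
#'   probability matrix `P`, `n_frames`, and `cumulative` flag.
#' @export
ss_map <- function(trajs, codes = "H", cumulative = FALSE) {
  if (inherits(trajs, "ss_trajectory")) trajs <- list(trajs)
  nres <- unique(vapply(trajs, n_residues, integer(1)))
  if (length(nres) != 1)
    stop("trajectories have mismatched residue counts")
  counts <- matrix(0, nrow = nres, ncol = nres)
  total <- 0L
  for (tr in trajs) {
    hel <- matrix(tr$codes %in% codes, nrow = n_frames(tr))
    total <- total + nrow(hel)
    for (f in seq_len(nrow(hel))) {
      r <- rle(hel[f, ])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        L <- r$lengths[k]
        counts[starts[k]:ends[k], L] <- counts[starts[k]:ends[k], L] + 1
      }
    }
  }
  P <- counts / total
  if (cumulative)
    P <- t(apply(P, 1, function(row) rev(cumsum(rev(row)))))
  structure(list(P = P, n_frames = total, cumulative = cumulative),
            class = "ss_map")
}

#' @export
print.ss_map <- function(x, ...) {
  cat(sprintf("ss_map: %d residues, %d frames%s; max P = %.3f\n",
              nrow(x$P), x$n_frames,
              if (x$cumulative) " (cumulative >= L)" else "",
              max(x$P)))
  invisible(x)
}

#' Secondary chemical-shift difference (SCSD)
#'
#' `SCSD_i = (dCA_i - dCA_rc) - (dCB_i - dCB_rc)` in ppm, relative to a
#' random-coil reference keyed by residue type.  Positive values indicate
#' helix.  Glycine (no Cbeta) uses the Calpha term only and is flagged in
#' the `ca_only` column rather than dropped, preserving profile continuity.
#'
#' @param shifts A shift table ([read_shift_table()] or equivalent
#'   data.frame).
#' @param reference Random-coil reference table (columns `residue_type`,
#'   `ca_rc`, `cb_rc`); default [RANDOM_COIL_SHIFTS].
#' @return data.frame with columns `residue_index`, `residue_type`, `scsd`,
#'   `ca_only`.
#' @export
scsd <- function(shifts, reference = RANDOM_COIL_SHIFTS) {
  stopifnot(is.data.frame(shifts))
  idx <- match(shifts$residue_type, reference$residue_type)
  if (anyNA(idx))
    stop("no random-coil reference for residue type(s): ",
         paste(unique(shifts$residue_type[is.na(idx)]), collapse = ", "))
  d_ca <- shifts$delta_CA - reference$ca_rc[idx]
  d_cb <- shifts$delta_CB - reference$cb_rc[idx]
  ca_only <- is.na(d_cb)
  val <- ifelse(ca_only, d_ca, d_ca - d_cb)
  data.frame(residue_index = shifts$residue_index,
             residue_type = shifts$residue_type,
             scsd = val, ca_only = ca_only)
}

#' RMSD between predicted and experimental chemical shifts
#'
#' Root-mean-square deviation over the residues common to both tables, for
#' one nucleus at a time.
#'
#' @param predicted,experimental Shift tables.
#' @param nucleus `"CA"` or `"CB"`.
#' @return RMSD in ppm.
#' @export
shift_rmsd <- function(predicted, experimental, nucleus = c("CA", "CB")) {
  nucleus <- match.arg(nucleus)
  col <- paste0("delta_", nucleus)
  common <- intersect(predicted$residue_index, experimental$residue_index)
  p <- predicted[[col]][match(common, predicted$residue_index)]
  e <- experimental[[col]][match(common, experimental$residue_index)]
  keep <- !is.na(p) & !is.na(e)
  if (!sum(keep)) stop("no overlapping residues with defined ", nucleus,
                       " shifts")
  sqrt(mean((p[keep] - e[keep])^2))
}
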