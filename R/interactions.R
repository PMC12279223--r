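#' Detect hydrogen bonds geometrically
#'
#' Scans every frame for donor-hydrogen...acceptor triplets satisfying a
#' donor-acceptor distance cutoff (default 0.35 nm) and an H-D-A angle
#' cutoff (default 30 degrees) -- the default geometric criterion of
#' standard trajectory tools.  Donors are N/O/S atoms with a covalently
#' attached hydrogen (within 0.12 nm); acceptors are N/O atoms.
#'
#' @param coords A [coord_ensemble()] that includes hydrogens.
#' @param d_cut Donor-acceptor distance cutoff, nm.
#' @param angle_cut H-D-A angle cutoff, degrees.
#' @return A data.frame of class `"hbond_table"`.
#' @export
detect_hbonds <- function(coords, d_cut = 0.35, angle_cut = 30) {
  stopifnot(inherits(coords, "coord_ensemble"))
  a <- coords$atoms
  h_idx <- which(a$element == "H")
  if (!length(h_idx))
    stop("no hydrogens in input; supply a precomputed hbond table instead")
  don_idx <- which(a$element %in% c("N", "O", "S"))
  acc_idx <- which(a$element %in% c("N", "O"))
  nf <- dim(coords$coordinates)[1]
  out <- list()
  for (f in seq_len(nf)) {
    xyz <- coords$coordinates[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    ## attach each hydrogen to its closest candidate donor within 0.12 nm
    for (h in h_idx) {
      dd <- sqrt(colSums((t(xyz[don_idx, , drop = FALSE]) - xyz[h, ])^2))
      j <- which.min(dd)
      if (dd[j] > 0.12) next
      d <- don_idx[j]
      da <- sqrt(colSums((t(xyz[acc_idx, , drop = FALSE]) - xyz[d, ])^2))
      for (k in which(da <= d_cut & da > 1e-9)) {
        acc <- acc_idx[k]
        if (acc == d) next
        v_h <- xyz[h, ] - xyz[d, ]
        v_a <- xyz[acc, ] - xyz[d, ]
        cosang <- sum(v_h * v_a) /
          sqrt(sum(v_h^2) * sum(v_a^2))
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        if (ang <= angle_cut) {
          out[[length(out) + 1L]] <- data.frame(
            frame = f,
            donor_residue = a$residue_index[d], donor_role = a$role[d],
            donor_atom = a$atom_name[d], hydrogen_atom = a$atom_name[h],
            acceptor_residue = a$residue_index[acc],
            acceptor_role = a$role[acc], acceptor_atom = a$atom_name[acc],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(frame = integer(), donor_residue = integer(),
               donor_role = character(), donor_atom = character(),
               hydrogen_atom = character(), acceptor_residue = integer(),
               acceptor_role = character(), acceptor_atom = character(),
               stringsAsFactors = FALSE)
  class(df) <- c("hbond_table", "data.frame")
  df
}

#' Bifurcated hydrogen-bond occupancy
#'
#' Fraction of eligible frames in which a glutamine sidechain donates to the
#' backbone carbonyl four residues upstream (i -> i-4) while the helical
#' backbone-backbone bond between residues i and i-4 is simultaneously
#' present.  Only frames in which more than `helicity_threshold` of the
#' residues are alpha-helical are eligible (default > 30%), restricting the
#' statistic to helical conformers.
#'
#' @param hbonds An hbond table covering the same frames as `ss`.
#' @param ss An [ss_trajectory()].
#' @param helicity_threshold Minimum helical-residue fraction for an
#'   eligible frame (strict inequality).
#' @param helix_codes DSSP codes counted as helical.
#' @param sequence Optional amino-acid string; when given, only glutamine
#'   positions are scored.
#' @return Numeric vector of per-residue occupancies (`NA` where no
#'   sidechain donor was ever seen), with attributes `eligible_frames` and
#'   `undefined` (`TRUE` when no frame passed the helicity gate, in which
#'   case all occupancies are `NA`).
#' @export
bifurcated_hb_occupancy <- function(hbonds, ss, helicity_threshold = 0.30,
                                    helix_codes = "H", sequence = NULL) {
  stopifnot(inherits(ss, "ss_trajectory"), is.data.frame(hbonds))
  nres <- n_residues(ss)
  hel_frac <- rowMeans(matrix(ss$codes %in% helix_codes,
                              nrow = n_frames(ss)))
  eligible <- which(hel_frac > helicity_threshold)
  occ <- rep(NA_real_, nres)
  if (!length(eligible)) {
    warning("no frames pass the ", helicity_threshold * 100,
            "% helicity gate; occupancy undefined")
    attr(occ, "eligible_frames") <- 0L
    attr(occ, "undefined") <- TRUE
    return(occ)
  }
  hb <- hbonds[hbonds$frame %in% eligible, , drop = FALSE]
  sc <- hb[hb$donor_role == "sidechain" & hb$acceptor_role == "backbone" &
             hb$donor_residue - hb$acceptor_residue == 4, , drop = FALSE]
  cand <- sort(unique(sc$donor_residue))
  if (!is.null(sequence)) {
    seqc <- strsplit(toupper(sequence), "")[[1]]
    cand <- cand[seqc[cand] == "Q"]
  }
  bb <- hb[hb$donor_role == "backbone" & hb$acceptor_role == "backbone", ,
           drop = FALSE]
  for (i in cand) {
    sc_frames <- unique(sc$frame[sc$donor_residue == i])
    bb_i <- bb[(bb$donor_residue == i & bb$acceptor_residue == i - 4) |
                 (bb$donor_residue == i - 4 & bb$acceptor_residue == i), ,
               drop = FALSE]
    both <- intersect(sc_frames, unique(bb_i$frame))
    occ[i] <- length(both) / length(eligible)
  }
  attr(occ, "eligible_frames") <- length(eligible)
  attr(occ, "undefined") <- FALSE
  occ
}

## Minimum heavy-atom distance between every residue pair in one frame.
## Returns an nres x nres matrix (Inf where a residue has no atoms).
.residue_min_dist <- function(xyz, res_of, nres) {
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  d2[d2 < 0] <- 0
  out <- matrix(Inf, nres, nres)
  idx <- split(seq_len(nrow(xyz)), res_of)
  keys <- as.integer(names(idx))
  for (ai in seq_along(keys)) {
    for (bi in ai:length(keys)) {
      m <- min(d2[idx[[ai]], idx[[bi]]])
      out[keys[ai], keys[bi]] <- m
      out[keys[bi], keys[ai]] <- m
    }
  }
  sqrt(out)
}

#' Ensemble residue contact map
#'
#' Two residues are in contact in a frame when any two of their heavy atoms
#' lie within `cutoff` (default 0.6 nm); the map reports the fraction of
#' frames in contact.  Intramolecular maps are restricted to residue pairs
#' with sequence separation greater than 3 (`|i-j| > 3`); intermolecular
#' maps are averaged over all ordered chain pairs, with rows indexing the
#' first chain's residues.
#'
#' @param coords A [coord_ensemble()].
#' @param cutoff Contact cutoff, nm.
#' @param mode `"intra"` or `"inter"`.
#' @return An object of class `"contact_map_result"`: list with probability
#'   matrix `P`, `cutoff`, `mode`, `n_frames`.
#' @export
contact_map <- function(coords, cutoff = 0.6, mode = c("intra", "inter")) {
  mode <- match.arg(mode)
  stopifnot(inherits(coords, "coord_ensemble"))
  a <- coords$atoms
  chains <- unique(a$chain_id)
  if (mode == "inter" && length(chains) < 2)
    stop("intermolecular contact map requires at least two chains")
  nf <- dim(coords$coordinates)[1]
  ## per-chain local residue numbering
  local_res <- stats::ave(a$residue_index, a$chain_id,
                          FUN = function(r) match(r, unique(r)))
  nres_chain <- vapply(chains,
                       function(ch) max(local_res[a$chain_id == ch]),
                       numeric(1))
  if (mode == "inter" && length(unique(nres_chain)) != 1)
    stop("intermolecular maps require chains of equal residue counts")
  nres <- as.integer(max(nres_chain))
  acc <- matrix(0, nres, nres)
  denom <- 0L
  heavy <- a$is_heavy
  for (f in seq_len(nf)) {
    xyz <- coords$coordinates[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    if (mode == "intra") {
      for (ch in chains) {
        sel <- heavy & a$chain_id == ch
        md <- .residue_min_dist(xyz[sel, , drop = FALSE],
                                local_res[sel], nres)
        cm <- (md <= cutoff)
        sep <- abs(outer(seq_len(nres), seq_len(nres), "-"))
        cm[sep <= 3] <- FALSE
        acc <- acc + cm
        denom <- denom + 1L
      }
    } else {
      for (ci in chains) for (cj in chains) {
        if (ci == cj) next
        sel_i <- heavy & a$chain_id == ci
        sel_j <- heavy & a$chain_id == cj
        xyz_i <- xyz[sel_i, , drop = FALSE]
        xyz_j <- xyz[sel_j, , drop = FALSE]
        d2 <- outer(rowSums(xyz_i^2), rowSums(xyz_j^2), "+") -
          2 * xyz_i %*% t(xyz_j)
        d2[d2 < 0] <- 0
        cm <- matrix(FALSE, nres, nres)
        ri <- local_res[sel_i]; rj <- local_res[sel_j]
        within <- which(sqrt(d2) <= cutoff, arr.ind = TRUE)
        if (nrow(within))
          cm[cbind(ri[within[, 1]], rj[within[, 2]])] <- TRUE
        acc <- acc + cm
        denom <- denom + 1L
      }
    }
  }
  P <- acc / denom
  if (mode == "inter") P <- (P + t(P)) / 2   # symmetrize over ordered pairs
  structure(list(P = P, cutoff = cutoff, mode = mode, n_frames = nf),
            class = "contact_map_result")
}

#' @export
print.contact_map_result <- function(x, ...) {
  cat(sprintf("%smolecular contact map: %d residues, %d frames, %.2f nm\n",
              x$mode, nrow(x$P), x$n_frames, x$cutoff))
  invisible(x)
}

#' Per-frame inter-selection contact count
#'
#' Number of residue pairs (one residue from each selection, on distinct
#' chains) whose closest heavy atoms lie within `cutoff` in each frame --
#' the "number of intermolecular N17 contacts" order parameter.
#'
#' @param coords A [coord_ensemble()].
#' @param selection_a,selection_b Lists `list(chain =, residues =)` naming
#'   a chain and residue indices (global, as stored in the atom table); the
#'   chains must differ.
#' @param cutoff Contact cutoff, nm.
#' @return Integer vector, one count per frame.
#' @export
contact_count <- function(coords, selection_a, selection_b, cutoff = 0.6) {
  stopifnot(inherits(coords, "coord_ensemble"))
  if (identical(selection_a$chain, selection_b$chain))
    stop("selections must be on distinct chains")
  sel_a <- atom_select(coords, chain = selection_a$chain,
                       residues = selection_a$residues)
  sel_b <- atom_select(coords, chain = selection_b$chain,
                       residues = selection_b$residues)
  if (!length(sel_a) || !length(sel_b)) stop("empty selection")
  a <- coords$atoms
  nf <- dim(coords$coordinates)[1]
  counts <- integer(nf)
  for (f in seq_len(nf)) {
    xyz_a <- coords$coordinates[f, sel_a, , drop = TRUE]
    xyz_b <- coords$coordinates[f, sel_b, , drop = TRUE]
    if (is.null(dim(xyz_a))) xyz_a <- matrix(xyz_a, ncol = 3)
    if (is.null(dim(xyz_b))) xyz_b <- matrix(xyz_b, ncol = 3)
    d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), "+") -
      2 * xyz_a %*% t(xyz_b)
    d2[d2 < 0] <- 0
    close <- sqrt(d2) <= cutoff
    pairs <- unique(data.frame(
      i = a$residue_index[sel_a][row(close)[close]],
      j = a$residue_index[sel_b][col(close)[close]]))
    counts[f] <- nrow(pairs)
  }
  counts
}

#' Extract transient beta-conformer frames
#'
#' Frames in which strictly more than `min_beta_residues` residues carry the
#' extended-strand code `E` (default > 4, so a lone four-residue stretch is
#' not enough).  Each extracted frame is classified `n17_direct` when any
#' beta residue lies in the N17 domain (index <= `n17_end`) and
#' `polyq_internal` otherwise.  Isolated beta-bridges (`B`) are not counted
#' toward the threshold but bridge-containing frames are tallied separately.
#'
#' @param ss An [ss_trajectory()].
#' @param min_beta_residues Strict lower bound on the `E` count.
#' @param n17_end Last residue of the N17 domain (default 17).
#' @return An object of class `"beta_conformers"`: list with `frames`
#'   (data.frame `frame`, `n_beta`, `class`), `population`,
#'   `bridge_frames`, `n_frames`.
#' @export
beta_conformers <- function(ss, min_beta_residues = 4, n17_end = 17L) {
  stopifnot(inherits(ss, "ss_trajectory"))
  isE <- matrix(ss$codes == "E", nrow = n_frames(ss))
  nE <- rowSums(isE)
  sel <- which(nE > min_beta_residues)
  cls <- vapply(sel, function(f) {
    if (any(which(isE[f, ]) <= n17_end)) "n17_direct" else "polyq_internal"
  }, character(1))
  frames <- data.frame(frame = sel, n_beta = nE[sel],
                       class = if (length(sel)) cls else character(0))
  structure(list(frames = frames,
                 population = length(sel) / n_frames(ss),
                 bridge_frames = sum(rowSums(
                   matrix(ss$codes == "B", nrow = n_frames(ss))) > 0),
                 n_frames = n_frames(ss)),
            class = "beta_conformers")
}

#' @export
print.beta_conformers <- function(x, ...) {
  cat(sprintf(
    "beta conformers: %d of %d frames (population %.2f%%); %d bridge-only candidates\n",
    nrow(x$frames), x$n_frames, 100 * x$population, x$bridge_frames))
  if (nrow(x$frames))
    print(table(x$frames$class))
  invisible(x)
}
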