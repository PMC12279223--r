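#' Parameters for the helix nucleation/propagation generator
#'
#' The generator emulates the qualitative kinetics observed for N17-polyQ
#' constructs: helices nucleate inside a designated region (by default the
#' central region, residues 11-17) and then grow or shrink one residue per
#' frame at each end, so that residues far from the nucleation site become
#' helical late, if at all.
#'
#' @param nucleation_region A [region()] in which nuclei may appear.
#' @param k_nuc Per-frame nucleation probability while no helix is present.
#' @param p_ext Per-frame, per-end extension probability.
#' @param p_ret Per-frame, per-end retraction probability.
#' @param nucleus_length Initial helix length in residues (>= 4, the DSSP
#'   minimum for an alpha-helix).
#' @param n_frames Number of frames to generate.
#' @param frame_interval Time per frame (ns).
#' @param max_nuclei Maximum number of coexisting helices (default 1).
#' @param seed Integer seed fixing the full output.
#' @return An object of class `"helix_kinetics_params"`.
#' @export
helix_kinetics_params <- function(nucleation_region = region("central", 11, 17),
                                  k_nuc = 0.01,
                                  p_ext = 0.30,
                                  p_ret = 0.25,
                                  nucleus_length = 4L,
                                  n_frames = 5000L,
                                  frame_interval = 1,
                                  max_nuclei = 1L,
                                  seed = 1L) {
  stopifnot(inherits(nucleation_region, "region"),
            k_nuc >= 0, k_nuc <= 1, p_ext >= 0, p_ext <= 1,
            p_ret >= 0, p_ret <= 1, nucleus_length >= 4,
            n_frames >= 1, frame_interval > 0, max_nuclei >= 1)
  structure(list(nucleation_region = nucleation_region,
                 k_nuc = k_nuc, p_ext = p_ext, p_ret = p_ret,
                 nucleus_length = as.integer(nucleus_length),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 max_nuclei = as.integer(max_nuclei),
                 seed = as.integer(seed)),
            class = "helix_kinetics_params")
}

#' Generate a synthetic secondary-structure trajectory
#'
#' Stochastic lattice process over the construct sequence: while fewer than
#' `max_nuclei` helices exist, a nucleus of `nucleus_length` consecutive
#' residues appears, uniformly placed within the nucleation region, with
#' probability `k_nuc` per frame.  Each helix end then independently extends
#' (probability `p_ext`) or retracts (`p_ret`) by one residue per frame,
#' clamped to the chain; a helix shorter than four residues dissolves.
#' Helical residues emit `H`, all others `C`.  Bit-reproducible from the
#' seed in `params`.
#'
#' @param params A [helix_kinetics_params()].
#' @param construct A [construct_spec()] fixing the residue count.
#' @param trajectory_id Label for the output.
#' @return An [ss_trajectory()].
#' @export
gen_ss_trajectory <- function(params, construct,
                              trajectory_id = "synthetic") {
  stopifnot(inherits(params, "helix_kinetics_params"),
            inherits(construct, "construct_spec"))
  n_res <- nchar(build_construct(construct))
  reg <- params$nucleation_region
  if (reg$end > n_res)
    stop("nucleation region exceeds construct length ", n_res)
  if (reg$end - reg$start + 1L < params$nucleus_length)
    stop("nucleus of length ", params$nucleus_length,
         " does not fit in nucleation region ", reg$start, "-", reg$end)
  withr::with_seed(params$seed, {
    codes <- matrix("C", nrow = params$n_frames, ncol = n_res)
    helices <- list()                 # list of c(start, end)
    starts_max <- reg$end - params$nucleus_length + 1L
    for (f in seq_len(params$n_frames)) {
      if (length(helices) < params$max_nuclei &&
          stats::runif(1) < params$k_nuc) {
        s <- if (starts_max > reg$start)
          sample(reg$start:starts_max, 1) else reg$start
        helices[[length(helices) + 1L]] <- c(s, s + params$nucleus_length - 1L)
      }
      if (length(helices)) {
        for (h in seq_along(helices)) {
          iv <- helices[[h]]
          # left end: extension moves start down, retraction moves it up
          iv[1] <- iv[1] - (stats::runif(1) < params$p_ext) +
            (stats::runif(1) < params$p_ret)
          iv[2] <- iv[2] + (stats::runif(1) < params$p_ext) -
            (stats::runif(1) < params$p_ret)
          iv[1] <- max(1L, iv[1]); iv[2] <- min(n_res, iv[2])
          helices[[h]] <- iv
        }
        helices <- Filter(function(iv) iv[2] - iv[1] + 1L >= 4L, helices)
        helices <- .merge_intervals(helices)
        for (iv in helices) codes[f, iv[1]:iv[2]] <- "H"
      }
    }
    ss_trajectory(codes, frame_interval = params$frame_interval,
                  trajectory_id = trajectory_id)
  })
}

.merge_intervals <- function(ivs) {
  if (length(ivs) < 2) return(ivs)
  ivs <- ivs[order(vapply(ivs, `[`, numeric(1), 1))]
  out <- list(ivs[[1]])
  for (iv in ivs[-1]) {
    last <- out[[length(out)]]
    if (iv[1] <= last[2] + 1) {
      out[[length(out)]] <- c(last[1], max(last[2], iv[2]))
    } else {
      out[[length(out) + 1L]] <- iv
    }
  }
  out
}

#' Inject rare beta-sheet frames into a trajectory
#'
#' Each frame is independently selected with probability `beta_fraction`;
#' in selected frames the residues of `strand_ranges` are recoded `E`,
#' emulating the transient two-stranded beta-sheets seen at ~2% population
#' in expanded polyQ constructs.
#'
#' @param base An [ss_trajectory()].
#' @param beta_fraction Probability that a frame carries the beta-sheet.
#' @param strand_ranges List of [region()]s (the strands); must not overlap.
#' @param seed Integer seed.
#' @return An [ss_trajectory()] with injected `E` frames.
#' @export
gen_beta_frames <- function(base, beta_fraction, strand_ranges, seed = 1L) {
  stopifnot(inherits(base, "ss_trajectory"),
            beta_fraction >= 0, beta_fraction <= 1)
  idx <- unlist(lapply(strand_ranges, region_residues))
  if (anyDuplicated(idx)) stop("overlapping strand ranges")
  if (max(idx) > n_residues(base))
    stop("strand range exceeds construct length")
  withr::with_seed(seed, {
    pick <- stats::runif(n_frames(base)) < beta_fraction
    codes <- base$codes
    codes[pick, idx] <- "E"
    ss_trajectory(codes, frame_interval = base$frame_interval,
                  trajectory_id = paste0(base$trajectory_id, "+beta"))
  })
}

#' Parameters for the ideal-helix dimer generator
#'
#' @param helix_length Residues per chain (default 17, the N17 domain
#'   length).
#' @param inter_helical_angle Angle between the two helix axes, degrees
#'   (0 = parallel, 180 = antiparallel).
#' @param separation Perpendicular axis-axis distance, nm.
#' @param axial_offset Shift of chain B along its own axis, nm.
#' @param rise_per_residue,residues_per_turn,radius Ideal helix geometry
#'   (defaults: 0.15 nm rise, 3.6 residues/turn, 0.23 nm Calpha radius).
#' @param n_frames Number of identical frames to emit.
#' @param seed Integer seed (reserved; the default generator is
#'   deterministic).
#' @return An object of class `"dimer_geometry_params"`.
#' @export
dimer_geometry_params <- function(helix_length = 17L,
                                  inter_helical_angle = 180,
                                  separation = 1.0,
                                  axial_offset = 0,
                                  rise_per_residue = IDEAL_HELIX$rise_nm,
                                  residues_per_turn = IDEAL_HELIX$residues_per_turn,
                                  radius = IDEAL_HELIX$radius_nm,
                                  n_frames = 1L,
                                  seed = 1L) {
  stopifnot(helix_length >= 4,
            inter_helical_angle >= 0, inter_helical_angle <= 180,
            separation > 0, n_frames >= 1)
  structure(list(helix_length = as.integer(helix_length),
                 inter_helical_angle = inter_helical_angle,
                 separation = separation, axial_offset = axial_offset,
                 rise_per_residue = rise_per_residue,
                 residues_per_turn = residues_per_turn,
                 radius = radius, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "dimer_geometry_params")
}

## Calpha trace of an ideal helix whose axis is +z, N-terminus at z = 0.
.ideal_helix_ca <- function(n, rise, per_turn, radius) {
  i <- seq_len(n) - 1
  ang <- 2 * pi * i / per_turn
  cbind(radius * cos(ang), radius * sin(ang), rise * i)
}

#' Generate a two-chain ideal-helix dimer
#'
#' Places two ideal Calpha-trace alpha-helices (chains A and B) with a
#' requested inter-helical angle and perpendicular separation.  Chain A runs
#' along +z; chain B is rotated about the x-axis by the requested angle and
#' displaced along x by `separation`, so that the angle between the fitted
#' helix axes equals the request.
#'
#' @param params A [dimer_geometry_params()].
#' @param check_overlap Error if any inter-chain atom pair comes closer
#'   than 0.1 nm.
#' @return A [coord_ensemble()] with chains `A` and `B`.
#' @export
gen_dimer_coords <- function(params, check_overlap = FALSE) {
  stopifnot(inherits(params, "dimer_geometry_params"))
  ca <- .ideal_helix_ca(params$helix_length, params$rise_per_residue,
                        params$residues_per_turn, params$radius)
  ## centre chain A on the origin along z
  ca[, 3] <- ca[, 3] - mean(ca[, 3])
  theta <- params$inter_helical_angle * pi / 180
  rot_x <- matrix(c(1, 0, 0,
                    0, cos(theta), -sin(theta),
                    0, sin(theta), cos(theta)), 3, 3, byrow = TRUE)
  cb <- ca %*% t(rot_x)
  cb[, 1] <- cb[, 1] + params$separation
  if (params$axial_offset != 0) {
    axis_b <- c(0, -sin(theta), cos(theta))  # rotated +z
    cb <- sweep(cb, 2, params$axial_offset * axis_b, "+")
  }
  xyz <- rbind(ca, cb)
  if (check_overlap) {
    d <- .pair_min_dist(ca, cb)
    if (d < 0.1)
      stop("steric overlap: minimum inter-chain distance ",
           format(d, digits = 3), " nm < 0.1 nm")
  }
  atoms <- data.frame(
    atom_name = "CA",
    residue_index = c(seq_len(params$helix_length),
                      params$helix_length + seq_len(params$helix_length)),
    chain_id = rep(c("A", "B"), each = params$helix_length),
    element = "C", is_heavy = TRUE, role = "backbone",
    stringsAsFactors = FALSE)
  coords <- array(NA_real_, dim = c(params$n_frames, nrow(xyz), 3))
  for (f in seq_len(params$n_frames)) coords[f, , ] <- xyz
  coord_ensemble(coords, atoms)
}

.pair_min_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Generate a hydrogen-bond fixture table
#'
#' For each designated glutamine residue `i`, every frame carries the
#' helical backbone bond N(i) -> O(i-4); the frames listed in `bhb_frames`
#' additionally carry the sidechain bond NE2(i) -> O(i-4), producing a
#' bifurcated-hydrogen-bond coexistence pattern with a known occupancy.
#'
#' @param construct A [construct_spec()].
#' @param n_frames Total number of frames.
#' @param bhb_frames Integer frame indices carrying the sidechain bond.
#' @param residues Glutamine residue indices to instrument; defaults to the
#'   first polyQ residue (18).
#' @return A data.frame of class `"hbond_table"`.
#' @export
gen_hbond_fixture <- function(construct, n_frames, bhb_frames,
                              residues = NULL) {
  stopifnot(inherits(construct, "construct_spec"), n_frames >= 1)
  seqc <- strsplit(build_construct(construct), "")[[1]]
  if (is.null(residues)) {
    residues <- which(seqc == "Q")[1]
    if (is.na(residues)) stop("construct contains no glutamine")
  }
  if (any(residues - 4 < 1))
    stop("residue(s) ", paste(residues[residues - 4 < 1], collapse = ", "),
         " have no i-4 partner")
  if (any(seqc[residues] != "Q"))
    stop("designated residue(s) are not glutamine")
  bhb_frames <- as.integer(bhb_frames)
  if (length(bhb_frames) && (min(bhb_frames) < 1 || max(bhb_frames) > n_frames))
    stop("bhb_frames outside 1..", n_frames)
  rows <- list()
  for (i in residues) {
    rows[[length(rows) + 1L]] <- data.frame(
      frame = seq_len(n_frames), donor_residue = i,
      donor_role = "backbone", donor_atom = "N", hydrogen_atom = "H",
      acceptor_residue = i - 4L, acceptor_role = "backbone",
      acceptor_atom = "O", stringsAsFactors = FALSE)
    if (length(bhb_frames)) {
      rows[[length(rows) + 1L]] <- data.frame(
        frame = bhb_frames, donor_residue = i,
        donor_role = "sidechain", donor_atom = "NE2",
        hydrogen_atom = "HE21",
        acceptor_residue = i - 4L, acceptor_role = "backbone",
        acceptor_atom = "O", stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$frame, df$donor_residue, df$donor_role), ]
  rownames(df) <- NULL
  class(df) <- c("hbond_table", "data.frame")
  df
}
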