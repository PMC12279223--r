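# Shared fixtures and independent brute-force oracles.

random_ss_matrix <- function(n_frames, n_residues,
                             codes = c("H", "C", "E", "T"),
                             prob = c(0.4, 0.4, 0.1, 0.1)) {
  matrix(sample(codes, n_frames * n_residues, replace = TRUE, prob = prob),
         nrow = n_frames)
}

# SS-map oracle: for each frame and residue, walk outward to measure the
# maximal helical run containing that residue (no rle, no shared code path).
ss_map_oracle <- function(codes, helix = "H") {
  nf <- nrow(codes); nr <- ncol(codes)
  counts <- matrix(0, nr, nr)
  for (f in seq_len(nf)) {
    hel <- codes[f, ] %in% helix
    for (i in seq_len(nr)) {
      if (!hel[i]) next
      a <- i
      while (a > 1 && hel[a - 1]) a <- a - 1
      b <- i
      while (b < nr && hel[b + 1]) b <- b + 1
      counts[i, b - a + 1] <- counts[i, b - a + 1] + 1
    }
  }
  counts / nf
}

# Contact-map oracle: quadruple loop over residues and their heavy atoms.
contact_map_oracle <- function(xyz_frames, atoms, cutoff = 0.6) {
  nres <- max(atoms$residue_index)
  acc <- matrix(0, nres, nres)
  for (f in seq_along(xyz_frames)) {
    xyz <- xyz_frames[[f]]
    for (i in seq_len(nres - 1)) {
      for (j in (i + 1):nres) {
        if (abs(i - j) <= 3) next
        ai <- which(atoms$residue_index == i & atoms$is_heavy)
        aj <- which(atoms$residue_index == j & atoms$is_heavy)
        hit <- FALSE
        for (p in ai) {
          for (q in aj) {
            if (sqrt(sum((xyz[p, ] - xyz[q, ])^2)) <= cutoff) {
              hit <- TRUE
              break
            }
          }
          if (hit) break
        }
        if (hit) {
          acc[i, j] <- acc[i, j] + 1
          acc[j, i] <- acc[j, i] + 1
        }
      }
    }
  }
  acc / length(xyz_frames)
}

# Random single-chain coordinate ensemble: a loose coil with a few heavy
# atoms per residue, scaled so that some residue pairs fall within 0.6 nm.
random_coord_ensemble <- function(n_frames = 20, n_residues = 30,
                                  atoms_per_res = 3, spread = 0.35) {
  n_at <- n_residues * atoms_per_res
  coords <- array(NA_real_, dim = c(n_frames, n_at, 3))
  for (f in seq_len(n_frames)) {
    backbone <- apply(matrix(rnorm(n_residues * 3, sd = spread),
                             ncol = 3), 2, cumsum)
    at <- backbone[rep(seq_len(n_residues), each = atoms_per_res), ] +
      matrix(rnorm(n_at * 3, sd = 0.08), ncol = 3)
    coords[f, , ] <- at
  }
  atoms <- data.frame(
    atom_name = rep(c("CA", "CB", "CG"), times = n_residues),
    residue_index = rep(seq_len(n_residues), each = atoms_per_res),
    chain_id = "A", element = "C", is_heavy = TRUE,
    role = rep(c("backbone", "sidechain", "sidechain"), times = n_residues),
    stringsAsFactors = FALSE)
  coord_ensemble(coords, atoms)
}

q16_spec <- function(...) construct_spec(polyq_length = 16, tail = "p5", ...)
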