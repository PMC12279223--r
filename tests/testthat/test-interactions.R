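hb_probe <- function(acc_xyz) {
  # donor N(res 5, backbone) with H along +x; acceptor O on residue 1
  atoms <- data.frame(
    atom_name = c("N", "H", "O"),
    residue_index = c(5L, 5L, 1L),
    chain_id = "A",
    element = c("N", "H", "O"),
    is_heavy = c(TRUE, FALSE, TRUE),
    role = "backbone", stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 0), c(0.1, 0, 0), acc_xyz)
  coord_ensemble(array(xyz, dim = c(1, 3, 3)), atoms)
}

test_that("geometric hydrogen-bond detection applies both cutoffs", {
  # colinear N-H...O at 0.30 nm: recorded
  hit <- detect_hbonds(hb_probe(c(0.30, 0, 0)))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$donor_residue, 5)
  expect_equal(hit$acceptor_residue, 1)
  # donor-acceptor at 0.40 nm: absent
  expect_equal(nrow(detect_hbonds(hb_probe(c(0.40, 0, 0)))), 0)
  # H-D-A angle 45 deg: absent
  r <- 0.30
  expect_equal(nrow(detect_hbonds(
    hb_probe(c(r * cos(pi / 4), r * sin(pi / 4), 0)))), 0)
  # no hydrogens: informative error
  no_h <- hb_probe(c(0.3, 0, 0))
  no_h$atoms <- no_h$atoms[-2, ]
  no_h$coordinates <- no_h$coordinates[, -2, , drop = FALSE]
  expect_error(detect_hbonds(no_h), "no hydrogens")
})

test_that("bifurcated-HB occupancy counts same-frame coexistence", {
  sp <- q16_spec()
  all_helical <- ss_trajectory(matrix("H", 4, 38))
  hb <- gen_hbond_fixture(sp, 4, bhb_frames = c(2, 3))
  occ <- bifurcated_hb_occupancy(hb, all_helical)
  expect_equal(occ[18], 0.5)
  expect_equal(attr(occ, "eligible_frames"), 4)
  # no sidechain bond anywhere -> zero occupancy for the instrumented residue
  occ0 <- bifurcated_hb_occupancy(gen_hbond_fixture(sp, 4, integer(0)),
                                  all_helical)
  expect_true(is.na(occ0[18]) || occ0[18] == 0)
  # sidechain bond without the backbone partner -> occupancy 0
  sc_only <- hb[hb$donor_role == "sidechain", ]
  class(sc_only) <- class(hb)
  expect_equal(bifurcated_hb_occupancy(sc_only, all_helical)[18], 0)
})

test_that("the >30% helicity gate excludes coil frames", {
  sp <- q16_spec()
  hb <- gen_hbond_fixture(sp, 4, bhb_frames = c(2, 3))
  # frames 1-2 helical (fraction 1), frames 3-4 coil (fraction 0):
  # eligible = {1, 2}; only frame 2 carries both bonds -> occupancy 1/2
  codes <- rbind(matrix("H", 2, 38), matrix("C", 2, 38))
  occ <- bifurcated_hb_occupancy(hb, ss_trajectory(codes))
  expect_equal(attr(occ, "eligible_frames"), 2)
  expect_equal(occ[18], 0.5)
  # all-coil: flagged undefined
  expect_warning(
    und <- bifurcated_hb_occupancy(hb, ss_trajectory(matrix("C", 4, 38))),
    "helicity gate")
  expect_true(attr(und, "undefined"))
  expect_true(all(is.na(und)))
})

test_that("contact map equals the brute-force oracle with |i-j|>3 exclusion", {
  set.seed(77)
  ce <- random_coord_ensemble(n_frames = 5, n_residues = 12)
  cm <- contact_map(ce)
  frames <- lapply(seq_len(5), function(f) ce$coordinates[f, , ])
  expect_equal(cm$P, contact_map_oracle(frames, ce$atoms), tolerance = 1e-14)
  expect_equal(cm$P, t(cm$P))
  # |i-j| <= 3 band identically zero
  sep <- abs(outer(1:12, 1:12, "-"))
  expect_true(all(cm$P[sep <= 3] == 0))
  # shrinking the cutoff never creates contacts
  cm_small <- contact_map(ce, cutoff = 0.4)
  expect_true(all(cm_small$P <= cm$P + 1e-14))
})

test_that("contact cutoff boundary: 0.59 nm is a contact, 0.61 nm is not", {
  atoms <- data.frame(atom_name = "CA", residue_index = 1:10, chain_id = "A",
                      element = "C", is_heavy = TRUE, role = "backbone")
  place <- function(gap) {
    xyz <- cbind(seq(0, 90, by = 10), 0, 0)  # residues far apart
    xyz[10, ] <- xyz[1, ] + c(gap, 0, 0)     # residues 1 and 10 at `gap` nm
    coord_ensemble(array(xyz, dim = c(1, 10, 3)), atoms)
  }
  expect_equal(contact_map(place(0.59))$P[1, 10], 1)
  expect_equal(contact_map(place(0.61))$P[1, 10], 0)
})

test_that("inter-chain contact count matches brute force and is monotone", {
  p <- dimer_geometry_params(helix_length = 10, inter_helical_angle = 0,
                             separation = 0.3)
  ce <- gen_dimer_coords(p)
  sel_a <- list(chain = "A", residues = 1:10)
  sel_b <- list(chain = "B", residues = 11:20)
  cc6 <- contact_count(ce, sel_a, sel_b, cutoff = 0.6)
  # brute-force residue-pair count
  xyz <- ce$coordinates[1, , ]
  cnt <- 0
  for (i in 1:10) for (j in 11:20) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 0.6) cnt <- cnt + 1
  }
  expect_equal(cc6, cnt)
  expect_gt(cc6, 0)
  # monotone in the cutoff
  expect_lte(contact_count(ce, sel_a, sel_b, cutoff = 0.4), cc6)
  expect_error(contact_count(ce, sel_a, sel_a), "distinct chains")
})

test_that("beta-conformer extraction applies the strict >4 rule and classes", {
  codes <- matrix("C", 4, 38)
  codes[1, 20:24] <- "E"              # 5 strand residues, polyQ only
  codes[2, c(10:12, 20:22)] <- "E"    # 6 residues incl. N17 -> direct
  codes[3, 20:23] <- "E"              # exactly 4: not extracted
  codes[4, 20] <- "B"                 # bridge only: not extracted
  bc <- beta_conformers(ss_trajectory(codes))
  expect_equal(bc$frames$frame, c(1, 2))
  expect_equal(bc$frames$class, c("polyq_internal", "n17_direct"))
  expect_equal(bc$population, 0.5)
  expect_equal(bc$bridge_frames, 1)
})

test_that("beta population estimator is unbiased on generator output", {
  base <- ss_trajectory(matrix("C", 10000, 38))
  strands <- list(region("s1", 20, 25), region("s2", 28, 33))
  pops <- vapply(1:5, function(s) {
    inj <- gen_beta_frames(base, 0.02, strands, seed = s)
    beta_conformers(inj)$population
  }, numeric(1))
  se <- sqrt(0.02 * 0.98 / 10000)
  expect_lt(abs(mean(pops) - 0.02), 3 * se / sqrt(5))
})
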