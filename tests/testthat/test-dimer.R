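sel_a <- list(chain = "A", residues = 1:17)
sel_b <- list(chain = "B", residues = 18:34)

test_that("inter-helical angle recovers generator geometry across the range", {
  for (ang in c(0, 45, 90, 135, 180)) {
    ce <- gen_dimer_coords(dimer_geometry_params(inter_helical_angle = ang,
                                                 separation = 2))
    got <- interhelical_angle(ce, sel_a, sel_b)
    expect_lt(abs(got - ang), 2)
  }
  # atom-vector mode is exact when first and last residue share a phase
  # (19 residues = first-to-last span of five whole turns)
  for (ang in c(0, 90, 180)) {
    ce19 <- gen_dimer_coords(dimer_geometry_params(
      helix_length = 19, inter_helical_angle = ang, separation = 2))
    got2 <- interhelical_angle(ce19, list(chain = "A", residues = 1:19),
                               list(chain = "B", residues = 20:38),
                               method = "atom_vector")
    expect_lt(abs(got2 - ang), 2)
  }
  # a helix against itself is parallel by identity
  ce <- gen_dimer_coords(dimer_geometry_params())
  expect_lt(interhelical_angle(ce, sel_a, sel_a), 1e-6)
  expect_error(interhelical_angle(ce, list(chain = "A", residues = 1:3),
                                  sel_b),
               "at least 4")
})

test_that("minimum distance matches brute force and the set separation", {
  ce <- gen_dimer_coords(dimer_geometry_params(separation = 10,
                                               inter_helical_angle = 0))
  md <- min_distance(ce, sel_a, sel_b)
  expect_lt(abs(md - 10), 0.5)          # axes 10 nm apart, 0.23 nm radius
  xyz <- ce$coordinates[1, , ]
  brute <- min(as.matrix(dist(xyz))[1:17, 18:34])
  expect_equal(md, brute, tolerance = 1e-12)
})

test_that("PMF follows the closed-form two-bin solutions", {
  # counts 90:10 -> F = {0, ln 9}
  x <- c(rep(1, 90), rep(3, 10))
  y <- rep(5, 100)
  pm <- pmf2d(x, y, x_breaks = c(0, 2, 4), y_breaks = c(0, 10))
  expect_equal(pm$F[1, 1], 0, tolerance = 1e-12)
  expect_equal(pm$F[2, 1], log(9), tolerance = 1e-12)
  # uniform 2-bin occupancy -> F = 0 everywhere occupied
  pm2 <- pmf2d(c(rep(1, 50), rep(3, 50)), y,
               x_breaks = c(0, 2, 4), y_breaks = c(0, 10))
  expect_equal(pm2$F[, 1], c(0, 0), tolerance = 1e-12)
  # single occupied bin -> 0 there, sentinel elsewhere
  pm3 <- pmf2d(rep(1, 10), rep(5, 10),
               x_breaks = c(0, 2, 4), y_breaks = c(0, 10))
  expect_equal(pm3$F[1, 1], 0)
  expect_true(is.na(pm3$F[2, 1]))
  expect_error(pmf2d(numeric(0), numeric(0)), "zero frames")
})

test_that("exp(-F) renormalized reproduces the input histogram exactly", {
  set.seed(12)
  x <- rpois(500, 12)
  y <- runif(500, 0, 180)
  pm <- pmf2d(x, y)
  occ <- pm$counts > 0
  p_back <- exp(-pm$F[occ]) / sum(exp(-pm$F[occ]))
  expect_equal(p_back, (pm$counts[occ] / sum(pm$counts)), tolerance = 1e-12)
})

test_that("association events follow the hysteretic state machine", {
  tr <- association_events(c(30, 30, 0, 0, 30),
                           bound_threshold = 10, unbound_threshold = 1)
  expect_equal(tr$dissociation_frames, 3)
  expect_equal(tr$reassociation_frames, 5)
  # constant bound series: no events
  none <- association_events(rep(50, 20), 10, 1)
  expect_equal(length(none$dissociation_frames), 0)
  # oscillation inside [unbound, bound): no spurious events
  osc <- association_events(rep(c(2, 8), 10), 10, 1)
  expect_equal(length(osc$dissociation_frames), 0)
  expect_equal(length(osc$reassociation_frames), 0)
  # events alternate dissociation/reassociation
  multi <- association_events(c(30, 0, 30, 0, 30), 10, 1)
  ev <- sort(c(multi$dissociation_frames, multi$reassociation_frames))
  expect_equal(ev, c(2, 3, 4, 5))
  expect_error(association_events(1:5, 1, 5), "hysteresis|bound_threshold")
})

test_that("event counts are invariant to benign padding", {
  core <- c(30, 30, 0, 0, 30)
  base <- association_events(core, 10, 1)
  padded <- association_events(c(50, 40, core, 45, 60), 10, 1)
  expect_equal(length(padded$dissociation_frames),
               length(base$dissociation_frames))
  expect_equal(length(padded$reassociation_frames),
               length(base$reassociation_frames))
})
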