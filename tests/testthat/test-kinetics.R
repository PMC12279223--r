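test_that("initiation times use the 1-based frame-time convention", {
  tr <- ss_trajectory(c("CC", "CC", "HC", "HC"), frame_interval = 10)
  it <- initiation_times(tr)
  expect_equal(it$mean_ns[1], 30)            # first H in frame 3 x 10 ns
  expect_false(it$defined[2])                # never helical
  expect_true(is.na(it$mean_ns[2]))
})

test_that("initiation statistics across trajectories use the per-residue SEM", {
  mk <- function(first_h, nf = 40) {
    codes <- matrix("C", nf, 1)
    codes[first_h:nf, 1] <- "H"
    ss_trajectory(codes, frame_interval = 10)
  }
  it <- initiation_times(list(mk(10), mk(30)))   # times 100 and 300 ns
  expect_equal(it$mean_ns, 200)
  expect_equal(it$se_ns, 100)                    # sd/sqrt(2) closed form
  expect_equal(it$n_defined, 2)
  # residue defined in only one trajectory uses that trajectory alone
  codes_never <- ss_trajectory(matrix("C", 40, 1), frame_interval = 10)
  it1 <- initiation_times(list(mk(10), codes_never))
  expect_equal(it1$mean_ns, 100)
  expect_equal(it1$se_ns, 0)
})

test_that("Monte Carlo comparison matches the closed-form normal difference", {
  it <- structure(
    data.frame(residue = 1:2, mean_ns = c(100, 500), se_ns = c(10, 50),
               defined = TRUE, n_defined = 3),
    class = c("initiation_times", "data.frame"))
  mc <- mc_region_compare(it, region_a = 1L, region_b = 2L,
                          n_trials = 1e6, seed = 42)
  # P = Phi(400 / sqrt(10^2 + 50^2)) ~ 1
  p_true <- pnorm(400 / sqrt(100 + 2500))
  se_bin <- sqrt(p_true * (1 - p_true) / 1e6)
  expect_lt(abs(mc$p_a_before_b - p_true), max(3 * se_bin, 1e-5))
  expect_lt(abs(mc$delta_t_mean - 400), 3 * sqrt(2600) / sqrt(1e6) * 3 + 1)
  expect_equal(sum(mc$histogram$prob), 1)
  # identical regions -> symmetry
  sym <- mc_region_compare(it, 1:2, 1:2, n_trials = 2e5, seed = 7)
  expect_lt(abs(sym$p_a_before_b - 0.5), 0.005)
  expect_lt(abs(sym$delta_t_mean), 1)
  # zero standard errors degenerate to a deterministic comparison
  it0 <- it; it0$se_ns <- 0
  class(it0) <- class(it)
  det <- mc_region_compare(it0, 1L, 2L, n_trials = 1000, seed = 1)
  expect_true(det$p_a_before_b %in% c(0, 0.5, 1))
  expect_equal(det$p_a_before_b, 1)
})

test_that("Monte Carlo result is bit-reproducible from its seed", {
  it <- structure(
    data.frame(residue = 1:4, mean_ns = c(50, 80, 300, 420),
               se_ns = c(5, 12, 60, 80), defined = TRUE, n_defined = 3),
    class = c("initiation_times", "data.frame"))
  a <- mc_region_compare(it, 1:2, 3:4, n_trials = 1e5, seed = 123)
  b <- mc_region_compare(it, 1:2, 3:4, n_trials = 1e5, seed = 123)
  expect_identical(a$p_a_before_b, b$p_a_before_b)
  expect_identical(a$delta_t_mean, b$delta_t_mean)
})

test_that("undefined residues are excluded loudly; empty regions error", {
  it <- structure(
    data.frame(residue = 1:3, mean_ns = c(100, NA, 300),
               se_ns = c(10, NA, 30), defined = c(TRUE, FALSE, TRUE),
               n_defined = c(3, 0, 3)),
    class = c("initiation_times", "data.frame"))
  expect_warning(mc_region_compare(it, 1:2, 3L, n_trials = 100, seed = 1),
                 "undefined")
  expect_error(
    suppressWarnings(mc_region_compare(it, 2L, 3L, n_trials = 100, seed = 1)),
    "empty")
})

test_that("raising one region's times shifts the difference monotonically", {
  it <- structure(
    data.frame(residue = 1:4, mean_ns = c(50, 80, 300, 420),
               se_ns = c(5, 12, 60, 80), defined = TRUE, n_defined = 3),
    class = c("initiation_times", "data.frame"))
  base <- mc_region_compare(it, 1:2, 3:4, n_trials = 1e5, seed = 9)
  it2 <- it; it2$mean_ns[3:4] <- it$mean_ns[3:4] + 100
  class(it2) <- class(it)
  up <- mc_region_compare(it2, 1:2, 3:4, n_trials = 1e5, seed = 9)
  expect_gt(up$delta_t_mean, base$delta_t_mean)
})
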