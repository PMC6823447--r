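# Coupled-oscillator cohort generator.

test_that("identical config and master seed reproduce the cohort bit-exactly", {
  cfg <- tiny_config(n_trials_per_condition = 3)
  a <- make_cohort(cfg)
  b <- make_cohort(cfg)
  expect_identical(a$epochs[[1]]$data, b$epochs[[1]]$data)
  expect_identical(a$epochs[[2]]$data, b$epochs[[2]]$data)
  expect_identical(a$behaviour, b$behaviour)
  expect_identical(a$truth$seeds, b$truth$seeds)
  expect_identical(a$artifacts[[1]]$head_position,
                   b$artifacts[[1]]$head_position)
})

test_that("a correct-only cohort reproduces the two-condition cohort's correct trials", {
  cfg2 <- tiny_config(n_trials_per_condition = 3, master_seed = 3)
  cfg1 <- tiny_config(n_trials_per_condition = 3, master_seed = 3,
                      conditions = "correct")
  both <- make_cohort(cfg2)
  correct_only <- make_cohort(cfg1)
  expect_identical(both$epochs[[1]]$data[1:3, , ],
                   correct_only$epochs[[1]]$data)
  expect_identical(both$behaviour$accuracy, correct_only$behaviour$accuracy)
  expect_error(tiny_config(conditions = "miss"), "subset")
})

test_that("epoch containers satisfy their shape and axis invariants", {
  cfg <- tiny_config()
  ch <- make_cohort(cfg)
  ep <- ch$epochs[[1]]
  n_expected <- round(diff(cfg$epoch_window) * cfg$sampling_rate) + 1
  expect_equal(dim(ep$data),
               c(2 * cfg$n_trials_per_condition, cfg$n_regions, n_expected))
  expect_length(ep$time_axis, n_expected)
  expect_true(all(diff(ep$time_axis) > 0))
  expect_true(all(is.finite(ep$data)))
  expect_identical(ep$region_labels, aal_labels(cfg$n_regions))
  expect_setequal(unique(ep$trial_labels), c("correct", "incorrect"))
})

test_that("each band's oscillation keeps at least 90% of its power in band", {
  for (bname in c("theta", "alpha", "low_gamma")) {
    cfg <- simulation_config(n_regions = 2, groups = list(FT = 2),
                             n_trials_per_condition = 2,
                             bands = default_bands()[bname], noise_sd = 0,
                             master_seed = 9)
    ch <- make_cohort(cfg)
    band <- cfg$bands[[1]]
    for (r in 1:2) {
      frac <- band_power_fraction(ch$epochs[[1]]$data[1, r, ], 600,
                                  band$f_low, band$f_high)
      expect_gt(frac, 0.9)
    }
  }
})

test_that("a fully coupled planted edge shows retention-only phase locking", {
  # parameter-recovery oracle: kappa = 1 on edge (3, 7), alpha, retention,
  # FT correct trials -> retention wPLI near 1, baseline near 0, and no
  # coupling in the incorrect condition
  net <- planted_network("alpha", matrix(c(3, 7), 1), kappa = 1,
                         group = "FT", condition = "correct")
  cfg <- simulation_config(n_regions = 8, groups = list(FT = 2),
                           n_trials_per_condition = 50,
                           bands = default_bands()["alpha"],
                           planted_networks = list(net), master_seed = 11)
  ch <- make_cohort(cfg)
  cc <- subject_connectivity(ch$epochs[[1]], cfg$bands$alpha,
                             condition = "correct", zscore = FALSE)
  ret <- window_average(cc, c(350, 1150))
  base <- window_average(cc, c(-500, 0))
  expect_gt(ret[3, 7], 0.9)
  expect_lt(base[3, 7], 0.3)
  ci <- subject_connectivity(ch$epochs[[1]], cfg$bands$alpha,
                             condition = "incorrect", zscore = FALSE)
  expect_lt(window_average(ci, c(350, 1150))[3, 7], 0.3)
  # unplanted pairs stay near-null in the retention window
  others <- ret[upper.tri(ret)]
  others <- others[others != ret[3, 7]]
  expect_lt(max(others), 0.5)
})

test_that("retention wPLI on a planted edge is non-decreasing in kappa", {
  vals <- vapply(c(0, 0.3, 0.6, 1.0), function(kap) {
    nets <- if (kap > 0)
      list(planted_network("alpha", matrix(c(1, 2), 1), kappa = kap))
    else list()
    cfg <- simulation_config(n_regions = 4, groups = list(FT = 2),
                             n_trials_per_condition = 150,
                             bands = default_bands()["alpha"],
                             planted_networks = nets, master_seed = 21)
    ch <- make_cohort(cfg)
    mean(vapply(ch$epochs, function(e)
      window_average(subject_connectivity(e, cfg$bands$alpha,
                                          condition = "correct",
                                          zscore = FALSE),
                     c(350, 1150))[1, 2], numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_lt(vals[1], 0.25)   # kappa = 0 is at the null level
})

test_that("contradictory planted specifications are rejected", {
  e <- matrix(c(1, 2), 1)
  overlapping <- list(
    planted_network("alpha", e, kappa = 0.5, window = c(250, 1250)),
    planted_network("alpha", e, kappa = 0.9, window = c(1000, 1500)))
  expect_error(tiny_config(planted_networks = overlapping), "conflicting")
  # disjoint windows for the same edge are fine
  disjoint <- list(
    planted_network("alpha", e, kappa = 0.5, window = c(250, 1250)),
    planted_network("alpha", e, kappa = 0.9, window = c(1300, 1800)))
  expect_s3_class(tiny_config(planted_networks = disjoint), "sim_config")
  # different conditions for the same edge/window are fine
  two_cond <- list(
    planted_network("alpha", e, kappa = 0.5, condition = "correct"),
    planted_network("alpha", e, kappa = 0.9, condition = "incorrect"))
  expect_s3_class(tiny_config(planted_networks = two_cond), "sim_config")
})

test_that("configuration invariants are enforced", {
  expect_error(tiny_config(groups = list(FT = 1)), "group sizes")
  expect_error(
    tiny_config(planted_networks = list(
      planted_network("beta", matrix(c(1, 2), 1), kappa = 0.5))),
    "unknown band")
  expect_error(
    tiny_config(planted_networks = list(
      planted_network("alpha", matrix(c(1, 99), 1), kappa = 0.5))),
    "invalid region")
  expect_error(planted_network("alpha", matrix(c(2, 1), 1), kappa = 0.5),
               "i < j")
  expect_error(planted_network("alpha", matrix(c(1, 2), 1), kappa = 1.2),
               "kappa")
  expect_error(
    tiny_config(task_windows = list(baseline = c(-1500, 0))),
    "within the epoch window")
})

test_that("behaviour table follows the accuracy link, with clamping", {
  cfg <- tiny_config(planted_networks = list(
    planted_network("alpha", matrix(c(1, 2), 1), kappa = 1,
                    condition = NULL)))
  ch <- make_cohort(cfg)
  truth <- ch$truth
  # slope 0, noise 0: every subject sits at the intercept
  tb <- make_behaviour_table(truth, link = list(intercept = 75, slope = 0,
                                                noise_sd = 0))
  expect_true(all(tb$accuracy == 75))
  # clamping: intercept 99 + slope 5 * kappa 1 -> 100
  tb2 <- make_behaviour_table(truth, link = list(intercept = 99, slope = 5,
                                                 noise_sd = 0))
  expect_true(all(tb2$accuracy == 100))
  expect_true(all(truth$subjects$kappa == 1))
})

test_that("positive accuracy slope yields a positive kappa-accuracy association", {
  net <- planted_network("alpha", matrix(c(1, 2), 1), kappa = 0.5,
                         kappa_range = c(0.05, 0.95), condition = NULL)
  cfg <- simulation_config(n_regions = 3, groups = list(FT = 15),
                           n_trials_per_condition = 2,
                           bands = default_bands()["alpha"],
                           planted_networks = list(net),
                           behaviour_link = list(intercept = 60, slope = 30,
                                                 noise_sd = 3),
                           master_seed = 5)
  ch <- make_cohort(cfg)
  expect_gt(cor(ch$truth$subjects$kappa, ch$behaviour$accuracy), 0)
  expect_true(all(ch$behaviour$accuracy >= 0 & ch$behaviour$accuracy <= 100))
})

test_that("simulation truth serializes to JSON and records seeds", {
  cfg <- tiny_config(planted_networks = list(
    planted_network("alpha", matrix(c(1, 2), 1), kappa = 0.7)))
  ch <- make_cohort(cfg)
  js <- jsonlite::toJSON(wplinet:::truth_to_list(ch$truth),
                         auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$master_seed, cfg$master_seed)
  expect_equal(dim(back$seeds), dim(ch$truth$seeds))
  expect_true(all(ch$truth$seeds >= 0 & ch$truth$seeds < 2^31))
  expect_equal(back$networks$kappa[[1]], 0.7)
})
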