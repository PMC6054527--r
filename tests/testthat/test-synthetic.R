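test_that("track generator respects rates, counts and determinism", {
  # zero-rate cell is silent
  ss <- generate_track_session(track_sim_config(
    field_centers = c(50, 150), peak_rates = c(0, 10),
    n_laps_per_trajectory = 5, seed = 2))
  expect_equal(length(ss$spikes[[1]]), 0)
  expect_gt(length(ss$spikes[[2]]), 0)

  # Poisson expectation: total count ~ rate integral over the session
  for (sd0 in c(3, 4)) {
    cfg <- track_sim_config(field_centers = 100, field_widths = 10,
                            peak_rates = 15, n_laps_per_trajectory = 20,
                            seed = sd0)
    n <- length(generate_track_session(cfg)$spikes[[1]])
    expected <- 2 * 20 * 15 * sqrt(2 * pi) * 10 / 20   # per-traversal integral
    expect_lt(abs(n - expected), 3 * sqrt(expected))
  }

  # bit-identical reruns under a fixed seed
  a <- generate_track_session(track_sim_config(seed = 11))
  b <- generate_track_session(track_sim_config(seed = 11))
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$lfp$samples, b$lfp$samples)

  # invalid geometry is rejected
  expect_error(track_sim_config(field_centers = 300), "within")
})

test_that("synthetic lap structure is recovered exactly", {
  cfg <- track_sim_config(n_laps_per_trajectory = 8, seed = 6)
  ss <- generate_track_session(cfg)
  laps <- segment_laps(linearize(ss$position, track_geometry(200)))
  expect_equal(sum(laps$trajectory == "AtoB"), 8)
  expect_equal(sum(laps$trajectory == "BtoA"), 8)
})

test_that("rest generator enforces interval structure and input checks", {
  rs <- generate_rest_session(rest_sim_config(duration = 300, seed = 8))
  gt <- rs$ground_truth$true_ripple_intervals
  expect_gt(nrow(gt), 30)
  expect_true(all(gt$end > gt$start))
  expect_true(all(gt$start[-1] - gt$end[-nrow(gt)] >= 0.03))
  expect_true(all(gt$end <= 300))

  expect_error(rest_sim_config(duration = 0), "positive")
  expect_error(rest_sim_config(ripple_freq = 80), "100-250")
  expect_warning(rest_sim_config(duration = 2, ripple_rate = 0.3),
                 "fewer than one ripple")

  # determinism
  a <- generate_rest_session(rest_sim_config(duration = 60, seed = 9))
  b <- generate_rest_session(rest_sim_config(duration = 60, seed = 9))
  expect_identical(a$lfp$samples, b$lfp$samples)
  expect_identical(a$spikes, b$spikes)
})

test_that("rest LFP background is calibrated in ripple-band sd units", {
  rs <- generate_rest_session(rest_sim_config(
    duration = 120, ripple_rate = 0.05, seed = 10))
  gt <- rs$ground_truth$true_ripple_intervals
  # mask event samples, measure background band sd against the 5 uV unit
  fs <- rs$lfp$rate
  filt <- bandpass(rs$lfp$samples, fs, 100, 250)
  mask <- rep(TRUE, length(filt))
  for (j in seq_len(nrow(gt)))
    mask[round(gt$start[j] * fs):round(gt$end[j] * fs)] <- FALSE
  expect_equal(sd(filt[mask]), 5, tolerance = 0.5)
})

test_that("cohort presets shape pre/post coincidence injection", {
  wt <- generate_cohort("WT-like", 2, seed = 5, rest_duration = 60)
  expect_equal(length(wt), 2)
  expect_equal(wt[[1]]$pre_run$ground_truth$injected_pair_synchrony$rate[1], 0.01)
  expect_equal(wt[[1]]$post_run$ground_truth$injected_pair_synchrony$rate[1], 0.12)
  rtt <- generate_cohort("RTT-like", 1, seed = 5, rest_duration = 60)
  expect_equal(rtt[[1]]$pre_run$ground_truth$injected_pair_synchrony$rate[1], 0.12)
  expect_equal(rtt[[1]]$post_run$ground_truth$injected_pair_synchrony$rate[1], 0.12)

  expect_error(generate_cohort("WT-like", 0), "n_animals")
  expect_error(generate_cohort("mystery", 2))
})

test_that("von Mises sampler concentrates around its mean", {
  set.seed(12)
  x <- placeripple:::rvonmises(2000, pi / 3, 4)
  m <- Arg(mean(exp(1i * x)))
  expect_lt(abs(m - pi / 3), 0.1)
  R <- Mod(mean(exp(1i * x)))
  expect_gt(R, 0.8); expect_lt(R, 0.95)   # kappa = 4 -> R ~ 0.86
})
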