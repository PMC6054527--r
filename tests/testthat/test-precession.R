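test_that("spike phases follow the trough-zero convention", {
  fs <- 2000
  t <- seq(0, 10, by = 1 / fs)
  lfp <- lfp_trace(-cos(2 * pi * 8 * t) * 50, rate = fs)
  troughs <- seq(0.5, 9.5, by = 1 / 8)            # LFP minima
  ph <- assign_spike_phases(troughs, lfp)
  err <- abs(((as.numeric(ph) + 180) %% 360) - 180)
  expect_lt(max(err), 5)
  peaks <- troughs + 1 / 16
  php <- assign_spike_phases(peaks, lfp)
  expect_lt(max(abs(as.numeric(php) - 180)), 5)
  # spikes outside coverage are dropped and counted
  ph2 <- assign_spike_phases(c(1, 20), lfp)
  expect_equal(length(ph2), 1)
  expect_equal(attr(ph2, "n_dropped"), 1)
})

test_that("generator spike phases round-trip through phase assignment", {
  ss <- generate_track_session(track_sim_config(
    field_centers = 100, n_laps_per_trajectory = 10, seed = 7))
  gt <- ss$ground_truth$spike_phases[[1]]
  ok <- !is.na(gt)
  ph <- assign_spike_phases(ss$spikes[[1]][ok], ss$lfp)
  err <- abs(((as.numeric(ph) - gt[ok] + 180) %% 360) - 180)
  expect_lt(mean(err), 10)
})

test_that("optimal linear fit recovers a noiseless precession line", {
  set.seed(3)
  s <- runif(100, 0, 40)
  fit <- optimal_linear_fit(wrap360(300 - 2.0 * s), s)
  expect_equal(fit$slope, -2.0, tolerance = 1e-9)
  expect_equal(abs(fit$r), 1, tolerance = 1e-9)

  # rotating all phases changes nothing (the shift search absorbs it)
  fit90 <- optimal_linear_fit(wrap360(300 - 2.0 * s + 90), s)
  expect_equal(fit90$slope, fit$slope, tolerance = 1e-9)
  expect_equal(abs(fit90$r), abs(fit$r), tolerance = 1e-9)

  # position offsets change nothing
  fit_off <- optimal_linear_fit(wrap360(300 - 2.0 * s), s + 57)
  expect_equal(fit_off$slope, fit$slope, tolerance = 1e-9)

  # too few spikes: missing
  expect_true(is.na(optimal_linear_fit(c(10, 20), c(1, 2))$slope))
})

test_that("random phases yield weak optimal-linear correlations", {
  set.seed(4)
  n <- 30
  rbest <- replicate(200, {
    abs(optimal_linear_fit(runif(n, 0, 360), runif(n, 0, 40))$r)
  })
  # the shift search inflates |r| under the null, but it stays modest
  expect_lt(mean(rbest), 0.45)
})

test_that("circular-linear fit recovers slope, offset quality and wrap-invariance", {
  set.seed(9)
  s <- runif(120, 0, 40)
  fit <- circular_linear_fit(wrap360(90 - 360 * s / 40), s)
  expect_lt(abs(fit$slope - (-0.025)), 1e-6)
  expect_gt(abs(fit$rho), 0.99)

  # uniform random phases: near-zero correlation on average
  rhos <- replicate(100, {
    circular_linear_fit(runif(60, 0, 360), runif(60, 0, 40))$rho
  })
  expect_lt(abs(mean(rhos, na.rm = TRUE)), 0.1)

  # wrapping through 0/360 mid-field is immaterial
  ph <- wrap360(10 - 3 * s)      # crosses the seam repeatedly
  f1 <- circular_linear_fit(ph, s)
  f2 <- circular_linear_fit(wrap360(ph + 117), s)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-6)
})

test_that("grid search with refinement matches a dense-grid oracle", {
  set.seed(13)
  for (rep in 1:10) {
    n <- 60
    s <- runif(n, 0, 40)
    a_true <- runif(1, -0.04, 0.04)
    ph <- wrap360(360 * a_true * s + rnorm(n, sd = 30))
    fit <- circular_linear_fit(ph, s)
    dense <- seq(-0.05, 0.05, by = 1e-4)
    phi <- ph * pi / 180
    sc <- s - mean(s)
    R <- vapply(dense, function(a)
      Mod(mean(exp(1i * (phi - 2 * pi * a * sc)))), numeric(1))
    expect_lt(abs(fit$slope - dense[which.max(R)]), 1e-3)
  }
})

test_that("field-level precession fit pools in-field spikes and reports sizes", {
  ss <- generate_track_session(track_sim_config(
    field_centers = 100, n_laps_per_trajectory = 15, seed = 5))
  lin <- linearize(ss$position, track_geometry(200))
  pos <- approx(lin$timestamp, lin$linear_pos, xout = ss$spikes[[1]])$y
  laps <- segment_laps(lin)
  laps <- laps[laps$trajectory == "AtoB", ]
  inlap <- rep(FALSE, length(ss$spikes[[1]]))
  for (j in seq_len(nrow(laps)))
    inlap <- inlap | (ss$spikes[[1]] >= laps$start_time[j] &
                        ss$spikes[[1]] < laps$end_time[j])
  fit <- fit_field_precession(ss$spikes[[1]][inlap], pos[inlap],
                              data.frame(start = 70, end = 130), ss$lfp)
  expect_gt(fit$n_spikes, 50)
  expect_lt(abs(fit$linear$slope - (-6)), 0.2 * 6)
  expect_lt(abs(fit$circular$slope - (-6 / 360)), 0.2 * 6 / 360)
})
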