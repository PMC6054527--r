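test_that("rate curve equals counts over occupancy in the trivial case", {
  # 10 bins visited for 1 s each, one spike per bin, no smoothing
  rate <- 33
  lin <- lin_from_x(rep(seq(1, 19, by = 2), each = rate), rate = rate, L = 20)
  laps <- data.frame(trajectory = "AtoB", start_time = 0,
                     end_time = max(lin$timestamp) + 1)
  spikes <- seq(0.5, by = 1, length.out = 10)
  cv <- compute_rate_curve(spikes, lin, laps,
                           binning_params(bin_size = 2, smooth_sigma = 0))
  occ_bins <- cv$occupancy > 0
  expect_equal(sum(occ_bins), 10)
  expect_equal(unname(cv$rate[occ_bins]), rep(1, 10), tolerance = 0.05)
  expect_equal(sum(cv$p[occ_bins]), 1)
})

test_that("spikes during masked periods contribute nothing", {
  rate <- 33
  lin <- lin_from_x(rep(seq(1, 19, by = 2), each = rate), rate = rate, L = 20)
  lin$valid[1:(5 * rate)] <- FALSE
  laps <- data.frame(trajectory = "AtoB", start_time = 0,
                     end_time = max(lin$timestamp) + 1)
  spikes_in_masked <- seq(0.2, 4.8, by = 0.2)
  cv <- compute_rate_curve(spikes_in_masked, lin, laps,
                           binning_params(2, 0))
  expect_true(all(cv$counts == 0))
  all_masked <- lin
  all_masked$valid <- FALSE
  expect_error(compute_rate_curve(1, all_masked, laps, binning_params()),
               "occupancy")
})

test_that("rate-curve peak recovers a synthetic cell's field center", {
  ss <- generate_track_session(track_sim_config(
    field_centers = 100, field_widths = 10, peak_rates = 15,
    n_laps_per_trajectory = 20, seed = 1))
  ra <- analyze_run_session(ss$position, ss$spikes)
  for (tr in c("AtoB", "BtoA")) {
    cv <- ra$curves[["cell01"]][[tr]]
    expect_lt(abs(cv$bin_centers[which.max(cv$rate)] - 100), 4)
  }
})

test_that("spatial information matches closed forms and the summation oracle", {
  # uniform firing carries no information
  expect_equal(spatial_information(make_curve(rep(1, 10), rep(3, 10))), 0)

  # all firing in one of N equal bins: log2(N)
  for (N in c(2, 4, 8, 16)) {
    cv <- make_curve(rep(1, N), c(4, rep(0, N - 1)))
    expect_equal(spatial_information(cv), log2(N), tolerance = 1e-12)
  }

  # 3-bin hand example against direct summation
  occ <- c(2, 1, 1); x <- c(3, 1, 0)
  p <- occ / sum(occ); lam <- sum(p * x)
  oracle <- sum(ifelse(x > 0, p * (x / lam) * log2(x / lam), 0))
  expect_equal(spatial_information(make_curve(occ, x)), oracle,
               tolerance = 1e-12)
  expect_equal(oracle, 0.5511844, tolerance = 1e-6)

  # invariance to positive rate scaling
  cv1 <- make_curve(c(1, 2, 1, 3), c(0.5, 4, 1, 0))
  cv2 <- make_curve(c(1, 2, 1, 3), 7 * c(0.5, 4, 1, 0))
  expect_equal(spatial_information(cv1), spatial_information(cv2))

  # silent cell: undefined, not zero
  expect_true(is.na(spatial_information(make_curve(rep(1, 4), rep(0, 4)))))
})

test_that("stability is the Pearson correlation over common occupied bins", {
  a <- make_curve(rep(1, 20), sin(seq_len(20)) + 2)
  expect_equal(stability(a, a), 1)
  b <- make_curve(rep(1, 20), max(a$rate) - a$rate)
  expect_equal(stability(a, b), -1)
  # fewer than 3 common bins or flat curve: missing
  expect_true(is.na(stability(make_curve(c(1, 1, 0), 1:3),
                              make_curve(c(1, 0, 1), 3:1))))
  expect_true(is.na(stability(make_curve(rep(1, 5), rep(2, 5)),
                              make_curve(rep(1, 5), 1:5))))
})

test_that("independent random curves have near-zero mean stability", {
  set.seed(21)
  r <- replicate(400, stability(make_curve(rep(1, 100), runif(100)),
                                make_curve(rep(1, 100), runif(100))))
  expect_lt(abs(mean(r)), 0.02)
})

test_that("place-field detection applies peak, boundary and merge rules", {
  expect_equal(nrow(detect_place_fields(make_curve(rep(1, 30), rep(0, 30)))), 0)

  # sub-threshold peak
  low <- rep(0, 30); low[15] <- 0.9
  expect_equal(nrow(detect_place_fields(make_curve(rep(1, 30), low))), 0)

  # two supra-threshold peaks whose 10% boundaries are 4 cm apart: merged
  x <- rep(0, 40)
  x[10:14] <- c(0.5, 2, 0.5, 0.3, 0.21)   # boundary at bin 14 (0.21 >= 0.2)
  x[17:19] <- c(0.6, 3, 0.6)              # gap bins 15:16 = 4 cm
  f <- detect_place_fields(make_curve(rep(1, 40), x))
  expect_equal(nrow(f), 1)
  expect_equal(f$peak_rate, 3)

  # triangular peak: boundaries at the 10% crossings
  nb <- 60
  apex <- 30
  tri <- pmax(0, 5 * (1 - abs(seq_len(nb) - apex) / 12.5))
  f <- detect_place_fields(make_curve(rep(1, nb), tri))
  expect_equal(nrow(f), 1)
  expect_equal(f$peak_pos, make_curve(rep(1, nb), tri)$bin_centers[apex])
  expect_equal(f$length, 24, tolerance = 4)   # 10% crossing at +/- ~11.25 bins

  # idempotence and disjointness on a multi-peak curve
  set.seed(5)
  y <- gauss_smooth(rpois(100, 2) * runif(100), 2)
  f1 <- detect_place_fields(make_curve(rep(1, 100), y))
  if (nrow(f1) > 1) expect_true(all(f1$start[-1] > f1$end[-nrow(f1)]))
})

test_that("cell classification applies the rate thresholds strictly", {
  sess <- data.frame(cell_id = c("a", "b", "c", "d"),
                     mean_rate = c(7.5, 3, 0.2, 7.0))
  traj <- data.frame(cell_id = c("a", "b", "c", "d"),
                     mean_rate = c(2.0, 0.6, 0.5, 0.4))
  cl <- classify_cells(sess, traj)
  cl <- cl[match(c("a", "b", "c", "d"), cl$cell_id), ]
  expect_equal(cl$is_pyramidal, c(FALSE, TRUE, TRUE, TRUE))   # 7.5 > 7; 7.0 allowed
  # b: 0.6 Hz on one trajectory -> active; c: exactly 0.5 -> not (strict >)
  expect_equal(cl$is_run_active, c(FALSE, TRUE, FALSE, FALSE))
})
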