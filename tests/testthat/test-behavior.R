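test_that("linearize projects onto the track and flags off-path samples", {
  geom <- track_geometry(200)
  pos <- data.frame(timestamp = c(0.1, 0.2, 0.3, 0.4),
                    x = c(0, 100, 205, 100), y = c(0, 0, 0, 50))
  lin <- linearize(pos, geom)
  expect_equal(lin$linear_pos[1], 0)        # endpoint A
  expect_equal(lin$linear_pos[2], 100)      # midpoint
  expect_equal(lin$linear_pos[3], 200)      # clamped beyond B, still near path
  expect_false(lin$valid[4])                # 50 cm off the path
  expect_equal(attr(lin, "n_off_path"), 1)
})

test_that("projection error on noisy samples stays below the noise scale", {
  set.seed(11)
  pos <- triangle_position(3)
  noisy <- pos
  noisy$x <- pos$x + rnorm(nrow(pos), sd = 1)
  noisy$y <- rnorm(nrow(pos), sd = 1)
  lin <- linearize(noisy, track_geometry(200))
  err <- abs(lin$linear_pos - pmin(pmax(pos$x, 0), 200))
  expect_lt(mean(err), 1.5)
})

test_that("lap segmentation counts full excursions only", {
  pos <- triangle_position(5)
  lin <- linearize(pos, track_geometry(200))
  laps <- segment_laps(lin)
  expect_equal(sum(laps$trajectory == "AtoB"), 5)
  expect_equal(sum(laps$trajectory == "BtoA"), 5)
  expect_true(all(laps$end_time > laps$start_time))

  # stationary animal: no laps
  still <- data.frame(timestamp = seq(0, 10, by = 0.03), x = 50, y = 0)
  expect_equal(nrow(segment_laps(linearize(still, track_geometry(200)))), 0)

  # excursion reaching only 120 of 200 cm then returning: not a lap
  t <- seq(0, 24, by = 1 / 33)
  x <- 120 * (1 - abs(t - 12) / 12)      # 0 -> 120 -> 0
  part <- data.frame(timestamp = t, x = x, y = 0)
  expect_equal(nrow(segment_laps(linearize(part, track_geometry(200)))), 0)
})

test_that("lap count is invariant to a uniform time shift", {
  pos <- triangle_position(4)
  shifted <- pos
  shifted$timestamp <- pos$timestamp + 1234.5
  l1 <- segment_laps(linearize(pos, track_geometry(200)))
  l2 <- segment_laps(linearize(shifted, track_geometry(200)))
  expect_equal(nrow(l1), nrow(l2))
  expect_equal(l2$start_time - 1234.5, l1$start_time, tolerance = 1e-9)
})

test_that("speed recovers uniform, zero and sinusoidal motion", {
  t <- seq(0, 20, by = 1 / 33)
  unif <- data.frame(timestamp = t, x = 10 * t, y = 0)
  v <- compute_speed(unif)
  inner <- seq(20, length(t) - 20)
  expect_equal(mean(v[inner]), 10, tolerance = 0.01)

  still <- data.frame(timestamp = t, x = 5, y = 7)
  expect_lt(max(compute_speed(still)), 1e-10)

  sine <- data.frame(timestamp = t, x = 10 * sin(2 * pi * t), y = 0)
  vpk <- max(compute_speed(sine, smooth_window = 0.03), na.rm = TRUE)
  expect_equal(vpk, 2 * pi * 10, tolerance = 0.05 * 2 * pi * 10)
})

test_that("motion filter masks long stops but keeps brief dips", {
  rate <- 33
  n <- 10 * rate
  x <- numeric(n)
  speed <- rep(10, n)
  speed[(2 * rate):(4 * rate)] <- 0          # 2 s full stop
  speed[(6 * rate):(6 * rate + 16)] <- 1     # ~0.5 s dip below 3 cm/s
  lin <- lin_from_x(seq(20, 180, length.out = n), rate = rate)
  out <- motion_filter(lin, speed)
  expect_true(all(!out$valid[(2 * rate + 1):(4 * rate - 1)]))
  expect_true(all(out$valid[(6 * rate):(6 * rate + 16)]))

  # constant running far from reward sites: nothing masked
  all_fast <- motion_filter(lin_from_x(seq(20, 180, length.out = n), rate = rate),
                            rep(10, n))
  expect_true(all(all_fast$valid))

  # idempotence
  twice <- motion_filter(out, speed)
  expect_identical(out$valid, twice$valid)
})

test_that("reward-site samples are excluded", {
  lin <- lin_from_x(seq(0, 200, length.out = 300))
  out <- motion_filter(lin, rep(10, 300))
  expect_true(all(!out$valid[lin$linear_pos <= 4]))
  expect_true(all(!out$valid[lin$linear_pos >= 196]))
  expect_true(all(out$valid[lin$linear_pos > 4.5 & lin$linear_pos < 195.5]))
})
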