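# build a rest-like trace with bursts at known times; near-rectangular
# envelope (short cosine ramps) so the detected extent tracks the true one
burst_trace <- function(burst_starts, dur_s = 0.1, freq = 150, amp_sd = 8,
                        total_s = 60, fs = 2000, ramp_s = 0.01, seed = 1) {
  set.seed(seed)
  x <- rnorm(total_s * fs)
  sd0 <- sd(bandpass(x, fs, 100, 250))
  for (t0 in burst_starts) {
    m <- round(dur_s * fs)
    idx <- round(t0 * fs) + seq_len(m)
    tt <- seq_len(m) / fs
    env <- rep(1, m)
    nr <- round(ramp_s * fs)
    env[1:nr] <- (1 - cos(pi * seq_len(nr) / nr)) / 2
    env[(m - nr + 1):m] <- rev(env[1:nr])
    x[idx] <- x[idx] + amp_sd * sd0 * env * sin(2 * pi * freq * tt)
  }
  lfp_trace(x, rate = fs)
}

test_that("a single injected burst is detected with its duration and frequency", {
  lfp <- burst_trace(30, dur_s = 0.1, freq = 150, amp_sd = 8, seed = 2)
  ev <- detect_ripples(lfp)
  expect_equal(nrow(ev), 1)
  expect_gt(ev$start, 29.9); expect_lt(ev$end, 30.25)
  expect_gte(ev$duration_ms, 80); expect_lte(ev$duration_ms, 140)
  expect_lt(abs(ev$freq_hz - 150), 10)
  expect_gte(ev$peak_sd, 6)
})

test_that("nearby bursts merge and out-of-range durations are rejected", {
  # two 6.5 sd bursts separated by a 20 ms gap: one merged event
  lfp <- burst_trace(c(20, 20.07), dur_s = 0.05, amp_sd = 6.5, seed = 3)
  ev <- detect_ripples(lfp)
  expect_equal(nrow(ev), 1)

  # a 600 ms burst exceeds the duration ceiling
  long <- burst_trace(20, dur_s = 0.6, amp_sd = 8, seed = 4)
  expect_equal(nrow(detect_ripples(long)), 0)

  # traces shorter than 1 s are refused
  expect_error(detect_ripples(lfp_trace(rnorm(500), rate = 2000)), "1 s")
})

test_that("detection is invariant to the recording gain", {
  lfp <- burst_trace(c(10, 25, 40), dur_s = 0.08, amp_sd = 7, seed = 5)
  ev1 <- detect_ripples(lfp)
  ev2 <- detect_ripples(lfp_trace(lfp$samples * 2, rate = lfp$rate))
  expect_equal(ev1$start, ev2$start)
  expect_equal(ev1$end, ev2$end)
  expect_equal(ev2$amplitude, 2 * ev1$amplitude)
})

test_that("detected events are sorted, disjoint and above threshold", {
  rs <- generate_rest_session(rest_sim_config(duration = 120, seed = 9))
  ev <- detect_ripples(rs$lfp)
  expect_gt(nrow(ev), 10)
  expect_true(all(diff(ev$start) > 0))
  expect_true(all(ev$start[-1] >= ev$end[-nrow(ev)]))
  expect_true(all(ev$peak_sd >= 6))
  expect_true(all(ev$duration_ms >= 30 & ev$duration_ms <= 500))
})

test_that("session summary reports occurrence rate and event means", {
  ev <- data.frame(start = seq_len(60), end = seq_len(60) + 0.05,
                   duration_ms = 50, amplitude = 40, freq_hz = 150,
                   peak_sd = 7)
  s <- ripple_session_summary(ev, 600)
  expect_equal(s$rate_hz, 0.1)
  empty <- ripple_session_summary(ev[0, ], 600)
  expect_equal(empty$rate_hz, 0)
  expect_true(is.na(empty$mean_duration_ms))
})

test_that("ripple firing statistics match the Poisson closed form", {
  ev <- data.frame(start = seq(1, by = 1, length.out = 50),
                   end = seq(1, by = 1, length.out = 50) + 0.1)
  st <- ev$start + 0.05
  full <- ripple_firing_stats(st, ev)
  expect_equal(full$participation_rate, 1)
  none <- ripple_firing_stats(numeric(0), ev)
  expect_equal(none$participation_rate, 0)
  expect_equal(none$spikes_per_ripple, 0)

  # Poisson cell at rate r: participation ~= 1 - exp(-r d)
  set.seed(31)
  r <- 8; d <- 0.1
  parts <- replicate(60, {
    spk <- sort(runif(rpois(1, r * 60), 0, 60))
    ev2 <- data.frame(start = seq(0.5, by = 1, length.out = 50),
                      end = seq(0.5, by = 1, length.out = 50) + d)
    ripple_firing_stats(spk, ev2)$participation_rate
  })
  expect_equal(mean(parts), 1 - exp(-r * d), tolerance = 0.03)
})
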