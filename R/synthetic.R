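#' Configuration for a synthetic track-running session
#'
#' The simulated animal runs back and forth on a linear track at constant
#' speed, completing `n_laps_per_trajectory` laps in each direction. Each
#' cell is a Gaussian-tuned place cell spiking as an inhomogeneous Poisson
#' process; within its field, spike theta phases precess linearly with the
#' distance traveled into the field, with von Mises jitter.
#'
#' @param track_length cm (default 200, a ~2 m track).
#' @param n_laps_per_trajectory laps per running direction.
#' @param run_speed cm/s (default 20, a typical mouse running speed).
#' @param field_centers cm, one per cell; must lie on the track.
#' @param field_widths Gaussian tuning sd per cell, cm.
#' @param peak_rates in-field peak rate per cell, Hz.
#' @param theta_freq theta frequency, Hz (default 8, inside the 6-10 band).
#' @param precession_slope signed phase slope vs distance into the field,
#'   deg/cm per cell (default -6: one precession cycle across a 60 cm field).
#' @param entry_phase theta phase at field entry, degrees.
#' @param phase_noise_kappa von Mises concentration of the phase jitter.
#' @param position_rate position sampling rate, Hz (default 33).
#' @param lfp_rate LFP sampling rate, Hz (default 2000).
#' @param seed integer seed.
#' @return validated config list.
#' @export
track_sim_config <- function(track_length = 200, n_laps_per_trajectory = 20,
                             run_speed = 20,
                             field_centers = c(40, 80, 120, 160),
                             field_widths = 10, peak_rates = 15,
                             theta_freq = 8, precession_slope = -6,
                             entry_phase = 340, phase_noise_kappa = 4,
                             position_rate = 33, lfp_rate = 2000, seed = 1) {
  n <- length(field_centers)
  rep_n <- function(x) if (length(x) == 1) rep(x, n) else x
  field_widths <- rep_n(field_widths); peak_rates <- rep_n(peak_rates)
  precession_slope <- rep_n(precession_slope)
  stopifnot(track_length > 0, n_laps_per_trajectory >= 1, run_speed > 0,
            length(field_widths) == n, length(peak_rates) == n,
            length(precession_slope) == n,
            all(peak_rates >= 0), all(field_widths > 0),
            position_rate > 0, lfp_rate > 0, theta_freq > 0)
  if (any(field_centers < 0 | field_centers > track_length))
    stop("field centers must lie within [0, track_length]")
  list(track_length = track_length,
       n_laps_per_trajectory = n_laps_per_trajectory, run_speed = run_speed,
       n_cells = n, field_centers = field_centers,
       field_widths = field_widths, peak_rates = peak_rates,
       theta_freq = theta_freq, precession_slope = precession_slope,
       entry_phase = entry_phase, phase_noise_kappa = phase_noise_kappa,
       position_rate = position_rate, lfp_rate = lfp_rate,
       seed = as.integer(seed))
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); mu, output in rad
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

# triangle-wave track position at arbitrary times
track_position_at <- function(t, L, v) {
  period <- 2 * L / v
  tau <- t %% period
  ifelse(tau < L / v, v * tau, 2 * L - v * tau)
}

#' Generate a synthetic track-running session
#'
#' Position is a triangle wave (constant-speed laps alternating direction),
#' the LFP a pure theta oscillation (trough at phase 0), and each cell's
#' spikes are drawn by thinning from its Gaussian spatial tuning. Spikes
#' falling inside the field (center +/- 3 sd) are then nudged within their
#' theta cycle to the time whose theta phase equals the precession target
#' `entry_phase + slope * distance_into_field + vonMises(kappa)`; this gives
#' exact phase ground truth while leaving the Poisson spike count untouched.
#'
#' @param config a [track_sim_config()].
#' @return list with `position` (data.frame timestamp, x, y), `spikes` (named
#'   list of sorted spike-time vectors), `lfp` ([lfp_trace()]), and
#'   `ground_truth` (field intervals, precession slopes, per-spike target
#'   phases, lap count, config).
#' @export
generate_track_session <- function(config) {
  L <- config$track_length; v <- config$run_speed
  period <- 2 * L / v
  duration <- config$n_laps_per_trajectory * period
  set.seed(child_seed(config$seed, 1))

  ts <- seq(0, duration, by = 1 / config$position_rate)
  position <- data.frame(timestamp = ts,
                         x = track_position_at(ts, L, v), y = 0)

  t_lfp <- seq(0, duration, by = 1 / config$lfp_rate)
  lfp <- lfp_trace(-50 * cos(2 * pi * config$theta_freq * t_lfp),
                   rate = config$lfp_rate, start_time = 0)

  f <- config$theta_freq
  spikes <- list(); phases_gt <- list(); fields <- list()
  for (ci in seq_len(config$n_cells)) {
    ctr <- config$field_centers[ci]; w <- config$field_widths[ci]
    pk <- config$peak_rates[ci]
    f_lo <- max(0, ctr - 3 * w); f_hi <- min(L, ctr + 3 * w)
    fields[[ci]] <- c(start = f_lo, end = f_hi)
    if (pk <= 0) {
      spikes[[ci]] <- numeric(0); phases_gt[[ci]] <- numeric(0)
      next
    }
    # thinning: homogeneous candidates at the peak rate
    n_cand <- stats::rpois(1, pk * duration)
    cand <- sort(stats::runif(n_cand, 0, duration))
    xc <- track_position_at(cand, L, v)
    keep <- stats::runif(n_cand) < exp(-(xc - ctr)^2 / (2 * w^2))
    st <- cand[keep]; xs <- xc[keep]
    ph <- rep(NA_real_, length(st))
    infield <- xs >= f_lo & xs <= f_hi
    if (any(infield)) {
      going_up <- (st[infield] %% period) < L / v
      d <- ifelse(going_up, xs[infield] - f_lo, f_hi - xs[infield])
      noise <- rvonmises(sum(infield), 0, config$phase_noise_kappa) * 180 / pi
      noise <- ifelse(noise > 180, noise - 360, noise)
      target <- wrap360(config$entry_phase +
                          config$precession_slope[ci] * d + noise)
      # move each spike to the nearest time with that theta phase
      k <- floor(st[infield] * f)
      tt <- st[infield]
      cands <- cbind((k - 1 + target / 360) / f, (k + target / 360) / f,
                     (k + 1 + target / 360) / f)
      pick <- max.col(-abs(cands - tt), ties.method = "first")
      newt <- cands[cbind(seq_along(tt), pick)]
      newt <- pmin(pmax(newt, 0), duration)
      st[infield] <- newt
      ph[infield] <- target
    }
    o <- order(st)
    spikes[[ci]] <- st[o]; phases_gt[[ci]] <- ph[o]
  }
  names(spikes) <- names(phases_gt) <- sprintf("cell%02d", seq_len(config$n_cells))

  list(position = position, spikes = spikes, lfp = lfp,
       ground_truth = list(
         true_field_intervals = do.call(rbind, fields),
         true_precession_slopes = config$precession_slope,
         spike_phases = phases_gt,
         n_laps = config$n_laps_per_trajectory,
         duration = duration, config = config))
}

#' Configuration for a synthetic rest session
#'
#' Rest LFP is 1/f ("pink") background noise scaled so that the sd of its
#' ripple-band-filtered version is one amplitude unit; ripple bursts are
#' Hann-windowed sinusoids at `ripple_freq` whose peak amplitude is
#' `ripple_amplitude_sd_units` of that unit. Spike trains are homogeneous
#' Poisson background; designated cell pairs additionally receive, per
#' ripple with probability `coincidence_rate`, one spike each inside a
#' common 20 ms sub-window — the knob that drives pairwise coactivity.
#'
#' @param duration rest duration, s (default 600; typical sessions are
#'   10-15 min).
#' @param ripple_rate ripple occurrence rate, events/s (default 0.3).
#' @param ripple_freq intra-ripple oscillation frequency, Hz (must lie in
#'   100-250; default 150).
#' @param ripple_duration_mean mean burst duration, ms (default 100).
#' @param ripple_amplitude_sd_units burst peak amplitude in background
#'   ripple-band sd units (default 8).
#' @param background_rates Hz per cell (default 1 Hz for 6 cells).
#' @param coincidence_pairs 2-column matrix of cell indices receiving
#'   injected coincidences (default: all pairs).
#' @param coincidence_rate per-ripple coincidence probability, in [0, 1];
#'   scalar or one per pair.
#' @param min_gap minimal gap enforced between consecutive ripples, s.
#' @param seed integer seed.
#' @return validated config list.
#' @export
rest_sim_config <- function(duration = 600, ripple_rate = 0.3,
                            ripple_freq = 150, ripple_duration_mean = 100,
                            ripple_amplitude_sd_units = 8,
                            background_rates = rep(1, 6),
                            coincidence_pairs = NULL, coincidence_rate = 0,
                            min_gap = 0.2, seed = 1) {
  if (duration <= 0) stop("duration must be positive")
  if (ripple_freq < 100 || ripple_freq > 250)
    stop("ripple_freq must lie within the 100-250 Hz ripple band")
  n <- length(background_rates)
  if (is.null(coincidence_pairs) && n >= 2)
    coincidence_pairs <- t(utils::combn(n, 2))
  npair <- if (is.null(coincidence_pairs)) 0 else nrow(coincidence_pairs)
  if (length(coincidence_rate) == 1) coincidence_rate <- rep(coincidence_rate, npair)
  stopifnot(all(coincidence_rate >= 0), all(coincidence_rate <= 1),
            length(coincidence_rate) == npair,
            all(background_rates >= 0), ripple_amplitude_sd_units > 0,
            ripple_duration_mean > 0)
  if (ripple_rate * duration < 1)
    warning("expected fewer than one ripple in the session; ",
            "statistics will be unreliable")
  list(duration = duration, ripple_rate = ripple_rate,
       ripple_freq = ripple_freq, ripple_duration_mean = ripple_duration_mean,
       ripple_amplitude_sd_units = ripple_amplitude_sd_units,
       background_rates = background_rates, n_cells = n,
       coincidence_pairs = coincidence_pairs,
       coincidence_rate = coincidence_rate, min_gap = min_gap,
       seed = as.integer(seed), lfp_rate = 2000)
}

# pink (1/f) noise of length n at sampling rate fs
pink_noise <- function(n, fs) {
  wh <- stats::rnorm(n)
  sp <- stats::fft(wh)
  f <- seq(0, n - 1) / n * fs
  f <- pmin(f, fs - f)
  scale <- 1 / sqrt(pmax(f, 1))           # flat below 1 Hz, 1/f above
  Re(stats::fft(sp * scale, inverse = TRUE)) / n
}

#' Generate a synthetic rest session
#'
#' @param config a [rest_sim_config()].
#' @return list with `lfp` ([lfp_trace()]), `spikes` (named list of sorted
#'   spike-time vectors) and `ground_truth` (`true_ripple_intervals`
#'   data.frame start/end in s, `injected_pair_synchrony`, config).
#' @export
generate_rest_session <- function(config) {
  set.seed(child_seed(config$seed, 2))
  fs <- config$lfp_rate
  n <- round(config$duration * fs)

  bg <- pink_noise(n, fs)
  band_sd <- stats::sd(bandpass(bg, fs, 100, 250, method = "butter"))
  bg <- bg / band_sd * 5                   # 5 uV ripple-band background sd
  unit <- 5                                # one amplitude unit, uV

  # ripple times: exponential gaps with an enforced minimum separation
  starts <- c(); durs <- c()
  t <- stats::rexp(1, config$ripple_rate)
  while (TRUE) {
    d <- stats::rnorm(1, config$ripple_duration_mean,
                      0.15 * config$ripple_duration_mean) / 1000
    d <- min(max(d, 0.5 * config$ripple_duration_mean / 1000),
             1.5 * config$ripple_duration_mean / 1000)
    if (t + d > config$duration - 0.5) break
    starts <- c(starts, t); durs <- c(durs, d)
    t <- t + d + config$min_gap + stats::rexp(1, config$ripple_rate)
  }

  samples <- bg
  amp <- config$ripple_amplitude_sd_units * unit
  for (j in seq_along(starts)) {
    i0 <- round(starts[j] * fs) + 1
    m <- round(durs[j] * fs)
    idx <- i0:(i0 + m - 1)
    hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, m - 1) / (m - 1))
    tt <- (idx - 1) / fs
    samples[idx] <- samples[idx] +
      amp * hann * sin(2 * pi * config$ripple_freq * (tt - starts[j]))
  }
  lfp <- lfp_trace(samples, rate = fs, start_time = 0)

  spikes <- lapply(config$background_rates, function(r) {
    k <- stats::rpois(1, r * config$duration)
    sort(stats::runif(k, 0, config$duration))
  })
  names(spikes) <- sprintf("cell%02d", seq_len(config$n_cells))

  pairs <- config$coincidence_pairs
  if (!is.null(pairs) && length(starts) > 0) {
    for (p in seq_len(nrow(pairs))) {
      pr <- config$coincidence_rate[p]
      if (pr <= 0) next
      hit <- stats::runif(length(starts)) < pr
      for (j in which(hit)) {
        lo <- starts[j]; hi <- starts[j] + durs[j] - 0.02
        t0 <- if (hi > lo) stats::runif(1, lo, hi) else lo
        spikes[[pairs[p, 1]]] <- c(spikes[[pairs[p, 1]]],
                                   t0 + stats::runif(1, 0, 0.02))
        spikes[[pairs[p, 2]]] <- c(spikes[[pairs[p, 2]]],
                                   t0 + stats::runif(1, 0, 0.02))
      }
    }
    spikes <- lapply(spikes, sort)
  }

  list(lfp = lfp, spikes = spikes,
       ground_truth = list(
         true_ripple_intervals = data.frame(start = starts,
                                            end = starts + durs),
         injected_pair_synchrony = if (is.null(pairs)) NULL else
           data.frame(cell_a = pairs[, 1], cell_b = pairs[, 2],
                      rate = config$coincidence_rate),
         config = config))
}

#' Generate a synthetic cohort of animals
#'
#' Each animal contributes a Pre-run rest session, a Run 1 track session and
#' a Post-run rest session. The `"WT-like"` preset injects a low per-ripple
#' coincidence rate in Pre-run and a high one in Post-run (experience-driven
#' increase in within-ripple synchrony); `"RTT-like"` injects an equally
#' elevated rate in both rest sessions (baseline hypersynchrony, no
#' increase).
#'
#' @param preset `"WT-like"` or `"RTT-like"`.
#' @param n_animals number of animals (>= 1).
#' @param seed integer seed; per-animal/session child seeds are derived
#'   deterministically.
#' @param n_cells place cells per animal (default 3, giving pair counts per cohort on the scale of a typical tetrode study).
#' @param rest_duration rest-session length, s (default 600).
#' @param coincidence_rates named list overriding the preset's `pre`/`post`
#'   per-ripple coincidence probabilities.
#' @return list of animals; each is a list `animal_id`, `preset`, `pre_run`,
#'   `run1`, `post_run` (the rest/track session objects).
#' @export
generate_cohort <- function(preset = c("WT-like", "RTT-like"), n_animals,
                            seed = 1, n_cells = 3, rest_duration = 600,
                            coincidence_rates = NULL) {
  preset <- match.arg(preset)
  if (n_animals < 1) stop("n_animals must be >= 1")
  rates <- if (!is.null(coincidence_rates)) coincidence_rates
  else if (preset == "WT-like") list(pre = 0.01, post = 0.12)
  else list(pre = 0.12, post = 0.12)

  lapply(seq_len(n_animals), function(a) {
    base <- child_seed(seed, a * 17)
    centers <- seq(20, 180, length.out = n_cells)
    run1 <- generate_track_session(track_sim_config(
      field_centers = centers, seed = child_seed(base, 2)))
    pre <- generate_rest_session(rest_sim_config(
      duration = rest_duration, background_rates = rep(1, n_cells),
      coincidence_rate = rates$pre, seed = child_seed(base, 1)))
    post <- generate_rest_session(rest_sim_config(
      duration = rest_duration, background_rates = rep(1, n_cells),
      coincidence_rate = rates$post, seed = child_seed(base, 3)))
    list(animal_id = sprintf("%s_%02d", sub("-like", "", preset), a),
         preset = preset, pre_run = pre, run1 = run1, post_run = post)
  })
}
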