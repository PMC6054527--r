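#' Theta-band parameters
#'
#' @param band theta band edges in Hz (default 6-10).
#' @param phase_convention only `"trough0"` is defined: the trough of the
#'   filtered theta oscillation is phase 0 degrees, the peak 180.
#' @return parameter list.
#' @export
theta_params <- function(band = c(6, 10), phase_convention = "trough0") {
  stopifnot(length(band) == 2, band[1] < band[2], band[1] > 0)
  phase_convention <- match.arg(phase_convention, "trough0")
  list(band = band, phase_convention = phase_convention)
}

#' Theta phase of each spike from the LFP
#'
#' The LFP is band-passed in the theta range with an exact zero-phase FFT
#' filter, its instantaneous phase taken from the analytic signal, and the
#' (unwrapped) phase linearly interpolated at spike times. Phase convention:
#' trough = 0 degrees. Spikes outside the LFP coverage are dropped; their
#' count is attached as attribute `n_dropped`.
#'
#' @param spike_times spike timestamps (s).
#' @param lfp list with `samples` (numeric), `rate` (Hz) and `start_time` (s,
#'   default 0) — see [lfp_trace()].
#' @param params [theta_params()].
#' @return numeric vector of phases in degrees `[0, 360)`, one per retained
#'   spike, with attribute `n_dropped`.
#' @export
assign_spike_phases <- function(spike_times, lfp, params = theta_params()) {
  start <- lfp$start_time %||% 0
  t_lfp <- start + (seq_along(lfp$samples) - 1) / lfp$rate
  inside <- spike_times >= t_lfp[1] & spike_times <= t_lfp[length(t_lfp)]
  dropped <- sum(!inside)
  st <- spike_times[inside]

  th <- bandpass(lfp$samples, lfp$rate, params$band[1], params$band[2],
                 method = "fft")
  # Arg(analytic) is 0 at the oscillation peak; shift by 180 for trough = 0
  ph <- Arg(analytic_signal(th)) * 180 / pi + 180
  # unwrap before interpolating so phases near the 0/360 seam stay exact
  unwrapped <- ph + 360 * cumsum(c(0, diff(ph) < -180)) -
    360 * cumsum(c(0, diff(ph) > 180))
  out <- wrap360(stats::approx(t_lfp, unwrapped, xout = st)$y)
  attr(out, "n_dropped") <- dropped
  out
}

#' Optimal linear regression of phase on position
#'
#' Ordinary least squares cannot be applied to circular phases directly, so
#' the phases are rotated: for every integer shift delta in 0..359 degrees the
#' phases are wrapped into `[delta, delta + 360)` and an OLS fit of phase
#' against position is computed; the rotation maximizing `|r|` wins (ties go
#' to the smallest shift). The winning slope is reported in deg/cm.
#'
#' @param phases spike theta phases in degrees.
#' @param positions spike positions (cm); any constant offset is immaterial.
#' @param min_spikes minimal number of spikes for a fit (default 5).
#' @return list `slope` (deg/cm), `r`, `shift` (deg), `n`; all `NA` when
#'   fewer than `min_spikes` spikes.
#' @export
optimal_linear_fit <- function(phases, positions, min_spikes = 5) {
  n <- length(phases)
  stopifnot(length(positions) == n)
  if (n < min_spikes) return(list(slope = NA_real_, r = NA_real_,
                                  shift = NA_real_, n = n))
  ph0 <- wrap360(phases)
  s <- positions - mean(positions)
  ss <- sum(s^2)
  if (ss == 0) return(list(slope = NA_real_, r = NA_real_,
                           shift = NA_real_, n = n))
  best <- list(slope = NA_real_, r = NA_real_, shift = NA_real_)
  best_abs <- -1
  for (delta in 0:359) {
    y <- ph0
    y[y < delta] <- y[y < delta] + 360       # wrap into [delta, delta + 360)
    yc <- y - mean(y)
    sy <- sum(yc^2)
    if (sy == 0) next
    r <- sum(s * yc) / sqrt(ss * sy)
    if (abs(r) > best_abs + 1e-12) {
      best <- list(slope = sum(s * yc) / ss, r = r, shift = delta)
      best_abs <- abs(r)
    }
  }
  if (!is.finite(best$r)) return(list(slope = NA_real_, r = NA_real_,
                                      shift = NA_real_, n = n))
  c(best, list(n = n))
}

#' Circular-linear regression of phase on position
#'
#' Fits phase = 2 pi a s + phi0 by maximizing the mean resultant length
#' \deqn{R(a) = \left| n^{-1} \sum_j e^{i(\phi_j - 2\pi a s_j)} \right|}
#' over a bounded slope range (dense grid then golden-section refinement;
#' R(a) is multimodal, so the grid step must be fine relative to 1/range(s)).
#' The offset is the argument of the resultant at the optimum. The
#' circular-linear correlation between the phases and the fitted circular
#' variable theta_j = 2 pi |a| s_j is computed with the sine-product formula
#' \deqn{\rho = \frac{\sum_j \sin(\phi_j - \bar\phi)\sin(\theta_j - \bar\theta)}
#'   {\sqrt{\sum_j \sin^2(\phi_j - \bar\phi) \sum_j \sin^2(\theta_j - \bar\theta)}}}
#' with circular means, signed by the slope direction.
#'
#' @param phases spike theta phases in degrees.
#' @param positions spike positions (cm).
#' @param slope_bounds allowed slope range in cycles/cm (default +/-0.05,
#'   i.e. at least two full cycles across a 40 cm field).
#' @param min_spikes minimal number of spikes (default 5).
#' @param grid_step grid resolution in cycles/cm (default 1e-3).
#' @return list `slope` (cycles/cm), `offset` (deg in [0, 360)), `rho`, `n`.
#'   `rho` is `NA` if all phases are identical.
#' @export
circular_linear_fit <- function(phases, positions,
                                slope_bounds = c(-0.05, 0.05),
                                min_spikes = 5, grid_step = 1e-3) {
  n <- length(phases)
  stopifnot(length(positions) == n, slope_bounds[1] < slope_bounds[2])
  if (n < min_spikes) return(list(slope = NA_real_, offset = NA_real_,
                                  rho = NA_real_, n = n))
  phi <- phases * pi / 180
  s <- positions - mean(positions)

  Rfun <- function(a) Mod(mean(exp(1i * (phi - 2 * pi * a * s))))
  grid <- seq(slope_bounds[1], slope_bounds[2], by = grid_step)
  Rg <- vapply(grid, Rfun, numeric(1))
  k <- which.max(Rg)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(Rfun, c(lo, hi), maximum = TRUE, tol = 1e-7)
  a <- opt$maximum
  offset <- wrap360(Arg(mean(exp(1i * (phi - 2 * pi * a * s)))) * 180 / pi)

  theta <- (2 * pi * abs(a) * s) %% (2 * pi)
  cmean <- function(x) Arg(mean(exp(1i * x)))
  sp <- sin(phi - cmean(phi)); st <- sin(theta - cmean(theta))
  den <- sqrt(sum(sp^2) * sum(st^2))
  rho <- if (den == 0) NA_real_ else sign(a) * sum(sp * st) / den
  list(slope = a, offset = offset, rho = rho, n = n)
}

#' Precession fits for all spikes within a place field
#'
#' Pools spikes across all laps whose interpolated position lies inside the
#' field, assigns their theta phases, and runs both the optimal linear and
#' the circular-linear regression. Positions are converted to distance
#' traveled into the field along the running direction, so precession slopes
#' from the two trajectories of a back-and-forth track are directly
#' comparable.
#'
#' @param spike_times spike timestamps (s).
#' @param spike_positions linearized positions at those times (cm).
#' @param field one row of [detect_place_fields()] output (`start`, `end`).
#' @param lfp [lfp_trace()] covering the session.
#' @param theta [theta_params()].
#' @param direction `"AtoB"` (field entered at `start`) or `"BtoA"` (entered
#'   at `end`).
#' @return list with `n_spikes`, `linear` ([optimal_linear_fit()] result) and
#'   `circular` ([circular_linear_fit()] result).
#' @export
fit_field_precession <- function(spike_times, spike_positions, field, lfp,
                                 theta = theta_params(),
                                 direction = c("AtoB", "BtoA")) {
  direction <- match.arg(direction)
  stopifnot(length(spike_times) == length(spike_positions))
  inside <- spike_positions >= field$start & spike_positions <= field$end
  st <- spike_times[inside]
  sp <- if (direction == "AtoB") spike_positions[inside] - field$start
        else field$end - spike_positions[inside]
  lfp_start <- lfp$start_time %||% 0
  lfp_end <- lfp_start + (length(lfp$samples) - 1) / lfp$rate
  covered <- st >= lfp_start & st <= lfp_end
  st <- st[covered]; sp <- sp[covered]
  ph <- assign_spike_phases(st, lfp, theta)
  list(n_spikes = length(st),
       linear = optimal_linear_fit(as.numeric(ph), sp),
       circular = circular_linear_fit(as.numeric(ph), sp))
}
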