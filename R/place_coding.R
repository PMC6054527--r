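#' Spatial binning parameters
#'
#' Trajectories are divided into 2 cm bins and rate curves smoothed with a
#' Gaussian kernel of sigma 2 bins; both follow the standard linear-track
#' convention and are configurable.
#'
#' @param bin_size bin width in cm.
#' @param smooth_sigma Gaussian sd in bins (0 disables smoothing).
#' @return parameter list.
#' @export
binning_params <- function(bin_size = 2, smooth_sigma = 2) {
  stopifnot(bin_size > 0, smooth_sigma >= 0)
  list(bin_size = bin_size, smooth_sigma = smooth_sigma)
}

#' Per-trajectory firing rate curve
#'
#' Occupancy per spatial bin is accumulated from valid (unmasked) position
#' samples falling inside the given laps; each cell's spike count per bin uses
#' the linearized position interpolated at the spike time, with spikes during
#' masked samples excluded. The raw rate is count/occupancy per bin, then
#' Gaussian-smoothed; bins never occupied carry `NA` and are excluded from the
#' occupancy probabilities.
#'
#' @param spike_times numeric vector of spike timestamps (s, sorted).
#' @param lin linearized series ([linearize()]), mask already applied.
#' @param laps lap table for a single trajectory ([segment_laps()] subset).
#' @param params [binning_params()].
#' @return object of class `rate_curve`: list with `bin_centers`, `occupancy`
#'   (s), `counts`, `rate_raw`, `rate` (smoothed, Hz), `p` (occupancy
#'   probability, `NA` for unoccupied bins), `mean_rate` (occupancy-weighted
#'   mean rate, Hz), `trajectory`, `params`.
#' @export
compute_rate_curve <- function(spike_times, lin, laps, params = binning_params()) {
  L <- attr(lin, "track_length")
  stopifnot(!is.null(L))
  if (nrow(laps) > 0 && length(unique(laps$trajectory)) > 1)
    stop("laps must belong to a single trajectory")
  edges <- seq(0, L, by = params$bin_size)
  if (edges[length(edges)] < L) edges <- c(edges, L)
  nb <- length(edges) - 1L
  centers <- (edges[-1] + edges[-length(edges)]) / 2

  in_lap <- function(tt) {
    if (nrow(laps) == 0) return(rep(FALSE, length(tt)))
    out <- rep(FALSE, length(tt))
    for (j in seq_len(nrow(laps)))
      out <- out | (tt >= laps$start_time[j] & tt < laps$end_time[j])
    out
  }

  keep <- lin$valid & in_lap(lin$timestamp)
  dt <- stats::median(diff(lin$timestamp))
  bin_of <- function(pos) pmin(nb, pmax(1L, findInterval(pos, edges,
                                                         rightmost.closed = TRUE)))
  occ <- numeric(nb)
  if (any(keep)) {
    tab <- tabulate(bin_of(lin$linear_pos[keep]), nbins = nb)
    occ <- tab * dt
  }
  if (sum(occ) == 0) stop("zero total occupancy on this trajectory")

  st <- spike_times[in_lap(spike_times)]
  counts <- numeric(nb)
  if (length(st) > 0) {
    # nearest position sample decides both the spike's bin and its mask state
    idx <- findInterval(st, lin$timestamp, all.inside = TRUE)
    nxt <- pmin(idx + 1L, nrow(lin))
    use_next <- abs(lin$timestamp[nxt] - st) < abs(lin$timestamp[idx] - st)
    idx[use_next] <- nxt[use_next]
    ok <- keep[idx]
    pos <- stats::approx(lin$timestamp, lin$linear_pos, xout = st[ok],
                         rule = 2)$y
    if (length(pos) > 0) counts <- tabulate(bin_of(pos), nbins = nb)
  }

  rate_raw <- ifelse(occ > 0, counts / occ, NA_real_)
  rate <- gauss_smooth(rate_raw, params$smooth_sigma)
  p <- ifelse(occ > 0, occ / sum(occ), NA_real_)
  occupied <- occ > 0
  lambda <- sum(p[occupied] * rate[occupied])
  structure(list(trajectory = if (nrow(laps)) laps$trajectory[1] else NA_character_,
                 bin_centers = centers, occupancy = occ, counts = counts,
                 rate_raw = rate_raw, rate = rate, p = p,
                 mean_rate = lambda, params = params),
            class = "rate_curve")
}

#' Skaggs spatial information of a rate curve (bits/spike)
#'
#' \deqn{SI = \sum_i p_i \frac{x_i}{\lambda} \log_2 \frac{x_i}{\lambda}}
#' over occupied bins, where \eqn{p_i} is the occupancy probability,
#' \eqn{x_i} the bin rate and \eqn{\lambda = \sum_i p_i x_i} the
#' occupancy-weighted mean rate. Zero-rate bins contribute 0. For a silent
#' cell (\eqn{\lambda = 0}) the quantity is undefined and `NA` is returned.
#'
#' @param curve a `rate_curve`.
#' @param use_smoothed compute on the smoothed (default) or raw curve.
#' @return spatial information in bits/spike (non-negative), or `NA`.
#' @export
spatial_information <- function(curve, use_smoothed = TRUE) {
  x <- if (use_smoothed) curve$rate else curve$rate_raw
  p <- curve$p
  occ <- is.finite(p) & is.finite(x)
  x <- x[occ]; p <- p[occ] / sum(p[occ])
  lambda <- sum(p * x)
  if (!is.finite(lambda) || lambda <= 0) return(NA_real_)
  pos <- x > 0
  sum(p[pos] * (x[pos] / lambda) * log2(x[pos] / lambda))
}

#' Rate-curve stability across two running sessions
#'
#' Pearson correlation between a cell's rate curves on the same trajectory in
#' two sessions, over the bins occupied in both. Fewer than 3 common bins or
#' zero variance in either curve gives `NA`.
#'
#' @param curve1,curve2 `rate_curve` objects with identical binning.
#' @param use_smoothed use smoothed (default) or raw rates.
#' @return correlation in [-1, 1], or `NA`.
#' @export
stability <- function(curve1, curve2, use_smoothed = TRUE) {
  stopifnot(length(curve1$bin_centers) == length(curve2$bin_centers))
  a <- if (use_smoothed) curve1$rate else curve1$rate_raw
  b <- if (use_smoothed) curve2$rate else curve2$rate_raw
  common <- is.finite(a) & is.finite(b) & curve1$occupancy > 0 & curve2$occupancy > 0
  if (sum(common) < 3) return(NA_real_)
  a <- a[common]; b <- b[common]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Detect place fields on a smoothed rate curve
#'
#' Each local peak with rate at least `peak_min` seeds a field; its boundaries
#' extend outward to the last bin whose rate is at least `boundary_frac` of
#' that field's peak. Fields separated by a gap of at most `merge_gap` cm are
#' combined (iteratively, so chains of near peaks collapse); a merged field's
#' peak is the maximum over its members. Ties between equal-rate bins break
#' toward the leftmost bin.
#'
#' @param curve a `rate_curve` (smoothed rates are used).
#' @param peak_min minimal qualifying peak rate in Hz (default 1).
#' @param boundary_frac boundary threshold as a fraction of the field peak
#'   (default 0.10).
#' @param merge_gap maximal gap in cm for merging neighboring fields
#'   (default 6).
#' @return data.frame `start`, `end`, `length` (cm), `peak_rate` (Hz),
#'   `peak_pos` (cm), `trajectory`; zero rows if no field qualifies.
#' @export
detect_place_fields <- function(curve, peak_min = 1, boundary_frac = 0.10,
                                merge_gap = 6) {
  x <- curve$rate
  x[!is.finite(x)] <- 0
  nb <- length(x)
  bw <- curve$params$bin_size
  empty <- data.frame(start = numeric(), end = numeric(), length = numeric(),
                      peak_rate = numeric(), peak_pos = numeric(),
                      trajectory = character(), stringsAsFactors = FALSE)
  if (nb == 0 || max(x) < peak_min) return(empty)

  left <- c(-Inf, x[-nb]); right <- c(x[-1], -Inf)
  is_peak <- x >= peak_min & x > left & x >= right   # leftmost of a plateau
  peaks <- which(is_peak)
  if (length(peaks) == 0) return(empty)

  taken <- rep(FALSE, nb)
  fields <- list()
  for (pk in peaks[order(-x[peaks], peaks)]) {
    if (taken[pk]) next
    thr <- boundary_frac * x[pk]
    lo <- pk; while (lo > 1 && x[lo - 1] >= thr) lo <- lo - 1
    hi <- pk; while (hi < nb && x[hi + 1] >= thr) hi <- hi + 1
    taken[lo:hi] <- TRUE
    fields[[length(fields) + 1L]] <- c(lo = lo, hi = hi, pk = pk)
  }
  f <- do.call(rbind, fields)
  f <- f[order(f[, "lo"]), , drop = FALSE]

  repeat {
    if (nrow(f) < 2) break
    gaps <- (f[-1, "lo"] - 1 - f[-nrow(f), "hi"]) * bw
    j <- which(gaps <= merge_gap)
    if (length(j) == 0) break
    j <- j[1]
    f[j, "hi"] <- max(f[j, "hi"], f[j + 1, "hi"])
    f[j, "pk"] <- if (x[f[j, "pk"]] >= x[f[j + 1, "pk"]]) f[j, "pk"] else f[j + 1, "pk"]
    f <- f[-(j + 1), , drop = FALSE]
  }

  edges <- seq(0, nb * bw, by = bw)
  data.frame(start = edges[f[, "lo"]],
             end = edges[f[, "hi"] + 1],
             length = (f[, "hi"] - f[, "lo"] + 1) * bw,
             peak_rate = x[f[, "pk"]],
             peak_pos = curve$bin_centers[f[, "pk"]],
             trajectory = rep(curve$trajectory %||% NA_character_, nrow(f)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean firing rate of a spike train within lap intervals
#'
#' @param spike_times spike timestamps (s).
#' @param laps lap table; only its `start_time`/`end_time` columns are used.
#' @return spikes per second of total lap time, or `NA` if no lap time.
#' @export
trajectory_mean_rate <- function(spike_times, laps) {
  if (nrow(laps) == 0) return(NA_real_)
  total <- sum(laps$end_time - laps$start_time)
  n <- 0L
  for (j in seq_len(nrow(laps)))
    n <- n + sum(spike_times >= laps$start_time[j] & spike_times < laps$end_time[j])
  n / total
}

#' Classify units as putative pyramidal and run-active
#'
#' A unit is a putative pyramidal cell if its session-wide mean rate is at
#' most `pyramidal_max_rate` (interneurons fire faster); only pyramidal cells
#' are considered for the run-active label, which requires a mean rate above
#' `active_min_rate` on at least one trajectory in at least one running
#' session (strict `>`).
#'
#' @param session_rates data.frame `cell_id`, `mean_rate` (Hz over the full
#'   running-session duration; for multiple run sessions, the maximum of the
#'   per-session means is compared against the pyramidal threshold).
#' @param traj_rates data.frame `cell_id`, `mean_rate` with one row per cell,
#'   trajectory and running session (Hz within laps).
#' @param pyramidal_max_rate Hz, default 7 (inclusive).
#' @param active_min_rate Hz, default 0.5 (exclusive).
#' @return data.frame `cell_id`, `is_pyramidal`, `is_run_active`.
#' @export
classify_cells <- function(session_rates, traj_rates,
                           pyramidal_max_rate = 7, active_min_rate = 0.5) {
  pyr_rate <- tapply(session_rates$mean_rate, session_rates$cell_id, max)
  is_pyr <- pyr_rate <= pyramidal_max_rate
  active_ids <- unique(traj_rates$cell_id[
    !is.na(traj_rates$mean_rate) & traj_rates$mean_rate > active_min_rate])
  ids <- names(pyr_rate)
  data.frame(cell_id = ids,
             is_pyramidal = as.vector(is_pyr),
             is_run_active = as.vector(is_pyr) & ids %in% as.character(active_ids),
             stringsAsFactors = FALSE)
}
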