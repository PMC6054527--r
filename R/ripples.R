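#' Ripple detection parameters
#'
#' Thresholds are expressed as multiples of the standard deviation of the
#' ripple-band-filtered trace computed over the whole rest session, so
#' detection is invariant to the recording gain.
#'
#' @param band ripple band in Hz (default 100-250).
#' @param peak_thresh peak threshold in sd units (default 6).
#' @param boundary_thresh start/end threshold in sd units (default 2.5).
#' @param merge_gap events closer than this are combined, ms (default 30,
#'   strict `<`).
#' @param min_dur,max_dur accepted duration range, ms (default 30-500,
#'   inclusive).
#' @param freq_method `"troughs"` counts oscillation troughs of the filtered
#'   trace within the event; `"spectral"` takes the FFT peak of the filtered
#'   segment.
#' @return parameter list.
#' @export
ripple_detection_params <- function(band = c(100, 250), peak_thresh = 6,
                                    boundary_thresh = 2.5, merge_gap = 30,
                                    min_dur = 30, max_dur = 500,
                                    freq_method = c("troughs", "spectral")) {
  stopifnot(band[1] < band[2], boundary_thresh < peak_thresh,
            min_dur < max_dur, merge_gap >= 0)
  list(band = band, peak_thresh = peak_thresh,
       boundary_thresh = boundary_thresh, merge_gap = merge_gap,
       min_dur = min_dur, max_dur = max_dur,
       freq_method = match.arg(freq_method))
}

#' Detect sharp-wave ripples in rest-session LFP
#'
#' The trace is band-pass filtered (zero-phase 4th-order Butterworth) and the
#' sd of the filtered trace computed over the entire session. Candidate
#' events are excursions of the analytic-signal envelope above
#' `boundary_thresh` sd that reach `peak_thresh` sd somewhere inside;
#' neighbors separated by less than `merge_gap` ms are combined, then events
#' outside `[min_dur, max_dur]` ms are discarded. Per event the amplitude is
#' the absolute value of the most negative trough of the filtered trace
#' (same units as the input) and the frequency the intra-event oscillation
#' frequency.
#'
#' @param lfp an [lfp_trace()].
#' @param params [ripple_detection_params()].
#' @return data.frame `start`, `end` (s, half-open), `duration_ms`,
#'   `amplitude`, `freq_hz`, `peak_sd` (envelope max in sd units); sorted,
#'   disjoint. Attribute `sigma` carries the filtered-trace sd.
#' @export
detect_ripples <- function(lfp, params = ripple_detection_params()) {
  fs <- lfp$rate
  n <- length(lfp$samples)
  if (n / fs < 1) stop("LFP trace shorter than 1 s")
  start0 <- lfp$start_time %||% 0
  filt <- bandpass(lfp$samples, fs, params$band[1], params$band[2],
                   method = "butter")
  sigma <- stats::sd(filt)
  env <- Mod(analytic_signal(filt))

  above <- env >= params$boundary_thresh * sigma
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  if (nrow(seg) > 0) {
    peak_ok <- vapply(seq_len(nrow(seg)), function(j)
      max(env[seg[j, 1]:seg[j, 2]]) >= params$peak_thresh * sigma, logical(1))
    seg <- seg[peak_ok, , drop = FALSE]
  }

  empty <- data.frame(start = numeric(), end = numeric(),
                      duration_ms = numeric(), amplitude = numeric(),
                      freq_hz = numeric(), peak_sd = numeric())
  attr(empty, "sigma") <- sigma
  if (nrow(seg) == 0) return(empty)

  # merge neighbors with gaps below merge_gap
  gap_samp <- params$merge_gap / 1000 * fs
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) for (j in 2:nrow(seg)) {
    last <- nrow(merged)
    if (seg[j, 1] - merged[last, 2] < gap_samp) {
      merged[last, 2] <- seg[j, 2]
    } else merged <- rbind(merged, seg[j, ])
  }

  dur_ms <- (merged[, 2] - merged[, 1] + 1) / fs * 1000
  keep <- dur_ms >= params$min_dur & dur_ms <= params$max_dur
  merged <- merged[keep, , drop = FALSE]
  if (nrow(merged) == 0) return(empty)

  ev_freq <- function(i0, i1) {
    x <- filt[i0:i1]
    if (params$freq_method == "spectral") {
      m <- length(x)
      sp <- Mod(stats::fft(x))[seq_len(floor(m / 2))]
      fax <- (seq_len(floor(m / 2)) - 1) / m * fs
      inband <- fax >= params$band[1] & fax <= params$band[2]
      if (!any(inband)) return(NA_real_)
      fax[inband][which.max(sp[inband])]
    } else {
      tr <- which(diff(sign(diff(x))) > 0) + 1L
      if (length(tr) < 2) return(NA_real_)
      (length(tr) - 1) / ((tr[length(tr)] - tr[1]) / fs)
    }
  }

  out <- data.frame(
    start = start0 + (merged[, 1] - 1) / fs,
    end = start0 + merged[, 2] / fs,
    duration_ms = (merged[, 2] - merged[, 1] + 1) / fs * 1000,
    amplitude = vapply(seq_len(nrow(merged)), function(j)
      abs(min(filt[merged[j, 1]:merged[j, 2]])), numeric(1)),
    freq_hz = vapply(seq_len(nrow(merged)), function(j)
      ev_freq(merged[j, 1], merged[j, 2]), numeric(1)),
    peak_sd = vapply(seq_len(nrow(merged)), function(j)
      max(env[merged[j, 1]:merged[j, 2]]) / sigma, numeric(1)))
  attr(out, "sigma") <- sigma
  out
}

#' Per-session ripple summary
#'
#' @param events [detect_ripples()] output.
#' @param session_duration rest-session length in seconds.
#' @return one-row data.frame `n_events`, `rate_hz` (events per second),
#'   `mean_duration_ms`, `mean_amplitude`, `mean_freq_hz`; the means are `NA`
#'   when there are no events (the rate is 0).
#' @export
ripple_session_summary <- function(events, session_duration) {
  stopifnot(session_duration > 0)
  n <- nrow(events)
  data.frame(n_events = n,
             rate_hz = n / session_duration,
             mean_duration_ms = if (n) mean(events$duration_ms) else NA_real_,
             mean_amplitude = if (n) mean(events$amplitude) else NA_real_,
             mean_freq_hz = if (n) mean(events$freq_hz) else NA_real_)
}

#' Per-cell firing statistics within ripple events
#'
#' @param spike_times one unit's spike timestamps (s).
#' @param events [detect_ripples()] output with at least one event.
#' @return one-row data.frame `participation_rate` (fraction of events with
#'   at least one spike), `spikes_per_ripple` (mean count) and
#'   `in_ripple_rate` (total in-event spikes over total event time, Hz).
#' @export
ripple_firing_stats <- function(spike_times, events) {
  n_ev <- nrow(events)
  if (n_ev == 0)
    return(data.frame(participation_rate = NA_real_,
                      spikes_per_ripple = NA_real_,
                      in_ripple_rate = NA_real_))
  counts <- vapply(seq_len(n_ev), function(j)
    sum(spike_times >= events$start[j] & spike_times < events$end[j]),
    numeric(1))
  total_time <- sum(events$end - events$start)
  data.frame(participation_rate = mean(counts > 0),
             spikes_per_ripple = mean(counts),
             in_ripple_rate = sum(counts) / total_time)
}
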