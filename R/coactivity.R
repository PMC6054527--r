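#' Cross-correlogram parameters
#'
#' Defaults follow the within-ripple coactivity convention: ripple events
#' padded by 150 ms on each side, 20 ms lag bins spanning -230..230 ms
#' (centers -220..220, so the baseline lag windows are covered exactly),
#' 5-bin nearest-neighbor smoothing, baseline from lags in
#' [-220, -180] and [180, 220] ms, coactivity averaged over lags in
#' [-50, 50] ms.
#'
#' @param window_pad padding around each ripple event, ms.
#' @param bin_width lag bin width, ms.
#' @param smooth_bins nearest-neighbor smoothing span in bins (odd).
#' @param baseline_lags two-column matrix of baseline lag intervals, ms.
#' @param coactivity_lags lag interval averaged for the coactivity value, ms.
#' @param max_lag half-range of the correlogram, ms.
#' @param norm `"per_bin"` rescales by the square root of the expected
#'   per-bin coincidence count of two Poisson trains with the same in-window
#'   counts, `sqrt(n_a n_b Delta / T)`; `"total"` uses the expectation summed
#'   over all lag bins.
#' @return parameter list.
#' @export
correlogram_params <- function(window_pad = 150, bin_width = 20,
                               smooth_bins = 5,
                               baseline_lags = rbind(c(-220, -180), c(180, 220)),
                               coactivity_lags = c(-50, 50),
                               max_lag = 230,
                               norm = c("per_bin", "total")) {
  stopifnot(bin_width > 0, smooth_bins %% 2 == 1,
            coactivity_lags[2] <= max_lag,
            all(abs(baseline_lags) <= max_lag))
  list(window_pad = window_pad, bin_width = bin_width,
       smooth_bins = smooth_bins, baseline_lags = baseline_lags,
       coactivity_lags = coactivity_lags, max_lag = max_lag,
       norm = match.arg(norm))
}

#' Padded ripple windows
#'
#' Pads each event by `pad` ms before its start and after its end and merges
#' overlapping (or touching) padded intervals. The total window time T is the
#' sum of merged interval lengths.
#'
#' @param events [detect_ripples()] output (sorted).
#' @param pad padding in ms (default 150).
#' @return data.frame `start`, `end` (s) with attribute `T` (total time, s).
#' @export
ripple_windows <- function(events, pad = 150) {
  if (nrow(events) == 0) {
    out <- data.frame(start = numeric(), end = numeric())
    attr(out, "T") <- 0
    return(out)
  }
  s <- events$start - pad / 1000
  e <- events$end + pad / 1000
  o <- order(s); s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]; outs <- c(); oute <- c()
  for (j in seq_along(s)[-1]) {
    if (s[j] <= me) me <- max(me, e[j]) else {
      outs <- c(outs, ms); oute <- c(oute, me); ms <- s[j]; me <- e[j]
    }
  }
  outs <- c(outs, ms); oute <- c(oute, me)
  out <- data.frame(start = outs, end = oute)
  attr(out, "T") <- sum(oute - outs)
  out
}

# spikes falling in any window, mapped to window-concatenated time (the
# inter-window gaps are removed, so the retained point process is stationary
# under a Poisson null and the per-bin expectation n_a n_b Delta / T holds at
# every lag)
window_spikes <- function(spike_times, windows) {
  if (nrow(windows) == 0 || length(spike_times) == 0)
    return(numeric(0))
  offsets <- cumsum(c(0, (windows$end - windows$start)[-nrow(windows)]))
  idx <- findInterval(spike_times, windows$start)
  inside <- idx >= 1 & spike_times < windows$end[pmax(idx, 1)]
  idx <- idx[inside]
  offsets[idx] + (spike_times[inside] - windows$start[idx])
}

#' Normalized pairwise cross-correlogram within ripple windows
#'
#' Counts spike-time differences `t_b - t_a` between the two trains, with
#' both spikes inside the same padded ripple window, in `bin_width` ms lag
#' bins. The raw counts are smoothed by nearest-neighbor averaging over
#' `smooth_bins` bins (shrinking at the edges, so baseline lags are not
#' biased by zero padding), the mean smoothed value over the baseline lags is
#' subtracted, and the result is rescaled by the square root of the number of
#' coincidences expected per bin from two independent Poisson trains with the
#' same in-window spike counts — `sqrt(n_a n_b Delta / T)` — which renders
#' the correlogram insensitive to the pair's firing rates.
#'
#' @param a_times,b_times the two units' spike timestamps (s).
#' @param windows [ripple_windows()] output.
#' @param params [correlogram_params()].
#' @return object of class `correlogram`: list `lag_centers` (ms), `raw`,
#'   `smoothed`, `baseline`, `normalized`, `n_a`, `n_b`, `T` (s); `NULL` if
#'   either train has no in-window spikes or T is 0.
#' @export
cross_correlogram <- function(a_times, b_times, windows,
                              params = correlogram_params()) {
  Ttot <- attr(windows, "T")
  sa <- window_spikes(a_times, windows)
  sb <- window_spikes(b_times, windows)
  if (is.null(Ttot) || Ttot <= 0 || length(sa) == 0 || length(sb) == 0)
    return(NULL)

  bw <- params$bin_width
  edges <- seq(-params$max_lag, params$max_lag, by = bw)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  nb <- length(centers)

  # spike-time differences t_b - t_a on the concatenated timeline, capped at
  # the correlogram range; two-pointer sweep avoids the full outer product
  raw <- numeric(nb)
  lim <- params$max_lag / 1000
  lo <- 1L
  for (i in seq_along(sa)) {
    while (lo <= length(sb) && sb[lo] < sa[i] - lim) lo <- lo + 1L
    j <- lo
    while (j <= length(sb) && sb[j] < sa[i] + lim) {
      d <- (sb[j] - sa[i]) * 1000
      if (d >= edges[1] && d < edges[length(edges)]) {
        k <- findInterval(d, edges)
        raw[k] <- raw[k] + 1
      }
      j <- j + 1L
    }
  }

  half <- (params$smooth_bins - 1L) / 2L
  smoothed <- vapply(seq_len(nb), function(i)
    mean(raw[max(1, i - half):min(nb, i + half)]), numeric(1))

  in_any <- function(x, intervals) {
    hit <- rep(FALSE, length(x))
    for (r in seq_len(nrow(intervals)))
      hit <- hit | (x >= intervals[r, 1] & x <= intervals[r, 2])
    hit
  }
  bl <- in_any(centers, params$baseline_lags)
  baseline <- mean(smoothed[bl])

  expected_per_bin <- length(sa) * length(sb) * (bw / 1000) / Ttot
  denom <- if (params$norm == "per_bin") sqrt(expected_per_bin)
           else sqrt(expected_per_bin * nb)
  structure(list(lag_centers = centers, raw = raw, smoothed = smoothed,
                 baseline = baseline,
                 normalized = (smoothed - baseline) / denom,
                 n_a = length(sa), n_b = length(sb), T = Ttot, params = params),
            class = "correlogram")
}

#' Coactivity of a cell pair
#'
#' The mean of the normalized cross-correlogram over lag bins whose centers
#' lie within the coactivity window (default [-50, 50] ms).
#'
#' @param cg a `correlogram` (or `NULL` for a missing pair).
#' @return a single number, `NA` for a missing correlogram.
#' @export
coactivity <- function(cg) {
  if (is.null(cg)) return(NA_real_)
  w <- cg$params$coactivity_lags
  sel <- cg$lag_centers >= w[1] & cg$lag_centers <= w[2]
  mean(cg$normalized[sel])
}

#' Coactivity for every unordered pair of units
#'
#' Pairs are ordered by sorted cell id; the lag sign convention is
#' `t_b - t_a` with `cell_a < cell_b`, though the coactivity value itself is
#' symmetric in the two cells.
#'
#' @param trains named list of spike-time vectors (names are cell ids).
#' @param windows [ripple_windows()] output.
#' @param params [correlogram_params()].
#' @param cell_ids optional subset of names to restrict the pairing to (e.g.
#'   run-active cells).
#' @return data.frame `cell_a`, `cell_b`, `n_a`, `n_b`, `coactivity` (one row
#'   per unordered pair; `NA` where either train is silent in the windows).
#' @export
pairwise_coactivity <- function(trains, windows, params = correlogram_params(),
                                cell_ids = NULL) {
  ids <- sort(if (is.null(cell_ids)) names(trains) else
    intersect(cell_ids, names(trains)))
  if (length(ids) < 2)
    return(data.frame(cell_a = character(), cell_b = character(),
                      n_a = numeric(), n_b = numeric(),
                      coactivity = numeric(), stringsAsFactors = FALSE))
  pairs <- utils::combn(ids, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    cg <- cross_correlogram(trains[[a]], trains[[b]], windows, params)
    data.frame(cell_a = a, cell_b = b,
               n_a = if (is.null(cg)) 0 else cg$n_a,
               n_b = if (is.null(cg)) 0 else cg$n_b,
               coactivity = coactivity(cg), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
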