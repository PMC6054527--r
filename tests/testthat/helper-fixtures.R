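# shared fixture builders; everything is generated in code at test time

# position data.frame for constant-speed back-and-forth running
triangle_position <- function(n_cycles = 5, L = 200, v = 20, rate = 33) {
  dur <- n_cycles * 2 * L / v
  t <- seq(0, dur, by = 1 / rate)
  tau <- t %% (2 * L / v)
  data.frame(timestamp = t, x = ifelse(tau < L / v, v * tau, 2 * L - v * tau),
             y = 0)
}

# linearized series straight from x positions (valid everywhere)
lin_from_x <- function(x, rate = 33, L = 200) {
  lin <- data.frame(timestamp = seq_along(x) / rate, linear_pos = x,
                    trajectory = "AtoB", valid = TRUE,
                    stringsAsFactors = FALSE)
  attr(lin, "track_length") <- L
  lin
}

# a rate_curve built directly from occupancy seconds and rates (no smoothing)
make_curve <- function(occupancy, rate, bin_size = 2) {
  nb <- length(occupancy)
  structure(list(trajectory = "AtoB",
                 bin_centers = bin_size * (seq_len(nb) - 0.5),
                 occupancy = occupancy,
                 counts = rate * occupancy,
                 rate_raw = ifelse(occupancy > 0, rate, NA_real_),
                 rate = ifelse(occupancy > 0, rate, NA_real_),
                 p = ifelse(occupancy > 0, occupancy / sum(occupancy), NA_real_),
                 mean_rate = sum((occupancy / sum(occupancy))[occupancy > 0] *
                                   rate[occupancy > 0]),
                 params = binning_params(bin_size = bin_size, smooth_sigma = 0)),
            class = "rate_curve")
}

# fixed windows for correlogram tests, with total time attribute
fixed_windows <- function(n = 200, length_s = 0.4, gap_s = 2) {
  out <- data.frame(start = seq(0, by = gap_s, length.out = n))
  out$end <- out$start + length_s
  attr(out, "T") <- n * length_s
  out
}
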