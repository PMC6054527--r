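#' Linear-track geometry
#'
#' The track is analyzed as a 1-D path between two reward ends A and B; the
#' two running directions are always treated as separate trajectories
#' (`"AtoB"`, `"BtoA"`). A rectangular or curved track is assumed to have been
#' unwrapped into this 1-D parameterization beforehand; here the path is the
#' segment from (0, 0) to (track_length, 0) in cm.
#'
#' @param track_length track length in cm.
#' @param max_off_path maximal allowed perpendicular distance (cm) of a
#'   position sample from the path; samples farther are masked invalid.
#' @return a `track_geometry` list.
#' @export
track_geometry <- function(track_length = 200, max_off_path = 10) {
  stopifnot(track_length > 0, max_off_path > 0)
  structure(list(track_length = track_length, max_off_path = max_off_path),
            class = "track_geometry")
}

#' Project position samples onto the track and assign running direction
#'
#' Each (x, y) sample is projected to the nearest point of the track path;
#' its coordinate along the path (cm from end A) is the linearized position.
#' The direction of travel, from the sign of the smoothed derivative of the
#' linearized position, assigns each sample to trajectory A->B or B->A;
#' samples with no net movement inherit the last determined direction.
#'
#' @param position data.frame with columns `timestamp` (s, strictly
#'   increasing), `x`, `y` (cm).
#' @param geometry a [track_geometry()].
#' @return data.frame `timestamp`, `linear_pos`, `trajectory`, `valid`.
#'   `valid` is FALSE for samples farther than `max_off_path` from the path;
#'   the count of such samples is attached as attribute `n_off_path`.
#' @export
linearize <- function(position, geometry) {
  stopifnot(all(c("timestamp", "x", "y") %in% names(position)))
  if (is.unsorted(position$timestamp, strictly = TRUE))
    stop("position timestamps must be strictly increasing")
  L <- geometry$track_length
  lin <- pmin(pmax(position$x, 0), L)
  off <- sqrt((position$x - lin)^2 + position$y^2)
  valid <- off <= geometry$max_off_path

  # direction from a lightly smoothed derivative; zero-runs take the last
  # known direction (locf), leading zeros the first known one
  dt <- diff(position$timestamp)
  v <- c(0, diff(gauss_smooth(lin, 2)) / ifelse(dt > 0, dt, NA))
  dir <- sign(v)
  dir[abs(v) < 1e-9] <- 0
  if (all(dir == 0)) {
    traj <- rep("AtoB", length(lin))
  } else {
    idx <- which(dir != 0)
    filled <- dir[idx][cumsum(seq_along(dir) %in% idx)]
    filled <- c(rep(dir[idx[1]], idx[1] - 1), filled)[seq_along(dir)]
    traj <- ifelse(filled > 0, "AtoB", "BtoA")
  }
  out <- data.frame(timestamp = position$timestamp, linear_pos = lin,
                    trajectory = traj, valid = valid,
                    stringsAsFactors = FALSE)
  attr(out, "track_length") <- L
  attr(out, "n_off_path") <- sum(!valid)
  out
}

#' Segment a linearized series into laps
#'
#' A lap is a continuous excursion that starts inside one end zone and ends
#' inside the opposite end zone without re-entering the zone of origin;
#' partial excursions (turn-arounds) are discarded. Lap intervals are
#' half-open `[start, end)`.
#'
#' @param lin a linearized series from [linearize()].
#' @param end_zone width of each end zone in cm (default 10).
#' @return data.frame `trajectory`, `start_time`, `end_time`; zero rows if no
#'   complete lap occurred.
#' @export
segment_laps <- function(lin, end_zone = 10) {
  L <- attr(lin, "track_length")
  stopifnot(!is.null(L), end_zone < L / 2)
  zone <- ifelse(lin$linear_pos <= end_zone, "A",
                 ifelse(lin$linear_pos >= L - end_zone, "B", "mid"))
  t <- lin$timestamp
  laps <- list()
  origin <- NA_character_
  t_leave <- NA_real_
  for (i in seq_along(zone)) {
    z <- zone[i]
    if (z == "mid") {
      next
    }
    if (!is.na(origin) && z != origin && !is.na(t_leave)) {
      laps[[length(laps) + 1L]] <- data.frame(
        trajectory = if (origin == "A") "AtoB" else "BtoA",
        start_time = t_leave, end_time = t[i], stringsAsFactors = FALSE)
    }
    # dwelling in a zone keeps pushing the prospective lap start forward, so
    # start_time ends up being the last sample inside the origin zone
    origin <- z
    t_leave <- t[i]
  }
  if (length(laps) == 0)
    return(data.frame(trajectory = character(), start_time = numeric(),
                      end_time = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, laps)
}

#' Running speed from position samples
#'
#' Positions are smoothed with a boxcar of `smooth_window` seconds (to
#' suppress 33 Hz tracking jitter) and differentiated with a centered finite
#' difference; the result keeps the input timestamps.
#'
#' @param position data.frame `timestamp`, `x`, `y`.
#' @param smooth_window boxcar length in seconds (default 0.25).
#' @return numeric vector of speeds (cm/s), same length as the input.
#' @export
compute_speed <- function(position, smooth_window = 0.25) {
  n <- nrow(position)
  stopifnot(n >= 2)
  t <- position$timestamp
  dt_med <- stats::median(diff(t))
  w <- max(1L, round(smooth_window / dt_med))
  if (w %% 2 == 0) w <- w + 1L
  box <- function(v) as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
  xs <- box(position$x); ys <- box(position$y)
  # filter() leaves NA at the edges; fall back to raw samples there
  xs[is.na(xs)] <- position$x[is.na(xs)]
  ys[is.na(ys)] <- position$y[is.na(ys)]
  ip <- pmin(n, seq_len(n) + 1L); im <- pmax(1L, seq_len(n) - 1L)
  sqrt((xs[ip] - xs[im])^2 + (ys[ip] - ys[im])^2) / (t[ip] - t[im])
}

#' Motion-filter parameters
#'
#' @param stop_speed_thresh speed below which the animal counts as stopped
#'   (cm/s; strict `<`).
#' @param stop_min_duration minimal stop duration to exclude (s; strict `>`).
#' @param reward_exclusion_radius half-width of the excluded zone around each
#'   reward site (cm).
#' @param speed_smooth_window boxcar used by [compute_speed()] (s).
#' @return a parameter list.
#' @export
motion_filter_params <- function(stop_speed_thresh = 3, stop_min_duration = 1,
                                 reward_exclusion_radius = 4,
                                 speed_smooth_window = 0.25) {
  stopifnot(stop_speed_thresh > 0, stop_min_duration > 0,
            reward_exclusion_radius > 0, speed_smooth_window > 0)
  list(stop_speed_thresh = stop_speed_thresh,
       stop_min_duration = stop_min_duration,
       reward_exclusion_radius = reward_exclusion_radius,
       speed_smooth_window = speed_smooth_window)
}

#' Mask stopped periods and reward sites
#'
#' Samples inside maximal runs of speed below `stop_speed_thresh` lasting
#' strictly longer than `stop_min_duration` are masked, as are samples within
#' `reward_exclusion_radius` of a reward site. Existing invalid samples stay
#' invalid; the operation is idempotent.
#'
#' @param lin linearized series ([linearize()]).
#' @param speed speed vector aligned with `lin` ([compute_speed()]).
#' @param params a [motion_filter_params()] list.
#' @param reward_positions linear positions (cm) of reward sites; default the
#'   two track ends.
#' @return `lin` with its `valid` column updated.
#' @export
motion_filter <- function(lin, speed, params = motion_filter_params(),
                          reward_positions = NULL) {
  stopifnot(length(speed) == nrow(lin))
  L <- attr(lin, "track_length")
  if (is.null(reward_positions)) reward_positions <- c(0, L)
  mask <- lin$valid

  slow <- speed < params$stop_speed_thresh
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    dur <- lin$timestamp[ends[j]] - lin$timestamp[starts[j]]
    if (dur > params$stop_min_duration) mask[starts[j]:ends[j]] <- FALSE
  }
  for (rp in reward_positions)
    mask[abs(lin$linear_pos - rp) <= params$reward_exclusion_radius] <- FALSE

  lin$valid <- mask
  lin
}
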