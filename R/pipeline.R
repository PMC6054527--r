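#' Analyze one track-running session
#'
#' Runs the behavioral chain (linearization, speed, motion filtering, lap
#' segmentation) and the place-coding chain (per-trajectory rate curves,
#' spatial information, place fields, classification) for every unit.
#'
#' @param position data.frame `timestamp`, `x`, `y`.
#' @param spikes named list of spike-time vectors.
#' @param track_length cm.
#' @param binning [binning_params()].
#' @param motion [motion_filter_params()].
#' @return list `laps`, `cells` (per cell/trajectory table with session and
#'   trajectory rates, SI, field count), `fields`, `classes`
#'   ([classify_cells()] output), `curves` (nested list cell -> trajectory).
#' @export
analyze_run_session <- function(position, spikes, track_length = 200,
                                binning = binning_params(),
                                motion = motion_filter_params()) {
  geom <- track_geometry(track_length)
  lin <- linearize(position, geom)
  speed <- compute_speed(position, motion$speed_smooth_window)
  lin <- motion_filter(lin, speed, motion)
  laps <- segment_laps(lin)
  session_dur <- diff(range(position$timestamp))

  trajs <- unique(laps$trajectory)
  rows <- list(); fields <- list(); curves <- list()
  for (id in names(spikes)) {
    st <- spikes[[id]]
    sess_rate <- length(st) / session_dur
    curves[[id]] <- list()
    for (tr in trajs) {
      lp <- laps[laps$trajectory == tr, , drop = FALSE]
      cv <- compute_rate_curve(st, lin, lp, binning)
      curves[[id]][[tr]] <- cv
      fl <- detect_place_fields(cv)
      if (nrow(fl) > 0) {
        fl$cell_id <- id
        fields[[length(fields) + 1L]] <- fl
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = id, trajectory = tr,
        session_rate = sess_rate,
        traj_rate = trajectory_mean_rate(st, lp),
        si = spatial_information(cv),
        mean_rate = cv$mean_rate,
        n_fields = nrow(fl), stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, rows)
  classes <- classify_cells(
    data.frame(cell_id = names(spikes),
               mean_rate = vapply(spikes, length, numeric(1)) / session_dur),
    data.frame(cell_id = cells$cell_id, mean_rate = cells$traj_rate))
  list(laps = laps, cells = cells,
       fields = if (length(fields)) do.call(rbind, fields) else NULL,
       classes = classes, curves = curves)
}

#' Analyze one rest session
#'
#' Detects ripples, summarizes them, computes per-cell in-ripple firing
#' statistics and the pairwise coactivity of the requested cells within
#' padded ripple windows.
#'
#' @param lfp [lfp_trace()] (or `NULL`, in which case the stage is skipped
#'   with a warning and `NULL` is returned).
#' @param spikes named list of spike-time vectors.
#' @param cell_ids cells eligible for pairing (default: all).
#' @param rparams [ripple_detection_params()].
#' @param cparams [correlogram_params()].
#' @return list `events`, `summary`, `firing`, `coactivity`, or `NULL`.
#' @export
analyze_rest_session <- function(lfp, spikes, cell_ids = names(spikes),
                                 rparams = ripple_detection_params(),
                                 cparams = correlogram_params()) {
  if (is.null(lfp)) {
    warning("rest session has no LFP; ripple stage skipped")
    return(NULL)
  }
  events <- detect_ripples(lfp, rparams)
  dur <- length(lfp$samples) / lfp$rate
  summary <- ripple_session_summary(events, dur)
  firing <- do.call(rbind, lapply(names(spikes), function(id)
    cbind(cell_id = id, ripple_firing_stats(spikes[[id]], events))))
  windows <- ripple_windows(events, cparams$window_pad)
  coact <- pairwise_coactivity(spikes, windows, cparams, cell_ids = cell_ids)
  list(events = events, summary = summary, firing = firing,
       coactivity = coact)
}

#' Run the full pipeline over a cohort directory
#'
#' Expects the layout of [write_cohort()]: one subdirectory per animal with
#' `pre_run/`, `run1/` and `post_run/` sessions. Emits per-cell, per-field,
#' per-session-ripple and per-pair coactivity tables as CSV under `out_dir`,
#' plus `params.yaml` echoing every analysis parameter. Pairing for
#' coactivity is restricted to run-active cells present in all three
#' sessions. A rest session without LFP is skipped with a warning; track
#' stages still run. Any stage failure aborts naming the stage and session.
#'
#' @param cohort_dir input cohort directory.
#' @param out_dir output directory for the report tables.
#' @param track_length cm.
#' @param binning,motion,rparams,cparams analysis parameter lists.
#' @return invisibly, the list of output file paths.
#' @export
run_pipeline <- function(cohort_dir, out_dir, track_length = 200,
                         binning = binning_params(),
                         motion = motion_filter_params(),
                         rparams = ripple_detection_params(),
                         cparams = correlogram_params()) {
  animals <- list.dirs(cohort_dir, recursive = FALSE)
  if (length(animals) == 0) stop("no animal directories in ", cohort_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cells <- list(); fields <- list(); rsum <- list(); coact <- list()

  for (ad in animals) {
    animal <- basename(ad)
    stage <- function(name, expr) {
      tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed for %s: %s", name, animal,
                     conditionMessage(e)), call. = FALSE))
    }
    run1 <- stage("load run1", load_session(file.path(ad, "run1")))
    ra <- stage("place coding", analyze_run_session(
      run1$position, run1$spikes, track_length, binning, motion))
    ra$cells$animal_id <- animal
    cells[[animal]] <- merge(ra$cells, ra$classes, by = "cell_id")
    if (!is.null(ra$fields)) {
      ra$fields$animal_id <- animal
      fields[[animal]] <- ra$fields
    }
    active <- ra$classes$cell_id[ra$classes$is_run_active]

    for (kind in c("pre_run", "post_run")) {
      sdir <- file.path(ad, kind)
      if (!dir.exists(sdir)) next
      rest <- stage(paste("load", kind), load_session(sdir))
      eligible <- Reduce(intersect, list(active, names(rest$spikes),
                                         names(run1$spikes)))
      res <- stage(paste("ripples", kind), analyze_rest_session(
        rest$lfp, rest$spikes, cell_ids = eligible, rparams = rparams,
        cparams = cparams))
      if (is.null(res)) next
      res$summary$animal_id <- animal
      res$summary$session_kind <- kind
      rsum[[paste(animal, kind)]] <- res$summary
      if (nrow(res$coactivity) > 0) {
        res$coactivity$animal_id <- animal
        res$coactivity$session_kind <- kind
        coact[[paste(animal, kind)]] <- res$coactivity
      }
    }
  }

  paths <- c(cells = file.path(out_dir, "cells.csv"),
             fields = file.path(out_dir, "fields.csv"),
             ripples = file.path(out_dir, "ripple_summary.csv"),
             coactivity = file.path(out_dir, "coactivity.csv"),
             params = file.path(out_dir, "params.yaml"))
  data.table::fwrite(data.table::rbindlist(cells), paths["cells"])
  if (length(fields))
    data.table::fwrite(data.table::rbindlist(fields), paths["fields"])
  if (length(rsum))
    data.table::fwrite(data.table::rbindlist(rsum), paths["ripples"])
  if (length(coact))
    data.table::fwrite(data.table::rbindlist(coact), paths["coactivity"])
  yaml::write_yaml(list(track_length = track_length, binning = binning,
                        motion = motion, ripple_detection = rparams,
                        correlogram = cparams[setdiff(names(cparams), "baseline_lags")],
                        baseline_lags = as.vector(t(cparams$baseline_lags))),
                   paths["params"])
  invisible(paths)
}
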