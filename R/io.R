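#' LFP trace container
#'
#' A uniformly sampled voltage series; timestamps are implicit
#' (`start_time + (i - 1) / rate`).
#'
#' @param samples numeric vector (microvolts).
#' @param rate sampling rate, Hz (default 2000).
#' @param start_time time of the first sample, s.
#' @return an `lfp_trace` list.
#' @export
lfp_trace <- function(samples, rate = 2000, start_time = 0) {
  stopifnot(rate > 0, is.numeric(samples), all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), rate = rate,
                 start_time = start_time), class = "lfp_trace")
}

#' Write one session to a directory
#'
#' Layout: `position.csv` (timestamp, x, y; absent for rest sessions),
#' `spikes.csv` (cell_id, timestamp; one row per spike, sorted within cell),
#' `lfp.feather` (Arrow feather with the sample vector) and `session.yaml`
#' (kind, rates, start time). CSVs carry a header row; all timestamps are
#' seconds from session start, coordinates cm.
#'
#' @param session a session object from [generate_track_session()] or
#'   [generate_rest_session()] (fields `position` optional, `spikes`, `lfp`).
#' @param dir target directory (created).
#' @param kind one of `"pre_run"`, `"run1"`, `"post_run"`, `"run2"`.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, kind) {
  kind <- match.arg(kind, c("pre_run", "run1", "post_run", "run2"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(session$position))
    data.table::fwrite(session$position, file.path(dir, "position.csv"))
  sp <- data.table::rbindlist(lapply(names(session$spikes), function(id)
    data.table::data.table(cell_id = id, timestamp = session$spikes[[id]])))
  if (nrow(sp) == 0)
    sp <- data.table::data.table(cell_id = character(), timestamp = numeric())
  data.table::fwrite(sp, file.path(dir, "spikes.csv"))
  if (!is.null(session$lfp)) {
    arrow::write_feather(data.frame(sample = session$lfp$samples),
                         file.path(dir, "lfp.feather"))
  }
  yaml::write_yaml(list(kind = kind,
                        lfp_rate = if (is.null(session$lfp)) NULL else session$lfp$rate,
                        lfp_start = if (is.null(session$lfp)) NULL else session$lfp$start_time),
                   file.path(dir, "session.yaml"))
  invisible(dir)
}

#' Load one session from a directory
#'
#' Validates the layout written by [write_session()]: spike timestamps must
#' be sorted within each cell (the offending row is named otherwise) and
#' position timestamps strictly increasing. An empty spike file yields a
#' bundle with zero units, not an error; a missing LFP yields `lfp = NULL`.
#'
#' @param dir session directory.
#' @return list `kind`, `position` (or `NULL`), `spikes` (named list),
#'   `lfp` (or `NULL`).
#' @export
load_session <- function(dir) {
  yml <- file.path(dir, "session.yaml")
  if (!file.exists(yml)) stop("missing session.yaml in ", dir)
  meta <- yaml::read_yaml(yml)

  spf <- file.path(dir, "spikes.csv")
  if (!file.exists(spf)) stop("missing spikes.csv in ", dir)
  sp <- data.table::fread(spf)
  spikes <- list()
  if (nrow(sp) > 0) {
    bad <- sp[, .I[c(FALSE, diff(timestamp) < 0)], by = cell_id]$V1
    if (length(bad) > 0)
      stop("spikes.csv row ", bad[1] + 1L,
           ": timestamps out of order within cell")
    spikes <- split(sp$timestamp, sp$cell_id)
  }

  position <- NULL
  pf <- file.path(dir, "position.csv")
  if (file.exists(pf)) {
    position <- as.data.frame(data.table::fread(pf))
    if (is.unsorted(position$timestamp, strictly = TRUE))
      stop("position.csv timestamps are not strictly increasing")
  }

  lfp <- NULL
  lf <- file.path(dir, "lfp.feather")
  if (file.exists(lf) && !is.null(meta$lfp_rate)) {
    lfp <- lfp_trace(arrow::read_feather(lf)$sample, rate = meta$lfp_rate,
                     start_time = meta$lfp_start %||% 0)
  }
  list(kind = meta$kind, position = position, spikes = spikes, lfp = lfp)
}

#' Write a synthetic cohort to disk
#'
#' One subdirectory per animal, containing `pre_run/`, `run1/` and
#' `post_run/` session directories.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir target directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  for (an in cohort) {
    base <- file.path(dir, an$animal_id)
    write_session(an$pre_run, file.path(base, "pre_run"), "pre_run")
    write_session(an$run1, file.path(base, "run1"), "run1")
    write_session(an$post_run, file.path(base, "post_run"), "post_run")
  }
  invisible(dir)
}

#' Per-animal pyramidal and run-active cell counts
#'
#' The published per-animal counts of putative pyramidal and run-active
#' cells on the novel and familiar track (WT and mutant animals). `NA`
#' marks animals without a usable recording for that track.
#'
#' @return data.frame `genotype`, `novel_pyramidal`, `novel_active`,
#'   `familiar_pyramidal`, `familiar_active`.
#' @export
cell_count_table <- function() {
  path <- system.file("extdata", "cell_counts.tsv", package = "placeripple")
  as.data.frame(data.table::fread(path))
}
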