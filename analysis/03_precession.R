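#!/usr/bin/env Rscript
# Step 3: theta phase precession within detected place fields.
#
# For each cell's largest place field on each trajectory of Run 1, pool all
# in-field spikes across laps, assign theta phases from the session LFP
# (6-10 Hz, trough = 0 degrees) and fit both the optimal linear regression
# (phases rotated through 360 shifts, best |r|) and the bounded
# circular-linear regression.

library(placeripple)

dir.create("results", showWarnings = FALSE)
rows <- list()
for (geno in c("WT", "RTT")) {
  for (ad in list.dirs(file.path("scratch/cohorts", geno), recursive = FALSE)) {
    s <- load_session(file.path(ad, "run1"))
    lin <- linearize(s$position, track_geometry(200))
    laps <- segment_laps(lin)
    ra <- analyze_run_session(s$position, s$spikes)
    for (id in names(s$spikes)) {
      st <- s$spikes[[id]]
      pos <- approx(lin$timestamp, lin$linear_pos, xout = st)$y
      for (tr in unique(laps$trajectory)) {
        fl <- ra$fields
        fl <- fl[!is.null(fl) & fl$cell_id == id & fl$trajectory == tr, ]
        if (is.null(fl) || nrow(fl) == 0) next
        fl <- fl[which.max(fl$peak_rate), ]
        lp <- laps[laps$trajectory == tr, ]
        inlap <- rep(FALSE, length(st))
        for (j in seq_len(nrow(lp)))
          inlap <- inlap | (st >= lp$start_time[j] & st < lp$end_time[j])
        fit <- fit_field_precession(st[inlap], pos[inlap], fl, s$lfp,
                                    direction = tr)
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = geno, animal_id = basename(ad), cell_id = id,
          trajectory = tr, n_spikes = fit$n_spikes,
          linear_slope = fit$linear$slope, linear_r = fit$linear$r,
          cl_slope = fit$circular$slope, cl_rho = fit$circular$rho)
      }
    }
  }
}
prec <- do.call(rbind, rows)
write.csv(prec, "results/precession.csv", row.names = FALSE)

ok <- is.finite(prec$linear_slope)
cat(sprintf("fitted %d fields; linear slope median %.2f deg/cm, |r| median %.2f\n",
            sum(ok), median(prec$linear_slope[ok]),
            median(abs(prec$linear_r[ok]))))
cat(sprintf("circular-linear slope median %.4f cycles/cm, rho median %.2f\n",
            median(prec$cl_slope[ok]), median(prec$cl_rho[ok], na.rm = TRUE)))
cat("wrote results/precession.csv\n")
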