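#!/usr/bin/env Rscript
# Step 2: place-coding analysis of the Run 1 track sessions.
#
# For every animal and cell: linearize positions, mask stops and reward
# sites, segment laps, build per-trajectory rate curves (2 cm bins, Gaussian
# sigma 2 bins), and report spatial information, place-field counts and the
# pyramidal / run-active classification. One row per cell and trajectory.

library(placeripple)

dir.create("results", showWarnings = FALSE)
rows <- list()
for (geno in c("WT", "RTT")) {
  for (ad in list.dirs(file.path("scratch/cohorts", geno), recursive = FALSE)) {
    s <- load_session(file.path(ad, "run1"))
    ra <- analyze_run_session(s$position, s$spikes)
    tab <- merge(ra$cells, ra$classes, by = "cell_id")
    tab$genotype <- geno
    tab$animal_id <- basename(ad)
    rows[[paste(geno, ad)]] <- tab
  }
}
cells <- do.call(rbind, rows)
write.csv(cells, "results/place_cells.csv", row.names = FALSE)

active <- cells[cells$is_run_active, ]
for (geno in c("WT", "RTT")) {
  g <- active[active$genotype == geno, ]
  s <- summarize_group(g$si, geno)
  cat(sprintf("%s: %d cell-trajectories, SI median %.2f [%.2f %.2f] bits/spike\n",
              geno, s$n, s$median, s$q25, s$q75))
}
cat("ranksum p (SI, WT vs RTT):",
    signif(ranksum_compare(active$si[active$genotype == "WT"],
                           active$si[active$genotype == "RTT"]), 3), "\n")
cat("wrote results/place_cells.csv\n")
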