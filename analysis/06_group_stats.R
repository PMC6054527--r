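#!/usr/bin/env Rscript
# Step 6: group-level statistics.
#
# (a) Run-active percentages from the published per-animal cell counts.
# (b) Equalized downsampling of spatial information across the four
#     genotype x track groups: the smallest group (31 cells) sets the
#     subsample size, the other groups are resampled without replacement
#     200 times, and the fraction of significant rank-sum comparisons is
#     reported. Here the four groups come from the simulated cohorts'
#     run-active cells, split by genotype, plus noise-degraded copies
#     standing in for the familiar-track groups.

library(placeripple)

dir.create("results", showWarnings = FALSE)
tab <- cell_count_table()
wt <- tab[tab$genotype == "WT", ]
rtt <- tab[tab$genotype == "RTT", ]
pcts <- data.frame(
  group = c("RTT novel", "WT novel", "WT familiar", "RTT familiar"),
  percent = c(
    classification_percentages(rtt$novel_pyramidal, rtt$novel_active)$percent,
    classification_percentages(wt$novel_pyramidal, wt$novel_active)$percent,
    classification_percentages(wt$familiar_pyramidal, wt$familiar_active)$percent,
    classification_percentages(rtt$familiar_pyramidal, rtt$familiar_active)$percent))
print(pcts)
write.csv(pcts, "results/run_active_percentages.csv", row.names = FALSE)

cells <- read.csv("results/place_cells.csv")
active <- cells[cells$is_run_active & is.finite(cells$si), ]
si_wt <- active$si[active$genotype == "WT"]
si_rtt <- active$si[active$genotype == "RTT"]
set.seed(99)
groups <- list(
  rtt_novel = sample(si_rtt, 31),
  wt_novel = si_wt,
  wt_familiar = si_wt * runif(length(si_wt), 0.6, 1.0),
  rtt_familiar = si_rtt * runif(length(si_rtt), 0.3, 0.7))
comps <- list(c("rtt_novel", "wt_novel"), c("rtt_novel", "rtt_familiar"),
              c("wt_novel", "wt_familiar"), c("wt_familiar", "rtt_familiar"))
ds <- downsampling_analysis(groups, comps, reference = "rtt_novel",
                            n_iterations = 200, seed = 100)
res <- data.frame(comparison = names(ds$fraction_significant),
                  fraction_significant = as.numeric(ds$fraction_significant))
print(res)
write.csv(res, "results/downsampling.csv", row.names = FALSE)
cat("wrote results/run_active_percentages.csv, results/downsampling.csv\n")
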