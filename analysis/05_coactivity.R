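#!/usr/bin/env Rscript
# Step 5: within-ripple pairwise coactivity before vs after running.
#
# For every pair of run-active cells recorded in Pre-run, Run 1 and
# Post-run, spikes inside the padded (150 ms) ripple windows are
# cross-correlated in 20 ms bins, smoothed over 5 bins, baseline-subtracted
# (lags 180-220 ms) and rescaled by the Poisson expectation; coactivity is
# the mean normalized value within +/-50 ms. The control-like cohort should
# show a Pre- to Post-run increase, the mutant-like cohort an elevated
# Pre-run level with no increase.

library(placeripple)

dir.create("results", showWarnings = FALSE)
pair_table <- function(geno) {
  do.call(rbind, lapply(
    list.dirs(file.path("scratch/cohorts", geno), recursive = FALSE),
    function(ad) {
      run1 <- load_session(file.path(ad, "run1"))
      ra <- analyze_run_session(run1$position, run1$spikes)
      active <- ra$classes$cell_id[ra$classes$is_run_active]
      out <- lapply(c(pre = "pre_run", post = "post_run"), function(kind) {
        s <- load_session(file.path(ad, kind))
        w <- ripple_windows(detect_ripples(s$lfp))
        pc <- pairwise_coactivity(s$spikes, w, cell_ids = active)
        pc$animal_id <- basename(ad)
        pc
      })
      merge(out$pre, out$post, by = c("animal_id", "cell_a", "cell_b"),
            suffixes = c("_pre", "_post"))
    }))
}

wt <- pair_table("WT"); wt$genotype <- "WT"
rtt <- pair_table("RTT"); rtt$genotype <- "RTT"
coact <- rbind(wt, rtt)
write.csv(coact, "results/coactivity.csv", row.names = FALSE)

cat(sprintf("WT:  %d pairs, median coactivity pre %.2f -> post %.2f, paired t p = %.2g\n",
            nrow(wt), median(wt$coactivity_pre), median(wt$coactivity_post),
            paired_compare(wt$coactivity_pre, wt$coactivity_post)))
cat(sprintf("RTT: %d pairs, median coactivity pre %.2f -> post %.2f, paired t p = %.2g\n",
            nrow(rtt), median(rtt$coactivity_pre), median(rtt$coactivity_post),
            paired_compare(rtt$coactivity_pre, rtt$coactivity_post)))
cat(sprintf("Pre-run WT vs RTT ranksum p = %.2g; Post-run p = %.2g\n",
            ranksum_compare(wt$coactivity_pre, rtt$coactivity_pre),
            ranksum_compare(wt$coactivity_post, rtt$coactivity_post)))
cat("wrote results/coactivity.csv\n")
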