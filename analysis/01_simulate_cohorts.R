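#!/usr/bin/env Rscript
# Step 1: simulate the two cohorts the downstream analyses consume.
#
# Each animal contributes a Pre-run rest session, a Run 1 track session and a
# Post-run rest session. The control-like cohort ("WT-like", 7 animals) gets
# a low per-ripple coincidence rate before running and a high one after; the
# mutant-like cohort ("RTT-like", 9 animals) gets an equally elevated rate in
# both rest sessions. Session files (CSV + feather LFP) are large and
# regenerable, so they go under scratch/, not results/.

library(placeripple)

seed <- 1
out <- "scratch/cohorts"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

wt <- generate_cohort("WT-like", n_animals = 7, seed = seed)
rtt <- generate_cohort("RTT-like", n_animals = 9, seed = seed + 1000)

write_cohort(wt, file.path(out, "WT"))
write_cohort(rtt, file.path(out, "RTT"))

n_ripples <- function(an) nrow(an$pre_run$ground_truth$true_ripple_intervals)
cat("WT-like cohort: ", length(wt), "animals,",
    sum(sapply(wt, n_ripples)), "ground-truth Pre-run ripples\n")
cat("RTT-like cohort:", length(rtt), "animals,",
    sum(sapply(rtt, n_ripples)), "ground-truth Pre-run ripples\n")
cat("sessions written under", out, "\n")
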