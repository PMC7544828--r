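#!/usr/bin/env Rscript

# Step 1: simulate a cohort and its first-experiment vocal sessions.
#
# Each participant produces a 270-trial session (80 baseline / 10 ramp /
# 100 hold / 80 washout) under a +/- 100 cent feedback shift, with a
# drifting voice, trial-to-trial and within-trial F0 variability and a
# parametric opposing/following response. Sessions are written as
# long-format CSVs with ground-truth JSON sidecars.

suppressPackageStartupMessages(library(pitchadapt))

seed <- 20201008
n <- 12
out_dir <- "results/sessions"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cohort <- sample_cohort(n, seed = seed)
for (p in cohort) {
  s <- generate_session(p$speaker, p$direction, 100,
                        seed = substream_seed(seed, paste0("exp1-", p$id)))
  stub <- file.path(out_dir, sprintf("participant%02d_exp1", p$id))
  write_session_csv(s, paste0(stub, ".csv"))
  write_ground_truth_json(s, paste0(stub, "_truth.json"))
  message(sprintf("participant %2d (%4s shift): %d/270 trials included",
                  p$id, p$direction, sum(s$trials$included)))
}
message("wrote ", n, " sessions to ", out_dir)
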