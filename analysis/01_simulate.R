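#!/usr/bin/env Rscript
# Build the demonstration dataset: one synthetic recording session with
# known ground truth (theta phase, fixation phase-locking, theta-gamma
# coupling), written as plain-text files under results/session/.
#
# The session is a scaled-down emulation of a spatial-memory viewing task:
# Mismatch trials carry retrieval-locked (pre-fixation, theta peak) and
# novelty-locked (post-fixation, theta trough) fixation classes, and
# theta-gamma coupling is switched on during Mismatch trials only.

suppressPackageStartupMessages(library(thetagaze))

out_dir <- "results/session"
cfg <- sim_config(
  duration_s = 120, fs = 500,
  theta_freq = 5, theta_amp = 1, gamma_freq = 90, gamma_amp = 0.4,
  coupling_phase = pi,
  coupling_depth_by_condition = c(Mismatch = 0.8, Match = 0),
  n_trials = 30, fixation_rate = 3,
  kappa_by_condition = c("Mismatch/original" = 4, "Mismatch/updated" = 4),
  preferred_phase_by_condition = c("Mismatch/original" = 0,
                                   "Mismatch/updated" = pi),
  lock_offset_ms_by_condition = c("Mismatch/original" = -400,
                                  "Mismatch/updated" = 100),
  p_remember = 0.72, blink_rate = 0.1, seed = 20260923)

paths <- make_dataset(cfg, out_dir)
ds <- read_dataset(out_dir)
cat("Wrote session to", out_dir, "\n")
cat("  samples:", ncol(ds$recording$signal), "at", ds$recording$fs, "Hz\n")
cat("  fixation events:", nrow(ds$events), "\n")
cat("  trials:", nrow(ds$trials), "(",
    sum(ds$trials$condition == "Mismatch"), "Mismatch )\n")
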