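#!/usr/bin/env Rscript
# Parse the raw gaze record into saccade/fixation/blink events, label the
# fixations by trial / ROI / memory outcome, and compare against the
# generator's programmed saccades. Writes results/labeled_fixations.tsv.

suppressPackageStartupMessages(library(thetagaze))

ds <- read_dataset("results/session")
parsed <- detect_eye_events(ds$gaze)
cat("Parsed events:\n")
print(table(parsed$kind))

truth <- ds$truth$gaze_truth
sac_t <- truth[truth$kind == "saccade" & truth$amplitude >= 1, ]
det <- parsed[parsed$kind == "saccade", ]
err <- vapply(sac_t$onset_ms, function(o) min(abs(det$onset_ms - o)),
              numeric(1))
cat(sprintf("Programmed saccades >= 1 deg: %d; recovered within 4 ms: %.1f%%\n",
            nrow(sac_t), 100 * mean(err <= 4)))

labeled <- assign_fixations_to_rois(parsed, ds$trials)
cat("Fixations in the analysis window, by class:\n")
fx <- labeled[labeled$in_analysis_window, ]
print(table(fx$condition, fx$roi))
utils::write.table(labeled, "results/labeled_fixations.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Wrote results/labeled_fixations.tsv\n")
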