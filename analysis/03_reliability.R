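#!/usr/bin/env Rscript
# Stage 3 — reliability of the simulated PN labels.
#
# Reads results/pn_labels.csv (from 01_simulate.R) and computes, per
# condition: intra-session intra-rater ICCs (sessions 1 vs 2, one per
# rater), inter-session intra-rater ICCs (sessions 1 vs 3), and inter-rater
# ICCs (one per session, across the 5 raters) — each as ICC(A,1) with its
# F-based 95% CI, SEM (ms) and interpretation band.

suppressPackageStartupMessages(library(mrcprel))

out <- "results"
labels_path <- file.path(out, "pn_labels.csv")
if (!file.exists(labels_path)) {
  stop("run analysis/01_simulate.R first (missing ", labels_path, ")")
}
labels <- read.csv(labels_path, stringsAsFactors = FALSE)

v <- validate_inputs(labels = labels)
if (nrow(v) > 0) {
  print(v)
  stop("label table failed validation")
}

tables <- list()
for (cond in unique(labels$condition)) {
  for (design in c("intra_session", "inter_session", "inter_rater")) {
    tables[[length(tables) + 1L]] <- reliability_report(labels, design, cond)
  }
}
rel <- do.call(rbind, tables)
rel[c("icc", "ci_low", "ci_high")] <- round(rel[c("icc", "ci_low", "ci_high")], 3)
rel$sem <- round(rel$sem, 1)
write.csv(rel, file.path(out, "reliability.csv"), row.names = FALSE)

message("reliability summary (mean ICC and SEM by condition and design):")
print(aggregate(cbind(icc, sem) ~ condition + design, rel,
                function(x) round(mean(x), 2)))
message("band counts:")
print(table(rel$condition, rel$band))
message("wrote ", file.path(out, "reliability.csv"))
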