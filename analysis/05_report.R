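#!/usr/bin/env Rscript
# Stage 5 — consolidated report.
#
# Collects the stage outputs into one JSON report: similarity summaries per
# condition, reliability tables (ICC/CI/SEM/band), per-condition CS trends
# and provenance (seed, protocol sizes). Every number in the report is read
# back from a stage output file.

suppressPackageStartupMessages(library(mrcprel))

out <- "results"
need <- file.path(out, c("similarity.csv", "reliability.csv",
                         "cs_trends.csv"))
if (!all(file.exists(need))) {
  stop("run stages 01-04 first (missing: ",
       paste(need[!file.exists(need)], collapse = ", "), ")")
}
sim <- read.csv(need[1], stringsAsFactors = FALSE)
rel <- read.csv(need[2], stringsAsFactors = FALSE)
trends <- read.csv(need[3], stringsAsFactors = FALSE)

agg <- aggregate(cs ~ condition, sim, function(x) c(mean(x), sd(x)))
similarity_summary <- data.frame(
  condition = agg$condition,
  mean_cs = round(agg$cs[, 1], 3), sd_cs = round(agg$cs[, 2], 3))

report <- list(
  provenance = list(
    seed = as.integer(Sys.getenv("MRCPREL_SEED", "1")),
    package_version = as.character(packageVersion("mrcprel")),
    n_conditions = length(unique(sim$condition)),
    n_datasets = length(unique(sim$dataset_id)),
    n_epochs_per_dataset = max(sim$epoch_index)
  ),
  similarity = similarity_summary,
  reliability = rel,
  cs_trends = trends
)
jsonlite::write_json(report, file.path(out, "report.json"),
                     auto_unbox = TRUE, digits = NA, dataframe = "rows")

message("similarity (mean ± sd) per condition:")
print(similarity_summary)
message("reliability bands:")
print(table(rel$condition, rel$band))
message("wrote ", file.path(out, "report.json"))
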