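#!/usr/bin/env Rscript
# Stage 4 — association models.
#
# (a) Cosine similarity across conditions: random-intercept (dataset) linear
#     mixed model with condition as fixed effect, followed by Tukey pairwise
#     contrasts of the condition means.
# (b) Matched-epoch probability: random-intercept logistic model of the
#     intra-rater matched indicator (accepted at both sessions 1 and 2) on
#     cosine similarity x condition, with per-condition CS trends
#     (simple slopes) and probability-vs-CS curves with 95% bands.

suppressPackageStartupMessages(library(mrcprel))

out <- "results"
need <- file.path(out, c("similarity.csv", "acceptance.csv"))
if (!all(file.exists(need))) {
  stop("run analysis/01_simulate.R first (missing inputs)")
}
sim <- read.csv(need[1], stringsAsFactors = FALSE)
acc <- read.csv(need[2], stringsAsFactors = FALSE)
conds <- c("healthy_voluntary", "healthy_imagined", "stroke_voluntary")

# (a) cosine similarity across conditions
sim <- sim[sim$valid, ]
sim$condition <- factor(sim$condition, levels = conds)
lmm <- fit_lmm_random_intercept(sim, "cs", "condition", "dataset_id")
tukey <- pairwise_tukey(lmm, "condition")
write.csv(lmm$coefficients, file.path(out, "lmm_coefficients.csv"),
          row.names = FALSE)
write.csv(tukey, file.path(out, "tukey_contrasts.csv"), row.names = FALSE)
message("cosine similarity across conditions (Tukey-adjusted):")
print(within(tukey, adjusted_p <- signif(adjusted_p, 3)))

# (b) matched-epoch probability vs cosine similarity
ev <- list(acceptance = acc)
md <- matched_epoch_data(ev, sessions = c(1, 2))
md$condition <- factor(md$condition, levels = conds)
glmm <- fit_glmm_logit_random_intercept(
  md, "matched", c("cs", "condition", "cs:condition"), "dataset_id",
  quad_points = 7)
trends <- simple_slopes(glmm, "cs", "condition")
write.csv(glmm$coefficients, file.path(out, "glmm_coefficients.csv"),
          row.names = FALSE)
write.csv(trends, file.path(out, "cs_trends.csv"), row.names = FALSE)
message("per-condition CS trends (log odds of a matched epoch per unit CS):")
print(within(trends, {
  slope <- round(slope, 2); ci_low <- round(ci_low, 2)
  ci_high <- round(ci_high, 2); se <- round(se, 2)
}))

# interaction test: does the CS trend differ across conditions?
glmm_red <- fit_glmm_logit_random_intercept(
  md, "matched", c("cs", "condition"), "dataset_id", quad_points = 7)
test <- lrt(glmm, glmm_red)
message(sprintf("CS x condition interaction: chi2[%d] = %.2f, p = %.3g",
                test$df, test$chi2, test$p))

# probability curves per condition over the observed CS range
grids <- lapply(conds, function(cond) {
  pc <- probability_curve(glmm, "cs", seq(-0.2, 0.9, by = 0.05),
                          at = list(condition = cond))
  pc$condition <- cond
  pc
})
curves <- do.call(rbind, grids)
write.csv(curves, file.path(out, "probability_curves.csv"),
          row.names = FALSE)
message("wrote coefficient tables, trends and probability curves to ", out)
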