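#' Two-way ANOVA decomposition of a complete ratings matrix
#'
#' Standard two-way, one-observation-per-cell decomposition of an
#' n targets x k raters matrix into between-target (rows), between-rater
#' (columns) and residual sums of squares, the basis of the ICC and the SEM.
#'
#' @param m numeric matrix, n >= 2 rows (targets, e.g. datasets) by k >= 2
#'   columns (raters or sessions); no missing cells.
#' @return An `anova_decomposition`: list with `SSR`, `SSC`, `SSE`, `MSR`,
#'   `MSC`, `MSE`, `df` (named vector) and `n`, `k`.
#' @export
two_way_anova <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("ratings matrix has missing cells; no imputation is done")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 targets and 2 raters")
  g <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  SSR <- k * sum((rm_ - g)^2)
  SSC <- n * sum((cm_ - g)^2)
  SST <- sum((m - g)^2)
  SSE <- SST - SSR - SSC
  df <- c(rows = n - 1, cols = k - 1, error = (n - 1) * (k - 1))
  structure(
    list(SSR = SSR, SSC = SSC, SSE = max(SSE, 0), SST = SST,
         MSR = SSR / df["rows"], MSC = SSC / df["cols"],
         MSE = max(SSE, 0) / df["error"], df = df, n = n, k = k),
    class = "anova_decomposition"
  )
}

#' Standard error of measurement from the ANOVA
#'
#' `SEM = sqrt(MSE)`, the absolute-reliability index in the measurement's
#' own units (ms for PN latencies).
#'
#' @param a an [two_way_anova()] decomposition.
#' @return Non-negative number.
#' @export
sem_from_anova <- function(a) {
  stopifnot(inherits(a, "anova_decomposition"))
  sqrt(unname(a$MSE))
}

#' Interpretation band for an ICC value
#'
#' Bands: excellent (> 0.8\], good \[0.6, 0.8\], moderate \[0.4, 0.6),
#' poor (< 0.4, including negative estimates). Boundary values 0.8 and 0.6
#' fall in "good".
#'
#' @param icc finite ICC value.
#' @return One of `"excellent"`, `"good"`, `"moderate"`, `"poor"`.
#' @export
interpret_icc <- function(icc) {
  stopifnot(is.finite(icc))
  if (icc > 0.8) "excellent"
  else if (icc >= 0.6) "good"
  else if (icc >= 0.4) "moderate"
  else "poor"
}

#' ICC(A,1): two-way random effects, absolute agreement, single measures
#'
#' Point estimate
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`
#' with the F-based two-sided confidence interval for absolute agreement
#' (Satterthwaite degrees of freedom for the mixed mean square), plus
#' `SEM = sqrt(MSE)` and the interpretation band. Negative point estimates
#' are reported as computed (not clamped) and flagged.
#'
#' @param m ratings matrix (targets x raters), or an existing
#'   [two_way_anova()] decomposition.
#' @param alpha two-sided error rate for the CI (default 0.05 for 95% CI).
#' @return An `icc_result`: list with `icc`, `ci_low`, `ci_high`, `sem`,
#'   `n`, `k`, `alpha`, `band`, `negative` flag and the `anova`
#'   decomposition.
#' @export
icc_a1 <- function(m, alpha = 0.05) {
  a <- if (inherits(m, "anova_decomposition")) m else two_way_anova(m)
  MSR <- unname(a$MSR); MSC <- unname(a$MSC); MSE <- unname(a$MSE)
  n <- a$n; k <- a$k
  if (MSR == 0 && MSC == 0 && MSE == 0) {
    stop("degenerate ratings: all values identical")
  }
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  icc <- (MSR - MSE) / denom

  if (MSE == 0) {
    # perfect agreement given target variance: interval collapses
    ci <- c(icc, icc)
  } else {
    aa <- (k * icc) / (n * (1 - icc))
    bb <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (aa * MSC + bb * MSE)^2 /
      ((aa * MSC)^2 / (k - 1) + (bb * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(lower, upper)
  }
  structure(
    list(icc = icc, ci_low = ci[1], ci_high = ci[2],
         sem = sem_from_anova(a), n = n, k = k, alpha = alpha,
         band = interpret_icc(icc), negative = icc < 0, anova = a),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f  %d%% CI [%.3f, %.3f]  SEM = %.1f  (%s; n = %d, k = %d)\n",
              x$icc, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              x$sem, x$band, x$n, x$k))
  invisible(x)
}

# pivot a long label table into a complete targets x raters matrix,
# erroring with the missing cells named
ratings_matrix <- function(labels, rows, cols, value = "pn_ms") {
  key_r <- as.character(labels[[rows]])
  key_c <- as.character(labels[[cols]])
  ur <- unique(key_r); uc <- unique(key_c)
  m <- matrix(NA_real_, length(ur), length(uc), dimnames = list(ur, uc))
  m[cbind(match(key_r, ur), match(key_c, uc))] <- labels[[value]]
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    stop("incomplete label table; missing cells: ",
         paste(sprintf("(%s, %s)", ur[miss[, 1]], uc[miss[, 2]]),
               collapse = ", "))
  }
  m
}

#' Reliability report over a PN label table
#'
#' Builds the study's reliability tables from long-format PN labels:
#' \describe{
#'   \item{intra_session}{one ICC per rater from sessions 1 vs 2
#'     (n = datasets, k = 2) — same-day repeatability.}
#'   \item{inter_session}{one ICC per rater from sessions 1 vs 3
#'     (n = datasets, k = 2) — across-day repeatability.}
#'   \item{inter_rater}{one ICC per session across all raters
#'     (n = datasets, k = raters).}
#' }
#'
#' @param labels data frame with `dataset_id`, `condition`, `rater_id`,
#'   `session`, `pn_ms`; must be complete for the requested design.
#' @param design `"intra_session"`, `"inter_session"` or `"inter_rater"`.
#' @param condition condition to analyse.
#' @param alpha CI error rate.
#' @param sessions for the intra designs, the two sessions compared
#'   (defaults 1,2 for intra_session and 1,3 for inter_session).
#' @return Data frame, one row per ICC: `condition`, `design`, `unit`
#'   (rater or session the row describes), `icc`, `ci_low`, `ci_high`,
#'   `sem`, `band`, `n`, `k`.
#' @export
reliability_report <- function(labels, design = c("intra_session",
                                                  "inter_session",
                                                  "inter_rater"),
                               condition, alpha = 0.05, sessions = NULL) {
  design <- match.arg(design)
  lab <- labels[labels$condition == condition, ]
  if (nrow(lab) == 0) stop("no labels for condition ", condition)
  rows <- list()
  if (design %in% c("intra_session", "inter_session")) {
    if (is.null(sessions)) {
      sessions <- if (design == "intra_session") c(1, 2) else c(1, 3)
    }
    for (r in unique(lab$rater_id)) {
      sub <- lab[lab$rater_id == r & lab$session %in% sessions, ]
      m <- ratings_matrix(sub, "dataset_id", "session")
      res <- icc_a1(m, alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = condition, design = design, unit = r,
        icc = res$icc, ci_low = res$ci_low, ci_high = res$ci_high,
        sem = res$sem, band = res$band, n = res$n, k = res$k,
        stringsAsFactors = FALSE
      )
    }
  } else {
    for (s in sort(unique(lab$session))) {
      sub <- lab[lab$session == s, ]
      m <- ratings_matrix(sub, "dataset_id", "rater_id")
      res <- icc_a1(m, alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = condition, design = design, unit = paste0("session_", s),
        icc = res$icc, ci_low = res$ci_low, ci_high = res$ci_high,
        sem = res$sem, band = res$band, n = res$n, k = res$k,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
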