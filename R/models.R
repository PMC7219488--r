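new_fit_result <- function(fit, family, fixed_formula, data, cluster = NULL) {
  beta <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  stat <- beta / se
  coefs <- data.frame(
    term = names(beta), estimate = unname(beta), se = unname(se),
    statistic = unname(stat), stringsAsFactors = FALSE
  )
  if (family == "binomial") {
    coefs$p <- 2 * stats::pnorm(-abs(coefs$statistic))
  }
  ri_sd <- if (inherits(fit, "merMod")) {
    vc <- lme4::VarCorr(fit)
    sqrt(unname(vc[[1]][1, 1]))
  } else {
    0
  }
  ll <- stats::logLik(fit)
  num <- vapply(data, is.numeric, logical(1))
  ranges <- lapply(data[num], range)
  structure(
    list(
      fit = fit, family = family, coefficients = coefs,
      random_intercept_sd = ri_sd,
      log_likelihood = as.numeric(ll), n_params = attr(ll, "df"),
      fixed_formula = fixed_formula, cluster = cluster,
      xlevels = lapply(Filter(is.factor, data), levels),
      ranges = ranges,
      vcov_fixed = V,
      converged = TRUE
    ),
    class = "fit_result"
  )
}

check_merMod_convergence <- function(fit) {
  if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0) {
    stop("mixed-model optimiser failed to converge: ",
         paste(unlist(fit@optinfo$conv$lme4), collapse = "; "))
  }
  invisible(fit)
}

#' Random-intercept linear mixed model (REML)
#'
#' Fits `response ~ fixed_terms + (1 | cluster)` by REML via [lme4::lmer()].
#' Used for the cosine-similarity-across-conditions analysis, with the
#' dataset as the clustering unit. A boundary fit (cluster variance
#' estimated at zero) is returned converged with `random_intercept_sd = 0`
#' and `boundary = TRUE`; its fixed effects then equal ordinary least
#' squares.
#'
#' @param data data frame.
#' @param response response variable name.
#' @param fixed_terms character vector of fixed-effect terms (may include
#'   interactions, e.g. `"cs:condition"`).
#' @param cluster grouping variable name for the single random intercept.
#' @return A `fit_result`: coefficient table (estimate, SE, t), the
#'   random-intercept SD, residual SD (`sigma`), REML criterion and the
#'   underlying fit.
#' @export
fit_lmm_random_intercept <- function(data, response, fixed_terms = "1",
                                     cluster) {
  stopifnot(length(unique(data[[cluster]])) >= 2)
  fixed <- stats::reformulate(fixed_terms, response = response)
  form <- stats::as.formula(
    paste(response, "~", paste(fixed_terms, collapse = " + "),
          "+ (1 |", cluster, ")"))
  fit <- lme4::lmer(form, data = data, REML = TRUE)
  check_merMod_convergence(fit)
  out <- new_fit_result(fit, "gaussian", fixed, data, cluster)
  out$sigma <- stats::sigma(fit)
  out$boundary <- out$random_intercept_sd < 1e-8
  out
}

#' Tukey pairwise contrasts of factor level means
#'
#' All pairwise comparisons of the estimated marginal means of `factor`,
#' with studentized-range (Tukey) adjusted p-values, via \pkg{emmeans}.
#'
#' @param fit a `fit_result` from [fit_lmm_random_intercept()] (or any fit
#'   emmeans supports).
#' @param factor factor name present in the model.
#' @return Data frame: `pair`, `estimate`, `se`, `df`, `t_stat`,
#'   `adjusted_p`.
#' @export
pairwise_tukey <- function(fit, factor) {
  stopifnot(inherits(fit, "fit_result"))
  if (!factor %in% all.vars(fit$fixed_formula)) {
    stop("factor '", factor, "' is not in the fitted model")
  }
  em <- emmeans::emmeans(fit$fit, specs = factor)
  pr <- summary(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
  data.frame(
    pair = as.character(pr$contrast), estimate = pr$estimate, se = pr$SE,
    df = pr$df, t_stat = pr$t.ratio, adjusted_p = pr$p.value,
    stringsAsFactors = FALSE
  )
}

#' Fixed-effects logistic regression (IRLS)
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares ([stats::glm()]), with Wald z tests. Complete or quasi-complete
#' separation (diverging coefficients / degenerate fitted probabilities) is
#' an error rather than a silent near-infinite fit.
#'
#' @param data data frame.
#' @param response binary response variable name (logical or 0/1).
#' @param fixed_terms character vector of model terms.
#' @return A `fit_result` with estimate, SE, z, p per coefficient.
#' @export
fit_logistic_irls <- function(data, response, fixed_terms = "1") {
  y <- data[[response]]
  if (length(unique(y)) < 2 && length(fixed_terms) >= 1) {
    if (all(as.integer(y) == 1L) || all(as.integer(y) == 0L)) {
      stop("separation: response is constant (all ",
           as.integer(y[1]), ")")
    }
  }
  form <- stats::reformulate(fixed_terms, response = response)
  fit <- stats::glm(form, data = data, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  co <- stats::coef(fit)
  mu <- stats::fitted(fit)
  if (any(abs(co) > 15) && (any(mu < 1e-8) || any(mu > 1 - 1e-8))) {
    stop("separation detected at term '", names(co)[which.max(abs(co))], "'")
  }
  new_fit_result(fit, "binomial", form, data)
}

#' Random-intercept logistic mixed model (adaptive Gauss--Hermite)
#'
#' Fits `response ~ fixed_terms + (1 | cluster)` with a logit link via
#' [lme4::glmer()], integrating the random intercept by adaptive
#' Gauss--Hermite quadrature with `quad_points` nodes (25 by default;
#' `quad_points = 1` is the Laplace approximation). This is the
#' matched-epoch model: log odds of an epoch being matched as a linear
#' function of cosine similarity, condition and their interaction, with a
#' random intercept per dataset.
#'
#' @param data data frame.
#' @param response binary response name.
#' @param fixed_terms character vector of fixed-effect terms.
#' @param cluster grouping variable name.
#' @param quad_points number of quadrature nodes (>= 1).
#' @return A `fit_result` with Wald z tests, random-intercept SD and the
#'   marginal log-likelihood.
#' @export
fit_glmm_logit_random_intercept <- function(data, response, fixed_terms = "1",
                                            cluster, quad_points = 25) {
  if (quad_points < 1) stop("quad_points must be >= 1")
  fixed <- stats::reformulate(fixed_terms, response = response)
  form <- stats::as.formula(
    paste(response, "~", paste(fixed_terms, collapse = " + "),
          "+ (1 |", cluster, ")"))
  fit <- lme4::glmer(form, data = data, family = stats::binomial(),
                     nAGQ = quad_points)
  check_merMod_convergence(fit)
  new_fit_result(fit, "binomial", fixed, data, cluster)
}

#' Likelihood-ratio test of nested fits
#'
#' `chi2 = 2 (logLik_full - logLik_reduced)` on `df` = parameter-count
#' difference. A chi-square statistic that is negative within numerical
#' tolerance is clamped to zero and flagged; beyond tolerance it is an
#' error (the larger model failed to reach its optimum).
#'
#' @param full,reduced nested `fit_result`s on the same data.
#' @param tol tolerance for a negative statistic.
#' @return List with `chi2`, `df`, `p`, `clamped`.
#' @export
lrt <- function(full, reduced, tol = 1e-6) {
  stopifnot(inherits(full, "fit_result"), inherits(reduced, "fit_result"))
  df <- full$n_params - reduced$n_params
  if (df < 0) stop("'full' must not have fewer parameters than 'reduced'")
  chi2 <- 2 * (full$log_likelihood - reduced$log_likelihood)
  clamped <- FALSE
  if (chi2 < 0) {
    if (chi2 < -tol) {
      stop("full model has lower log-likelihood than reduced model ",
           "(non-convergence?)")
    }
    chi2 <- 0
    clamped <- TRUE
  }
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p, clamped = clamped)
}

fixed_model_matrix <- function(fit, newdata) {
  tt <- stats::delete.response(stats::terms(fit$fixed_formula))
  mf <- stats::model.frame(tt, newdata, xlev = fit$xlevels)
  stats::model.matrix(tt, mf)
}

#' Matched-probability curve over a predictor grid
#'
#' Transforms the fitted log odds to the probability scale over a grid of
#' predictor values (other predictors held at supplied reference values),
#' with pointwise Wald confidence limits computed on the logit scale and
#' back-transformed (delta method). For mixed fits the curve is conditional
#' on a random intercept of zero (the typical dataset). Grid points outside
#' the observed predictor range are computed but flagged as extrapolation.
#'
#' @param fit a binomial `fit_result`.
#' @param predictor predictor name to vary.
#' @param grid numeric vector of predictor values.
#' @param at named list of reference values for the remaining model
#'   variables.
#' @param level confidence level.
#' @return Data frame: predictor value, `probability`, `ci_low`, `ci_high`,
#'   `extrapolated`.
#' @export
probability_curve <- function(fit, predictor, grid, at = list(),
                              level = 0.95) {
  stopifnot(inherits(fit, "fit_result"), fit$family == "binomial")
  vars <- all.vars(stats::delete.response(stats::terms(fit$fixed_formula)))
  if (!predictor %in% vars) stop("predictor '", predictor, "' not in model")
  newdata <- as.data.frame(c(stats::setNames(list(grid), predictor), at),
                           stringsAsFactors = FALSE)
  for (v in names(fit$xlevels)) {
    if (v %in% names(newdata)) {
      newdata[[v]] <- factor(newdata[[v]], levels = fit$xlevels[[v]])
    }
  }
  X <- fixed_model_matrix(fit, newdata)
  beta <- fit$coefficients$estimate
  eta <- drop(X %*% beta)
  se <- sqrt(rowSums((X %*% fit$vcov_fixed) * X))
  z <- stats::qnorm(1 - (1 - level) / 2)
  rng <- fit$ranges[[predictor]]
  out <- data.frame(
    grid, probability = stats::plogis(eta),
    ci_low = stats::plogis(eta - z * se),
    ci_high = stats::plogis(eta + z * se),
    extrapolated = if (is.null(rng)) FALSE else grid < rng[1] | grid > rng[2]
  )
  names(out)[1] <- predictor
  out
}

#' Per-level simple slopes of a predictor under treatment coding
#'
#' For a model with `predictor * factor` fixed effects, returns each factor
#' level's slope of `predictor` (reference slope, or reference slope plus
#' interaction), with Wald standard errors and confidence limits — the
#' "per-condition trend" presentation of an interaction model.
#'
#' @param fit a `fit_result` containing `predictor` and its interactions
#'   with `factor`.
#' @param predictor continuous predictor name.
#' @param factor factor name.
#' @param level confidence level.
#' @return Data frame: `level`, `slope`, `se`, `ci_low`, `ci_high`.
#' @export
simple_slopes <- function(fit, predictor, factor, level = 0.95) {
  stopifnot(inherits(fit, "fit_result"))
  terms_ <- fit$coefficients$term
  lvls <- fit$xlevels[[factor]]
  if (is.null(lvls)) stop("factor '", factor, "' not in model")
  base <- which(terms_ == predictor)
  if (length(base) != 1) stop("predictor '", predictor, "' not in model")
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- lapply(lvls, function(lv) {
    cvec <- numeric(length(terms_))
    cvec[base] <- 1
    inter <- which(terms_ %in% paste0(predictor, ":", factor, lv) |
                     terms_ %in% paste0(factor, lv, ":", predictor))
    if (length(inter) == 1) cvec[inter] <- 1
    est <- sum(cvec * fit$coefficients$estimate)
    se <- sqrt(drop(t(cvec) %*% fit$vcov_fixed %*% cvec))
    data.frame(level = lv, slope = est, se = se,
               ci_low = est - z * se, ci_high = est + z * se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
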