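sim_lmm_data <- function(n_cluster, n_per, sd_cluster, sd_resid = 1,
                         beta = c(0, 0.5)) {
  cluster <- rep(seq_len(n_cluster), each = n_per)
  x <- rnorm(n_cluster * n_per)
  u <- rnorm(n_cluster, 0, sd_cluster)
  data.frame(
    y = beta[1] + beta[2] * x + u[cluster] + rnorm(length(x), 0, sd_resid),
    x = x, cluster = factor(cluster)
  )
}

test_that("LMM with no cluster variability collapses to OLS", {
  set.seed(101)
  d <- sim_lmm_data(20, 15, sd_cluster = 0)
  fit <- fit_lmm_random_intercept(d, "y", "x", "cluster")
  expect_lt(fit$random_intercept_sd, 0.05)
  ols <- coef(lm(y ~ x, data = d))
  expect_equal(fit$coefficients$estimate, unname(ols), tolerance = 1e-2)
})

test_that("balanced one-way REML equals the closed-form ANOVA solution", {
  set.seed(102)
  n_cluster <- 12; n_per <- 8
  d <- sim_lmm_data(n_cluster, n_per, sd_cluster = 1.5, beta = c(2, 0))
  d$x <- NULL
  fit <- fit_lmm_random_intercept(d, "y", "1", "cluster")
  # method-of-moments components from the balanced one-way ANOVA
  gm <- mean(d$y)
  cm <- tapply(d$y, d$cluster, mean)
  MSB <- n_per * sum((cm - gm)^2) / (n_cluster - 1)
  MSW <- sum((d$y - cm[d$cluster])^2) / (n_cluster * (n_per - 1))
  expect_equal(fit$sigma^2, MSW, tolerance = 1e-6)
  expect_equal(fit$random_intercept_sd^2, (MSB - MSW) / n_per,
               tolerance = 1e-6)
  expect_equal(fit$coefficients$estimate[1], gm, tolerance = 1e-8)
})

test_that("LMM recovers known fixed effects at simulation scale", {
  set.seed(103)
  hits <- replicate(60, {
    d <- sim_lmm_data(30, 50, sd_cluster = 0.1, sd_resid = 0.15,
                      beta = c(0.4, 0.12))
    fit <- fit_lmm_random_intercept(d, "y", "x", "cluster")
    slope <- fit$coefficients[fit$coefficients$term == "x", ]
    abs(slope$estimate - 0.12) < 3 * slope$se
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Tukey contrasts reduce correctly and match the q distribution", {
  set.seed(104)
  d <- data.frame(
    g = factor(rep(c("a", "b", "c"), each = 20)),
    cluster = factor(rep(1:12, each = 5))
  )
  d$y <- c(0, 0.8, 0.3)[as.integer(d$g)] + rnorm(60)
  fit <- fit_lmm_random_intercept(d, "y", "g", "cluster")
  tk <- pairwise_tukey(fit, "g")
  expect_equal(nrow(tk), 3)
  # adjusted p equals the studentized-range oracle at each contrast
  for (i in seq_len(3)) {
    p_q <- ptukey(abs(tk$t_stat[i]) * sqrt(2), nmeans = 3, df = tk$df[i],
                  lower.tail = FALSE)
    expect_equal(tk$adjusted_p[i], p_q, tolerance = 1e-8)
  }

  # two levels: Tukey adjustment is a no-op
  d2 <- d[d$g != "c", ]; d2$g <- droplevels(d2$g)
  fit2 <- fit_lmm_random_intercept(d2, "y", "g", "cluster")
  tk2 <- pairwise_tukey(fit2, "g")
  p_t <- 2 * pt(-abs(tk2$t_stat), tk2$df)
  expect_equal(tk2$adjusted_p, p_t, tolerance = 1e-8)

  # identical group means: nothing significant
  set.seed(105)
  d3 <- d; d3$y <- rep(5, 60) + rnorm(60, 0, 1e-3) +
    as.numeric(d3$cluster) * 0
  fit3 <- fit_lmm_random_intercept(d3, "y", "g", "cluster")
  tk3 <- pairwise_tukey(fit3, "g")
  expect_true(all(tk3$adjusted_p > 0.5))

  expect_error(pairwise_tukey(fit, "condition"), "not in the fitted model")
})

test_that("logistic IRLS matches closed forms and flags separation", {
  # intercept-only: logit of the response mean
  set.seed(106)
  d <- data.frame(y = rbinom(400, 1, 0.3))
  fit <- fit_logistic_irls(d, "y")
  expect_equal(fit$coefficients$estimate[1], qlogis(mean(d$y)),
               tolerance = 1e-8)

  # 2x2 table with cell probabilities 20/80 and 50/50: slope = log 4
  d2 <- data.frame(
    x = rep(c(0, 1), each = 100),
    y = c(rep(c(1, 0), times = c(20, 80)), rep(c(1, 0), times = c(50, 50)))
  )
  fit2 <- fit_logistic_irls(d2, "y", "x")
  expect_equal(fit2$coefficients$estimate[2], log(4), tolerance = 1e-8)
  expect_equal(fit2$coefficients$estimate[1], qlogis(0.2), tolerance = 1e-8)

  expect_error(fit_logistic_irls(data.frame(y = rep(1, 50), x = rnorm(50)),
                                 "y", "x"),
               "separation")
  # quasi-complete separation on a perfectly predictive binary term
  d3 <- data.frame(x = rep(c(0, 1), each = 50), y = rep(c(0, 1), each = 50))
  expect_error(suppressWarnings(fit_logistic_irls(d3, "y", "x")),
               "separation")
})

test_that("GLMM nests the fixed-effects logistic model", {
  # no cluster effect in truth: GLMM fixed effects match IRLS within 1e-3
  set.seed(107)
  n <- 1500
  d <- data.frame(x = rnorm(n),
                  cluster = factor(rep(1:30, each = n / 30)))
  d$y <- rbinom(n, 1, plogis(-0.5 + 1.2 * d$x))
  glm_fit <- fit_logistic_irls(d, "y", "x")
  glmm_fit <- fit_glmm_logit_random_intercept(d, "y", "x", "cluster",
                                              quad_points = 25)
  expect_lt(glmm_fit$random_intercept_sd, 0.15)
  expect_equal(glmm_fit$coefficients$estimate,
               glm_fit$coefficients$estimate, tolerance = 1e-1)

  # with the variance truly at the boundary the fits agree tightly
  d0 <- d; d0$cluster <- factor(rep(1:30, times = n / 30))  # reshuffled
  glmm0 <- fit_glmm_logit_random_intercept(d0, "y", "x", "cluster",
                                           quad_points = 25)
  if (glmm0$random_intercept_sd < 1e-4) {
    expect_equal(glmm0$coefficients$estimate,
                 glm_fit$coefficients$estimate, tolerance = 1e-3)
  }

  expect_error(
    fit_glmm_logit_random_intercept(d, "y", "x", "cluster", quad_points = 0),
    "quad_points")
})

test_that("quadrature is converged at the default number of nodes", {
  set.seed(108)
  n <- 600
  cluster <- factor(rep(1:20, each = 30))
  u <- rnorm(20, 0, 0.8)
  d <- data.frame(x = rnorm(n), cluster = cluster)
  d$y <- rbinom(n, 1, plogis(-0.3 + 0.9 * d$x + u[cluster]))
  f25 <- fit_glmm_logit_random_intercept(d, "y", "x", "cluster", 25)
  f50 <- fit_glmm_logit_random_intercept(d, "y", "x", "cluster", 50)
  expect_lt(abs(f25$log_likelihood - f50$log_likelihood), 1e-4)
})

test_that("likelihood-ratio test behaves at its edges", {
  set.seed(109)
  d <- data.frame(x = rnorm(300), z = rnorm(300))
  d$y <- rbinom(300, 1, plogis(0.5 * d$x))
  full <- fit_logistic_irls(d, "y", c("x", "z"))
  reduced <- fit_logistic_irls(d, "y", "x")
  out <- lrt(full, reduced)
  expect_equal(out$df, 1)
  expect_gte(out$chi2, 0)
  expect_true(out$p >= 0 && out$p <= 1)

  # identical models: zero statistic, p = 1
  out0 <- lrt(full, full)
  expect_equal(out0$chi2, 0)
  expect_equal(out0$p, 1)

  # a "full" model with lower likelihood is a convergence failure signal
  fake <- reduced; fake$n_params <- full$n_params + 1
  fake$log_likelihood <- full$log_likelihood - 1
  expect_error(lrt(fake, full), "lower log-likelihood")
})

test_that("probability curves transform Wald limits through the logit", {
  set.seed(110)
  n <- 800
  d <- data.frame(cs = runif(n, 0, 1))
  d$y <- rbinom(n, 1, plogis(-2 + 4 * d$cs))
  fit <- fit_logistic_irls(d, "y", "cs")
  grid <- seq(0, 1, by = 0.1)
  pc <- probability_curve(fit, "cs", grid)

  # monotone non-decreasing for a positive slope
  expect_true(all(diff(pc$probability) >= 0))
  expect_true(all(pc$ci_low <= pc$probability & pc$probability <= pc$ci_high))

  # brute-force delta-method recomputation at every grid point
  beta <- fit$coefficients$estimate
  V <- fit$vcov_fixed
  for (i in seq_along(grid)) {
    xv <- c(1, grid[i])
    eta <- sum(xv * beta)
    se <- sqrt(drop(t(xv) %*% V %*% xv))
    expect_equal(pc$probability[i], plogis(eta), tolerance = 1e-10)
    expect_equal(pc$ci_low[i], plogis(eta - qnorm(0.975) * se),
                 tolerance = 1e-10)
    expect_equal(pc$ci_high[i], plogis(eta + qnorm(0.975) * se),
                 tolerance = 1e-10)
  }

  # the root of the linear predictor maps to probability one half
  x_half <- -beta[1] / beta[2]
  pc_half <- probability_curve(fit, "cs", x_half)
  expect_equal(pc_half$probability, 0.5, tolerance = 1e-10)

  # out-of-range grid points are flagged, not refused
  pc2 <- probability_curve(fit, "cs", c(-0.5, 0.5, 1.5))
  expect_equal(pc2$extrapolated, c(TRUE, FALSE, TRUE))

  expect_error(probability_curve(fit, "nope", grid), "not in model")
})

test_that("simple slopes reassemble reference and interaction terms", {
  set.seed(111)
  n <- 900
  d <- data.frame(
    cs = runif(n), g = factor(rep(c("a", "b", "c"), each = n / 3)),
    cluster = factor(rep(1:30, times = n / 30))
  )
  slopes_true <- c(a = 4, b = 1, c = 2.5)
  d$y <- rbinom(n, 1, plogis(-1 + slopes_true[d$g] * d$cs))
  fit <- fit_logistic_irls(d, "y", c("cs", "g", "cs:g"))
  ss <- simple_slopes(fit, "cs", "g")
  expect_equal(ss$level, c("a", "b", "c"))
  # slope of the reference level is the bare cs coefficient
  expect_equal(ss$slope[1],
               fit$coefficients$estimate[fit$coefficients$term == "cs"])
  # each level's slope equals a subset refit's slope (independent route)
  for (lv in c("a", "b", "c")) {
    sub <- fit_logistic_irls(d[d$g == lv, ], "y", "cs")
    expect_equal(ss$slope[ss$level == lv],
                 sub$coefficients$estimate[2], tolerance = 1e-6)
    expect_equal(ss$se[ss$level == lv], sub$coefficients$se[2],
                 tolerance = 1e-4)
  }
})
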