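# Independent oracles and small fixtures used across the suite.

# Textbook ICC(A,1) computed through a different route than the package:
# the ANOVA mean squares come from stats::aov on the long-format data, and
# every downstream quantity is recomputed step by step here.
oracle_icc_a1 <- function(m, alpha = 0.05) {
  n <- nrow(m); k <- ncol(m)
  long <- data.frame(
    y = as.vector(m),
    target = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  av <- summary(stats::aov(y ~ target + rater, data = long))[[1]]
  MSR <- av["target", "Mean Sq"]
  MSC <- av["rater", "Mean Sq"]
  MSE <- av["Residuals", "Mean Sq"]
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  list(
    MSR = MSR, MSC = MSC, MSE = MSE,
    icc = icc,
    ci_low = n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR),
    ci_high = n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR),
    sem = sqrt(MSE)
  )
}

# ratings matrix drawn from the two-way random-effects generative model
sim_ratings <- function(n, k, sd_target, sd_rater, sd_error, mu = 0) {
  mu + matrix(stats::rnorm(n, 0, sd_target), n, k) +
    matrix(stats::rnorm(k, 0, sd_rater), n, k, byrow = TRUE) +
    matrix(stats::rnorm(n * k, 0, sd_error), n, k)
}

# hand-built epoch_set around arbitrary epoch rows
make_toy_epochs <- function(epochs, fs = 500, pre_s = 3,
                            dataset_id = "toy", condition = "healthy_voluntary") {
  n <- ncol(epochs)
  cue <- round(pre_s * fs)
  structure(
    list(dataset_id = dataset_id, condition = condition, epochs = epochs,
         fs = fs, cue_index = cue,
         time_ms = (seq_len(n) - 1 - cue) / fs * 1000),
    class = "epoch_set"
  )
}

# acceptance record covering every epoch for one rater/session
make_acceptance <- function(dataset_id, rater_id, session, accept) {
  data.frame(
    dataset_id = dataset_id, condition = NA_character_, rater_id = rater_id,
    session = session, experience = 5,
    epoch_index = seq_along(accept), cs = NA_real_, accept = accept,
    stringsAsFactors = FALSE
  )
}

# |H(f)|^2 magnitude of a designed digital filter at frequency f (Hz),
# evaluated directly from the transfer-function polynomials
oracle_mag2 <- function(b, a, f, fs) {
  z <- exp(-2i * pi * f / fs)
  h <- sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1))
  Mod(h)^2
}
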