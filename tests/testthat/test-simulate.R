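fixed_params <- function(...) {
  # degenerate-variance condition for exact-limit checks
  condition_params(
    condition_id = "fixed",
    pn_amplitude_mean = -15, pn_amplitude_sd = 0,
    ramp_onset_ms = -1500,
    pn_latency_mean_ms = 100, pn_latency_between_sd_ms = 0,
    pn_latency_jitter_sd_ms = 0, amp_scale_sd = 0,
    background_noise_sd = 0, artefact_prob = 0,
    ...
  )
}

test_that("the template plants the PN where the parameters say", {
  set.seed(1)
  tpl <- make_template(fixed_params(), fs = 500, pre_s = 3, post_s = 1.5)
  expect_equal(min(tpl$samples), -15)
  expect_equal(which.min(tpl$samples) - 1L, tpl$cue_index + 0.1 * 500)
  expect_equal(tpl$true_pn_amplitude, -15)
  expect_equal(tpl$true_pn_ms, 100)
  # baseline before ramp onset is flat zero
  pre_ramp <- tpl$samples[tpl$time_ms < -1500]
  expect_true(all(abs(pre_ramp) < 0.1 * 15))
  # monotone ramp down, recovery back up
  ramp <- tpl$samples[tpl$time_ms >= -1500 & tpl$time_ms <= 100]
  expect_true(all(diff(ramp) <= 1e-12))

  # drawn amplitudes for healthy voluntary stay in the MRCP range
  hv <- default_condition_params()$healthy_voluntary
  set.seed(2)
  amps <- replicate(25, make_template(hv)$true_pn_amplitude)
  expect_true(all(amps >= -30 & amps <= -5))

  # latency outside the window errors
  bad <- condition_params("bad", -10, 0, -1500, 2000, 0, 0,
                          background_noise_sd = 0)
  expect_error(make_template(bad, 500, 3, 1.5), "outside")
  expect_error(make_template(fixed_params(), 500, pre_s = 1), "pre_s")
})

test_that("simulate_epoch degenerates to the template and flags artefacts", {
  set.seed(3)
  tpl <- make_template(fixed_params())
  ep <- simulate_epoch(tpl, fixed_params())
  expect_identical(ep$samples, tpl$samples)  # zero-noise limit is exact
  expect_false(ep$artefact)

  every <- fixed_params(); every$artefact_prob <- 1
  set.seed(4)
  flags <- replicate(10, simulate_epoch(tpl, every)$artefact)
  expect_true(all(flags))

  # determinism under a fixed seed
  noisy <- default_condition_params()$healthy_voluntary
  tpl2 <- with_substream(10, make_template(noisy))
  e1 <- with_substream(11, simulate_epoch(tpl2, noisy))
  e2 <- with_substream(11, simulate_epoch(tpl2, noisy))
  expect_identical(e1$samples, e2$samples)
})

test_that("simulate_dataset returns 50 reproducible epochs with ground truth", {
  cfg <- simulation_config(seed = 5)
  es <- simulate_dataset("healthy_voluntary", 1, cfg)
  expect_s3_class(es, "epoch_set")
  expect_equal(dim(es$epochs), c(50, 2250))
  expect_equal(es$cue_index, 1500)
  expect_length(es$ground_truth$artefact, 50)
  expect_lt(es$ground_truth$true_pn_amplitude, 0)

  # byte-identical across runs
  es2 <- simulate_dataset("healthy_voluntary", 1, cfg)
  expect_identical(es$epochs, es2$epochs)

  # rater panel composition does not perturb the dataset sub-stream
  cfg_more_raters <- simulation_config(
    seed = 5, rater_profiles = default_rater_profiles()[1:2])
  es3 <- simulate_dataset("healthy_voluntary", 1, cfg_more_raters)
  expect_identical(es$epochs, es3$epochs)

  expect_error(simulate_dataset("unknown", 1, cfg), "unknown condition")
})

test_that("noise-free datasets have cosine similarity exactly 1", {
  cfg <- simulation_config(
    seed = 6, n_epochs = 10,
    condition_params = list(fixed = fixed_params()))
  es <- simulate_dataset("fixed", 1, cfg)
  expect_equal(similarity_table(es)$cs, rep(1, 10), tolerance = 1e-12)
})

test_that("continuous recordings respect the cued-movement protocol", {
  cfg <- simulation_config(seed = 7)
  sim <- simulate_continuous("healthy_voluntary", cfg)
  expect_length(sim$cue_times, 50)
  expect_true(all(diff(sim$cue_times) > 0))
  # inter-cue gap = rest (6-8 s) + focus (2-3 s)
  expect_true(all(diff(sim$cue_times) >= 8 & diff(sim$cue_times) <= 11))
  expect_equal(nrow(sim$recording$data), 10)
  expect_true(all(c("Cz", "Fz", "Pz", "C3", "C4", "FP1") %in%
                    sim$recording$channel_names))
})

test_that("preprocess + epoching recovers the injected template", {
  # zero-noise recording: the full chain (band-pass, Laplacian, epoching)
  # must reproduce the injected MRCP shape in every epoch
  clean <- condition_params(
    "clean", -15, 0, -1500, 100, 0, 0, amp_scale_sd = 0,
    background_noise_sd = 0, artefact_prob = 0)
  cfg <- simulation_config(seed = 8, n_epochs = 10,
                           condition_params = list(clean = clean))
  sim <- simulate_continuous("clean", cfg)
  es <- preprocess_recording(sim$recording, sim$cue_times,
                             dataset_id = "rt", condition = "clean")
  expect_equal(nrow(es$epochs), 10)
  tpl <- sim$ground_truth$template$samples
  for (i in seq_len(nrow(es$epochs))) {
    expect_gt(stats::cor(es$epochs[i, ], tpl), 0.99)
  }
})

test_that("rater decisions follow the logistic acceptance model", {
  cfg <- simulation_config(seed = 9)
  es <- simulate_dataset("healthy_voluntary", 1, cfg)
  cs <- similarity_table(es)$cs

  # zero slope: empirical accept rate converges to plogis(intercept)
  flat <- rater_profile("flat", 5, accept_intercept = -0.4,
                        accept_cs_slope = 0)
  acc <- do.call(rbind, lapply(1:40, function(s)
    simulate_rater_decisions(es, cs, flat, s, seed = s)))
  expect_lt(abs(mean(acc$accept) - plogis(-0.4)), 0.03)

  # saturated intercept accepts everything
  sat <- rater_profile("sat", 5, accept_intercept = 10, accept_cs_slope = 0)
  acc_sat <- simulate_rater_decisions(es, cs, sat, 1, seed = 1)
  expect_true(all(acc_sat$accept))

  # determinism and session independence of sub-streams
  a1 <- simulate_rater_decisions(es, cs, flat, 1, seed = 3)
  a1b <- simulate_rater_decisions(es, cs, flat, 1, seed = 3)
  a2 <- simulate_rater_decisions(es, cs, flat, 2, seed = 3)
  expect_identical(a1$accept, a1b$accept)
  expect_false(identical(a1$accept, a2$accept))

  expect_error(simulate_rater_decisions(es, cs[-1], flat, 1, 1),
               "one cosine similarity per epoch")
})

test_that("two-session match probability follows the squared logistic curve", {
  # Monte-Carlo estimate of P(accept at both of 2 sessions | CS) against
  # plogis(eta)^2 for a steep acceptance rule
  steep <- rater_profile("steep", 5, accept_intercept = -2,
                         accept_cs_slope = 6)
  cs_grid <- c(0.1, 0.4, 0.7)
  m <- matrix(rep(sin(seq_len(200)), 3), 3, byrow = TRUE)
  es <- make_toy_epochs(m, fs = 100, pre_s = 1)
  probs <- vapply(cs_grid, function(csv) {
    cs <- rep(csv, 3)
    hits <- vapply(1:400, function(s) {
      a1 <- simulate_rater_decisions(es, cs, steep, 1, seed = s)
      a2 <- simulate_rater_decisions(es, cs, steep, 2, seed = s)
      mean(a1$accept & a2$accept)
    }, numeric(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
  expect_equal(probs, plogis(-2 + 6 * cs_grid)^2, tolerance = 0.05)
})

test_that("rater labels add bias and noise to the automatic PN", {
  set.seed(12)
  m <- matrix(rnorm(5 * 2250), 5)
  m[, 1000] <- m[, 1000] - 30
  es <- make_toy_epochs(m)
  avg <- grand_average(es)
  auto <- label_pn(avg)

  exact <- rater_profile("ex", 5, pn_bias_ms = 0, pn_noise_sd_ms = 0)
  lab <- simulate_rater_label(avg, exact, 1, seed = 1)
  expect_equal(lab$pn_ms, auto$pn_ms)

  biased <- rater_profile("b", 5, pn_bias_ms = 25, pn_noise_sd_ms = 0)
  expect_equal(simulate_rater_label(avg, biased, 1, seed = 1)$pn_ms,
               auto$pn_ms + 25)

  noisy <- rater_profile("n", 5, pn_bias_ms = 0, pn_noise_sd_ms = 40)
  l1 <- simulate_rater_label(avg, noisy, 1, seed = 2)
  l2 <- simulate_rater_label(avg, noisy, 1, seed = 2)
  expect_identical(l1$pn_ms, l2$pn_ms)

  flat <- avg; flat$samples <- rep(1, length(avg$samples))
  expect_error(simulate_rater_label(flat, exact, 1, seed = 1), "no defined PN")
})

test_that("label variance components reproduce the theoretical ICC", {
  # var_dataset = 10000 ms^2, var_bias = 0, var_noise = 100 ms^2
  # => ICC = 10000 / 10100 ~= 0.990; the estimate's CI should cover it
  set.seed(31)
  one_study <- function() {
    truth <- rnorm(10, 0, 100)
    labels <- truth + matrix(rnorm(50, 0, 10), 10, 5)
    icc_a1(labels)
  }
  r <- one_study()
  expect_true(r$ci_low <= 10000 / 10100 && 10000 / 10100 <= r$ci_high)
  est <- replicate(300, one_study()$icc)
  expect_lt(abs(mean(est) - 10000 / 10100), 0.02)
})
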