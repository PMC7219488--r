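#' Condition-specific MRCP generative parameters
#'
#' Bundles the parameters controlling the morphology of simulated
#' movement-related cortical potentials (MRCPs) for one movement condition.
#' Amplitudes are in microvolts (negative for the peak negativity, PN), times
#' in milliseconds relative to the cue to move (negative = pre-cue).
#'
#' @param condition_id one of `"healthy_voluntary"`, `"healthy_imagined"`,
#'   `"stroke_voluntary"` (or any label for custom conditions).
#' @param pn_amplitude_mean mean PN amplitude, µV; must be negative.
#' @param pn_amplitude_sd between-dataset SD of PN amplitude, µV.
#' @param ramp_onset_ms onset of the negative ramp, ms before the cue
#'   (negative).
#' @param pn_latency_mean_ms mean PN latency, ms relative to cue.
#' @param pn_latency_between_sd_ms between-dataset SD of PN latency, ms. This
#'   is the "participant" variance component that reliability statistics
#'   resolve against rater error.
#' @param pn_latency_jitter_sd_ms epoch-to-epoch latency jitter SD, ms.
#' @param amp_scale_sd epoch-to-epoch relative amplitude jitter SD (unitless).
#' @param recovery_ms duration of the post-PN return toward baseline, ms.
#' @param pn_peak_width_ms half-width of the sharp negative peak riding on
#'   the slow ramp, ms; larger values give a blunter, less defined PN.
#' @param pn_peak_depth_frac fraction of the PN amplitude contributed by the
#'   sharp peak (the slow ramp carries the rest), in \[0, 1\].
#' @param background_noise_sd total background noise SD per sample, µV.
#' @param pink_noise_fraction fraction of noise variance carried by the
#'   1/f (pink) component, in \[0, 1\].
#' @param artefact_prob per-epoch probability of a large low-frequency
#'   artefact transient, in \[0, 1\].
#' @param artefact_amplitude artefact peak amplitude, µV.
#' @return A `condition_params` list.
#' @export
condition_params <- function(condition_id,
                             pn_amplitude_mean,
                             pn_amplitude_sd,
                             ramp_onset_ms,
                             pn_latency_mean_ms,
                             pn_latency_between_sd_ms,
                             pn_latency_jitter_sd_ms,
                             amp_scale_sd = 0.1,
                             recovery_ms = 1000,
                             pn_peak_width_ms = 200,
                             pn_peak_depth_frac = 0.3,
                             background_noise_sd,
                             pink_noise_fraction = 0.5,
                             artefact_prob = 0.05,
                             artefact_amplitude = 60) {
  stopifnot(
    pn_amplitude_mean < 0,
    pn_amplitude_sd >= 0,
    ramp_onset_ms < pn_latency_mean_ms,
    pn_latency_jitter_sd_ms >= 0,
    pn_latency_between_sd_ms >= 0,
    background_noise_sd >= 0,
    pn_peak_width_ms > 0,
    pn_peak_depth_frac >= 0, pn_peak_depth_frac <= 1,
    pink_noise_fraction >= 0, pink_noise_fraction <= 1,
    artefact_prob >= 0, artefact_prob <= 1
  )
  structure(
    list(
      condition_id = condition_id,
      pn_amplitude_mean = pn_amplitude_mean,
      pn_amplitude_sd = pn_amplitude_sd,
      ramp_onset_ms = ramp_onset_ms,
      pn_latency_mean_ms = pn_latency_mean_ms,
      pn_latency_between_sd_ms = pn_latency_between_sd_ms,
      pn_latency_jitter_sd_ms = pn_latency_jitter_sd_ms,
      amp_scale_sd = amp_scale_sd,
      recovery_ms = recovery_ms,
      pn_peak_width_ms = pn_peak_width_ms,
      pn_peak_depth_frac = pn_peak_depth_frac,
      background_noise_sd = background_noise_sd,
      pink_noise_fraction = pink_noise_fraction,
      artefact_prob = artefact_prob,
      artefact_amplitude = artefact_amplitude
    ),
    class = "condition_params"
  )
}

#' Default calibrated condition parameters
#'
#' The three study conditions: voluntary ankle dorsiflexion in healthy people
#' (`healthy_voluntary`), imagined dorsiflexion in healthy people
#' (`healthy_imagined`) and voluntary dorsiflexion in people with stroke
#' (`stroke_voluntary`). Defaults are calibrated so that the condition-wise
#' grand mean cosine similarity of simulated datasets lands at about
#' 0.39 / 0.27 / 0.41 respectively, reproducing the morphology contrast the
#' analysis pipeline is designed to resolve: imagined movement gives smaller,
#' less defined and more variable peak negativities; stroke gives longer
#' latencies and somewhat smaller amplitudes than healthy voluntary movement.
#'
#' @return Named list of [condition_params()] objects, one per condition.
#' @export
default_condition_params <- function() {
  list(
    healthy_voluntary = condition_params(
      condition_id = "healthy_voluntary",
      pn_amplitude_mean = -15, pn_amplitude_sd = 2,
      ramp_onset_ms = -1500,
      pn_latency_mean_ms = 100, pn_latency_between_sd_ms = 100,
      pn_latency_jitter_sd_ms = 60,
      pn_peak_width_ms = 200, pn_peak_depth_frac = 0.35,
      background_noise_sd = 12.1,
      artefact_prob = 0.04, artefact_amplitude = 60
    ),
    healthy_imagined = condition_params(
      condition_id = "healthy_imagined",
      pn_amplitude_mean = -8, pn_amplitude_sd = 1.5,
      ramp_onset_ms = -1500,
      pn_latency_mean_ms = 150, pn_latency_between_sd_ms = 120,
      pn_latency_jitter_sd_ms = 120,
      pn_peak_width_ms = 600, pn_peak_depth_frac = 0.15,
      background_noise_sd = 14.4,
      artefact_prob = 0.08, artefact_amplitude = 40
    ),
    stroke_voluntary = condition_params(
      condition_id = "stroke_voluntary",
      pn_amplitude_mean = -12, pn_amplitude_sd = 2,
      ramp_onset_ms = -1800,
      pn_latency_mean_ms = 250, pn_latency_between_sd_ms = 150,
      pn_latency_jitter_sd_ms = 80,
      pn_peak_width_ms = 250, pn_peak_depth_frac = 0.3,
      background_noise_sd = 10.6,
      artefact_prob = 0.06, artefact_amplitude = 50
    )
  )
}

#' Simulated-rater generative profile
#'
#' Parameters of one simulated EEG expert. Epoch acceptance follows a logistic
#' model in the epoch's cosine similarity (CS):
#' `P(accept) = plogis(accept_intercept + accept_cs_slope * CS)`, independent
#' across sessions given CS. PN labels are the automatically detected PN
#' latency plus a rater-specific systematic bias and zero-mean Gaussian noise.
#'
#' @param rater_id rater label.
#' @param experience_years self-reported years of MRCP experience.
#' @param accept_intercept log-odds of acceptance at CS = 0. Either a single
#'   number or a named vector keyed by condition.
#' @param accept_cs_slope log-odds increase per unit CS; single number or a
#'   named vector keyed by condition.
#' @param pn_bias_ms systematic labelling bias, ms.
#' @param pn_noise_sd_ms SD of labelling noise, ms (>= 0).
#' @return A `rater_profile` list.
#' @export
rater_profile <- function(rater_id, experience_years,
                          accept_intercept = -1.5, accept_cs_slope = 4,
                          pn_bias_ms = 0, pn_noise_sd_ms = 30) {
  stopifnot(pn_noise_sd_ms >= 0, experience_years >= 0)
  structure(
    list(
      rater_id = rater_id, experience_years = experience_years,
      accept_intercept = accept_intercept, accept_cs_slope = accept_cs_slope,
      pn_bias_ms = pn_bias_ms, pn_noise_sd_ms = pn_noise_sd_ms
    ),
    class = "rater_profile"
  )
}

#' Default panel of five simulated raters
#'
#' Five raters with experience 1.5--8 years (mean 4.7), modest rater-specific
#' PN biases and labelling noise, and acceptance behaviour increasing in
#' cosine similarity.
#'
#' @param pn_noise_sd_ms labelling noise SD applied to every rater, ms.
#' @param pn_bias_sd_ms SD of the fixed per-rater biases, ms (the five biases
#'   are fixed quantiles of this spread, not random draws).
#' @return List of five [rater_profile()] objects.
#' @export
default_rater_profiles <- function(pn_noise_sd_ms = 30, pn_bias_sd_ms = 15) {
  experience <- c(1.5, 3, 5, 6, 8)
  # symmetric, zero-mean fixed biases with SD ~ pn_bias_sd_ms
  bias <- pn_bias_sd_ms * c(-1.264, -0.526, 0, 0.526, 1.264)
  # condition-specific acceptance behaviour: steep CS dependence for clear
  # voluntary MRCPs, shallow for the faint imagined ones; intercepts keep
  # the accept rate near one half at each condition's typical CS
  slope <- c(healthy_voluntary = 4.7, healthy_imagined = 1.3,
             stroke_voluntary = 2.6)
  icpt <- c(healthy_voluntary = -1.85, healthy_imagined = -0.35,
            stroke_voluntary = -1.05)
  lapply(seq_along(experience), function(i) {
    rater_profile(
      rater_id = paste0("E", i),
      experience_years = experience[i],
      accept_intercept = icpt,
      accept_cs_slope = slope,
      pn_bias_ms = bias[i],
      pn_noise_sd_ms = pn_noise_sd_ms
    )
  })
}

#' Study-level simulation configuration
#'
#' Defaults mirror the evaluation protocol the pipeline targets: 10 datasets
#' per condition, 50 epochs per dataset, 500 Hz sampling, 4.5 s epochs (3 s
#' pre-cue, 1.5 s post-cue), 5 raters, 3 evaluation sessions.
#'
#' @param n_datasets_per_condition datasets per condition.
#' @param n_epochs epochs per dataset.
#' @param fs sampling rate, Hz.
#' @param pre_s pre-cue window, s.
#' @param post_s post-cue window, s.
#' @param n_sessions number of evaluation sessions.
#' @param seed master seed; all sub-streams derive from it.
#' @param condition_params named list of [condition_params()]; defaults to
#'   [default_condition_params()].
#' @param rater_profiles list of [rater_profile()]; defaults to
#'   [default_rater_profiles()].
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_datasets_per_condition = 10,
                              n_epochs = 50,
                              fs = 500,
                              pre_s = 3,
                              post_s = 1.5,
                              n_sessions = 3,
                              seed = 1,
                              condition_params = default_condition_params(),
                              rater_profiles = default_rater_profiles()) {
  stopifnot(fs > 0, pre_s > 0, post_s > 0, n_epochs >= 1,
            n_datasets_per_condition >= 1)
  structure(
    list(
      n_datasets_per_condition = n_datasets_per_condition,
      n_epochs = n_epochs, fs = fs, pre_s = pre_s, post_s = post_s,
      n_raters = length(rater_profiles), n_sessions = n_sessions,
      seed = seed, condition_params = condition_params,
      rater_profiles = rater_profiles
    ),
    class = "simulation_config"
  )
}
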