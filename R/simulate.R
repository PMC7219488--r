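#' 1/f (pink) background noise
#'
#' Spectral-synthesis pink noise: Fourier amplitudes proportional to
#' 1/sqrt(f) with uniform random phases, inverse-transformed and standardised
#' to zero mean and unit SD. Draws from the current RNG stream.
#'
#' @param n number of samples.
#' @return Numeric vector of length `n` with mean 0 and SD 1.
#' @keywords internal
pink_noise <- function(n) {
  stopifnot(n >= 4)
  nf <- n %/% 2
  amp <- 1 / sqrt(seq_len(nf))
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[1 + seq_len(nf)] <- spec
  if (n %% 2 == 0) {
    # Nyquist bin must be real
    full[nf + 1] <- complex(real = amp[nf] * cos(phase[nf]))
    full[n - seq_len(nf - 1) + 1] <- Conj(spec[seq_len(nf - 1)])
  } else {
    full[n - seq_len(nf) + 1] <- Conj(spec[seq_len(nf)])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' Simulate one MRCP epoch from a dataset template
#'
#' Applies epoch-to-epoch variability to the dataset's template — relative
#' amplitude scaling and latency jitter — then adds a mixture of white and
#' pink background noise and, with probability `artefact_prob`, a large
#' low-frequency artefact transient (a broad negative Gaussian bump, as a
#' blink or movement artefact would appear in the 0.05--5 Hz band). Draws
#' from the current RNG stream.
#'
#' @param template an [make_template()] object.
#' @param params the matching [condition_params()].
#' @return List with `samples` (µV) and `artefact` (logical ground-truth
#'   flag).
#' @export
simulate_epoch <- function(template, params) {
  stopifnot(inherits(template, "mrcp_template"),
            inherits(params, "condition_params"))
  n <- length(template$samples)
  fs <- template$fs

  scale <- max(stats::rnorm(1, 1, params$amp_scale_sd), 0.1)
  jit_ms <- stats::rnorm(1, 0, params$pn_latency_jitter_sd_ms)
  shift <- as.integer(round(jit_ms * fs / 1000))
  y <- template$samples * scale
  if (shift > 0) {
    y <- c(numeric(shift), y[seq_len(n - shift)])
  } else if (shift < 0) {
    y <- c(y[(1 - shift):n], numeric(-shift))
  }

  sdn <- params$background_noise_sd
  if (sdn > 0) {
    f <- params$pink_noise_fraction
    noise <- numeric(n)
    if (f < 1) noise <- noise + sqrt(1 - f) * stats::rnorm(n)
    if (f > 0) noise <- noise + sqrt(f) * pink_noise(n)
    # epochs emulate the post-preprocessing virtual channel, so the
    # background noise carries the same 0.05-5 Hz band limitation
    noise <- butterworth_bandpass(noise, fs)
    noise <- (noise - mean(noise)) / stats::sd(noise)
    y <- y + sdn * noise
  }

  artefact <- stats::runif(1) < params$artefact_prob
  if (artefact) {
    centre <- stats::runif(1, 0, n - 1)
    width <- 0.3 * fs  # 300 ms SD: survives the 0.05-5 Hz band-pass
    bump <- -params$artefact_amplitude *
      exp(-((seq_len(n) - 1 - centre)^2) / (2 * width^2))
    y <- y + bump
  }
  list(samples = y, artefact = artefact)
}

#' Simulate one dataset of cue-locked MRCP epochs
#'
#' Generates a dataset (one simulated participant x condition recording) on
#' its own RNG sub-stream derived from `config$seed`, so datasets are
#' reproducible individually and unaffected by how many raters or other
#' datasets are simulated.
#'
#' @param condition condition name; must be present in
#'   `config$condition_params`.
#' @param participant_id integer id within the condition.
#' @param config a [simulation_config()].
#' @return An `epoch_set`: list with `dataset_id`, `condition`, `epochs`
#'   (n_epochs x n_samples matrix, µV), `fs`, `cue_index`, `time_ms` and a
#'   `ground_truth` list (template, true PN latency/amplitude, per-epoch
#'   artefact flags).
#' @export
simulate_dataset <- function(condition, participant_id, config) {
  stopifnot(inherits(config, "simulation_config"))
  params <- config$condition_params[[condition]]
  if (is.null(params)) stop("unknown condition: ", condition)
  seed_d <- substream_seed(config$seed, "dataset", condition, participant_id)
  with_substream(seed_d, {
    template <- make_template(params, config$fs, config$pre_s, config$post_s)
    eps <- lapply(seq_len(config$n_epochs), function(i)
      simulate_epoch(template, params))
    epochs <- do.call(rbind, lapply(eps, `[[`, "samples"))
    structure(
      list(
        dataset_id = sprintf("%s_%02d", condition, participant_id),
        condition = condition,
        epochs = epochs,
        fs = config$fs,
        cue_index = template$cue_index,
        time_ms = template$time_ms,
        ground_truth = list(
          template = template,
          true_pn_ms = template$true_pn_ms,
          true_pn_amplitude = template$true_pn_amplitude,
          artefact = vapply(eps, `[[`, logical(1), "artefact")
        )
      ),
      class = "epoch_set"
    )
  })
}

#' Simulate the full study's datasets
#'
#' @param config a [simulation_config()].
#' @param conditions conditions to simulate; default all configured.
#' @return List of [simulate_dataset()] `epoch_set`s.
#' @export
simulate_study <- function(config, conditions = names(config$condition_params)) {
  sets <- list()
  for (cond in conditions) {
    for (p in seq_len(config$n_datasets_per_condition)) {
      sets[[length(sets) + 1L]] <- simulate_dataset(cond, p, config)
    }
  }
  sets
}

#' Simulate a continuous multi-channel recording with cue times
#'
#' A thin multi-channel wrapper for exercising the preprocessing chain: a
#' 10-channel 10--20 montage (F3, Fz, F4, C3, Cz, C4, P3, Pz, P4, FP1) in
#' which the MRCP template is injected around each cue, at full gain on Cz
#' and reduced gain on surrounding electrodes, plus per-channel white noise.
#' Inter-trial timing follows the cued-movement protocol: per repetition a
#' focus period of 2--3 s precedes the cue and a rest of 6--8 s follows it,
#' both drawn uniformly.
#'
#' @param condition condition name.
#' @param config a [simulation_config()].
#' @param participant_id integer id (selects the RNG sub-stream).
#' @return List with `recording` (list: `channel_names`, `data` channels x
#'   samples µV, `fs`, `start_time`) and `cue_times` (s, strictly
#'   increasing).
#' @export
simulate_continuous <- function(condition, config, participant_id = 1) {
  stopifnot(inherits(config, "simulation_config"))
  params <- config$condition_params[[condition]]
  if (is.null(params)) stop("unknown condition: ", condition)
  stopifnot(config$n_epochs >= 1)
  seed_c <- substream_seed(config$seed, "continuous", condition, participant_id)
  with_substream(seed_c, {
    fs <- config$fs
    n_tr <- config$n_epochs
    focus <- stats::runif(n_tr, 2, 3)
    rest <- stats::runif(n_tr, 6, 8)
    cue_times <- numeric(n_tr)
    cue_times[1] <- config$pre_s + focus[1]
    if (n_tr > 1) {
      for (k in 2:n_tr) cue_times[k] <- cue_times[k - 1] + rest[k - 1] + focus[k]
    }
    total_s <- cue_times[n_tr] + config$post_s + rest[n_tr]
    n <- ceiling(total_s * fs)

    channels <- c("F3", "Fz", "F4", "C3", "Cz", "C4", "P3", "Pz", "P4", "FP1")
    gain <- c(F3 = 0.15, Fz = 0.3, F4 = 0.15, C3 = 0.3, Cz = 1, C4 = 0.3,
              P3 = 0.15, Pz = 0.3, P4 = 0.15, FP1 = 0)
    template <- make_template(params, fs, config$pre_s, config$post_s)

    data <- matrix(0, nrow = length(channels), ncol = n,
                   dimnames = list(channels, NULL))
    if (params$background_noise_sd > 0) {
      data[] <- stats::rnorm(length(data), 0, params$background_noise_sd)
    }
    len <- length(template$samples)
    for (ct in cue_times) {
      start <- round(ct * fs) - template$cue_index + 1L
      idx <- start:(start + len - 1L)
      data[, idx] <- data[, idx] +
        outer(gain[channels], template$samples)
    }
    list(
      recording = list(channel_names = channels, data = data, fs = fs,
                       start_time = 0),
      cue_times = cue_times,
      ground_truth = list(template = template)
    )
  })
}

resolve_by_condition <- function(x, condition) {
  if (length(x) == 1L && is.null(names(x))) return(unname(x))
  if (!condition %in% names(x)) {
    stop("no value for condition '", condition, "'")
  }
  unname(x[[condition]])
}

#' Simulate one rater's accept/reject decisions for a dataset at one session
#'
#' Acceptance is Bernoulli with
#' `P(accept) = plogis(accept_intercept + accept_cs_slope * CS)`, independent
#' across sessions given the epoch's cosine similarity (the rater has no
#' memory between sessions). Runs on a sub-stream keyed by (dataset, rater,
#' session).
#'
#' @param epochs an `epoch_set`.
#' @param cs numeric vector of per-epoch cosine similarities (one per epoch),
#'   e.g. `similarity_table(epochs)$cs`.
#' @param profile a [rater_profile()].
#' @param session session index.
#' @param seed master seed for the sub-stream (typically `config$seed`).
#' @return Data frame: `dataset_id`, `condition`, `rater_id`, `session`,
#'   `epoch_index` (1-based), `cs`, `accept` (logical).
#' @export
simulate_rater_decisions <- function(epochs, cs, profile, session, seed) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(profile, "rater_profile"))
  if (length(cs) != nrow(epochs$epochs)) {
    stop("need one cosine similarity per epoch")
  }
  icpt <- resolve_by_condition(profile$accept_intercept, epochs$condition)
  slope <- resolve_by_condition(profile$accept_cs_slope, epochs$condition)
  s <- substream_seed(seed, "decide", epochs$dataset_id, profile$rater_id,
                      session)
  accept <- with_substream(s, {
    stats::runif(length(cs)) < stats::plogis(icpt + slope * cs)
  })
  data.frame(
    dataset_id = epochs$dataset_id, condition = epochs$condition,
    rater_id = profile$rater_id, session = session,
    experience = profile$experience_years,
    epoch_index = seq_along(cs), cs = cs, accept = accept,
    stringsAsFactors = FALSE
  )
}

#' Simulate one rater's PN label for an average MRCP
#'
#' The label is the automatically detected PN latency of the average plus the
#' rater's systematic bias and zero-mean Gaussian labelling noise. With all
#' rater biases and noises expressed as variances, the expected ICC of labels
#' across raters is `var_dataset / (var_dataset + var_bias + var_noise)`,
#' where `var_dataset` is the between-dataset variance of the true PN
#' latency.
#'
#' @param avg an `average_mrcp` from [average_included()].
#' @param profile a [rater_profile()].
#' @param session session index.
#' @param seed master seed for the sub-stream.
#' @param window_ms PN search window passed to [label_pn()].
#' @return Data frame row: `dataset_id`, `rater_id`, `session`, `pn_ms`,
#'   `pn_amplitude`.
#' @export
simulate_rater_label <- function(avg, profile, session, seed,
                                 window_ms = c(-2000, 1500)) {
  stopifnot(inherits(profile, "rater_profile"))
  auto <- label_pn(avg, window_ms)
  s <- substream_seed(seed, "label", avg$dataset_id, profile$rater_id, session)
  pn <- with_substream(s, {
    auto$pn_ms + profile$pn_bias_ms + stats::rnorm(1, 0, profile$pn_noise_sd_ms)
  })
  data.frame(
    dataset_id = avg$dataset_id, rater_id = profile$rater_id,
    session = session, pn_ms = pn, pn_amplitude = auto$pn_amplitude,
    stringsAsFactors = FALSE
  )
}

#' Run the full simulated evaluation protocol over a study
#'
#' For every dataset, every rater and every session: compute the cosine
#' similarity table, draw accept/reject decisions, average the epochs that
#' rater included at that session, and draw the rater's PN label from their
#' own average. Mirrors the expert evaluation protocol end to end.
#'
#' @param study list of `epoch_set`s from [simulate_study()].
#' @param config the [simulation_config()] used to build the study.
#' @return List with `similarity` (per-epoch CS records), `acceptance`
#'   (decision records) and `labels` (PN label records, with `condition`).
#' @export
simulate_evaluations <- function(study, config) {
  stopifnot(inherits(config, "simulation_config"))
  sim_tabs <- list(); acc_tabs <- list(); lab_tabs <- list()
  for (es in study) {
    st <- similarity_table(es)
    sim_tabs[[length(sim_tabs) + 1L]] <- st
    for (profile in config$rater_profiles) {
      for (sess in seq_len(config$n_sessions)) {
        acc <- simulate_rater_decisions(es, st$cs, profile, sess, config$seed)
        acc_tabs[[length(acc_tabs) + 1L]] <- acc
        avg <- average_included(es, acc)
        lab <- simulate_rater_label(avg, profile, sess, config$seed)
        lab$condition <- es$condition
        lab$n_included <- avg$n_included
        lab_tabs[[length(lab_tabs) + 1L]] <- lab
      }
    }
  }
  list(
    similarity = do.call(rbind, sim_tabs),
    acceptance = do.call(rbind, acc_tabs),
    labels = do.call(rbind, lab_tabs)
  )
}
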