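#' Build a dataset-level MRCP template waveform
#'
#' Draws the dataset's PN amplitude and latency from the condition
#' distributions (using the current RNG stream) and constructs the noise-free
#' MRCP waveform: flat baseline at 0 µV, a smooth cosine ramp descending from
#' the ramp onset to the peak negativity, and a cosine recovery back toward
#' baseline. The slow ramp-plus-recovery spans roughly two seconds, giving the
#' waveform its characteristic ~0.5 Hz content. The drawn latency is snapped
#' to the sample grid so the waveform minimum equals the drawn amplitude
#' exactly at the PN sample.
#'
#' @param params a [condition_params()] object.
#' @param fs sampling rate, Hz.
#' @param pre_s seconds before the cue.
#' @param post_s seconds after the cue.
#' @return An `mrcp_template`: list with `samples` (µV), `fs`, `cue_index`
#'   (number of pre-cue samples), `time_ms`, `true_pn_index` (0-based),
#'   `true_pn_ms`, `true_pn_amplitude`.
#' @export
make_template <- function(params, fs = 500, pre_s = 3, post_s = 1.5) {
  stopifnot(inherits(params, "condition_params"), fs > 0)
  if (pre_s * 1000 < abs(params$ramp_onset_ms)) {
    stop("ramp onset precedes the epoch window: increase pre_s")
  }
  n <- round((pre_s + post_s) * fs)
  cue_index <- round(pre_s * fs)
  time_ms <- (seq_len(n) - 1 - cue_index) / fs * 1000

  amp <- min(stats::rnorm(1, params$pn_amplitude_mean, params$pn_amplitude_sd),
             -0.5)
  lat <- stats::rnorm(1, params$pn_latency_mean_ms,
                      params$pn_latency_between_sd_ms)
  # snap latency to the sample grid so the minimum is attained exactly
  lat <- round(lat * fs / 1000) / fs * 1000
  if (lat <= params$ramp_onset_ms || lat >= post_s * 1000) {
    stop(sprintf("drawn PN latency %.0f ms falls outside (%g, %g) ms",
                 lat, params$ramp_onset_ms, post_s * 1000))
  }

  onset <- params$ramp_onset_ms
  rec <- params$recovery_ms
  # slow negativity carries (1 - depth_frac) of the amplitude; a sharp peak
  # of half-width pn_peak_width_ms centred on the PN latency carries the rest
  # and makes the PN well localised (blunt when the width is large)
  depth <- params$pn_peak_depth_frac
  w <- min(params$pn_peak_width_ms, lat - onset, rec)
  broad <- amp * (1 - depth)
  y <- numeric(n)
  ramp <- time_ms >= onset & time_ms <= lat
  y[ramp] <- broad * (1 - cos(pi * (time_ms[ramp] - onset) / (lat - onset))) / 2
  recov <- time_ms > lat & time_ms <= lat + rec
  y[recov] <- broad * (1 + cos(pi * (time_ms[recov] - lat) / rec)) / 2
  if (depth > 0) {
    pk <- abs(time_ms - lat) <= w
    y[pk] <- y[pk] + amp * depth * (1 + cos(pi * (time_ms[pk] - lat) / w)) / 2
  }

  pn_index <- which(time_ms == lat) - 1L  # 0-based
  structure(
    list(samples = y, fs = fs, cue_index = cue_index, time_ms = time_ms,
         true_pn_index = pn_index, true_pn_ms = lat, true_pn_amplitude = amp,
         params = params),
    class = "mrcp_template"
  )
}
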