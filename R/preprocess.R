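#' Band-pass filter specification
#'
#' Defaults match the MRCP processing chain: 0.05--5 Hz second-order
#' Butterworth, applied forward and backward (zero phase, magnitude response
#' |H(f)|^2).
#'
#' @param low_hz lower band edge, Hz.
#' @param high_hz upper band edge, Hz.
#' @param order Butterworth design order (per band edge).
#' @param zero_phase apply forward--backward filtering.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_hz = 0.05, high_hz = 5, order = 2,
                        zero_phase = TRUE) {
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 zero_phase = zero_phase), class = "filter_spec")
}

# single IIR pass initialised to the steady state for a constant input equal
# to the first sample, so a constant signal yields the filter's DC gain
# exactly (zero for a band-pass) with no start-up transient
iir_pass <- function(b, a, x) {
  nc <- max(length(a), length(b))
  h0 <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], nc - 1),
                            init.y = rep(h0 * x[1], nc - 1)))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass (coefficients via [signal::butter()]) and
#' applies it forward and backward for zero phase distortion; the effective
#' magnitude response is |H(f)|^2. Edge transients are suppressed by odd
#' (point-reflected) signal extension of length 3 x (polynomial order + 1)
#' samples at each end together with steady-state filter initialisation.
#'
#' @param x numeric signal vector, µV.
#' @param fs sampling rate, Hz.
#' @param spec a [filter_spec()].
#' @return Filtered vector, same length as `x`.
#' @export
butterworth_bandpass <- function(x, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"), fs > 0)
  if (!(spec$low_hz > 0 && spec$low_hz < spec$high_hz &&
        spec$high_hz < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  b <- bf$b; a <- bf$a
  nmin <- 3 * max(length(a), length(b))
  if (length(x) <= nmin) {
    stop("signal too short for the filter's edge padding (need > ",
         nmin, " samples)")
  }
  # pad to ~3 time constants of the slowest (low-edge) mode so its start-up
  # transient has decayed before the signal proper begins
  npad <- max(nmin, min((length(x) - 1) %/% 2,
                        ceiling(3 * fs / (2 * pi * spec$low_hz))))
  # odd extension about the end points
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - npad)]
  xp <- c(pre, x, post)
  y <- iir_pass(b, a, xp)
  if (spec$zero_phase) {
    y <- rev(iir_pass(b, a, rev(y)))
  }
  y[(npad + 1):(npad + length(x))]
}

#' Large Laplacian spatial filter
#'
#' Computes a single virtual channel as the centre electrode minus the mean
#' of its surrounding electrodes. With the sparse 10--20 montage recorded,
#' the surrounding set for Cz is Fz, Pz, C3 and C4, weighted uniformly;
#' common-mode activity present on all electrodes cancels exactly.
#'
#' @param rec continuous recording: list with `channel_names` and `data`
#'   (channels x samples matrix, µV).
#' @param centre centre electrode name.
#' @param neighbours surrounding electrode names.
#' @return Numeric vector: the virtual channel, µV.
#' @export
large_laplacian <- function(rec, centre = "Cz",
                            neighbours = c("Fz", "Pz", "C3", "C4")) {
  missing <- setdiff(c(centre, neighbours), rec$channel_names)
  if (length(missing) > 0) {
    stop("channel(s) not in recording: ", paste(missing, collapse = ", "))
  }
  idx <- match(neighbours, rec$channel_names)
  rec$data[match(centre, rec$channel_names), ] -
    colMeans(rec$data[idx, , drop = FALSE])
}

# round half away from zero (commercial rounding), used for cue time -> sample
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

#' Extract cue-locked epochs from a virtual channel
#'
#' Cuts one fixed-length epoch per cue: `pre_s` seconds before to `post_s`
#' seconds after the cue. Sample indexing is 0-based with half-open intervals:
#' epoch k covers samples `[c_k - pre_s*fs, c_k + post_s*fs)` where
#' `c_k = round(cue_time * fs)` (round half away from zero), and the cue sits
#' at within-epoch index `pre_s * fs` (1500 under the default 500 Hz / 3 s
#' protocol).
#'
#' @param virtual numeric vector, the virtual channel, µV.
#' @param fs sampling rate, Hz.
#' @param cue_times cue onsets, seconds from recording start.
#' @param pre_s seconds before each cue.
#' @param post_s seconds after each cue.
#' @param dataset_id,condition optional metadata carried on the result.
#' @return An `epoch_set` (see [simulate_dataset()] for fields).
#' @export
extract_epochs <- function(virtual, fs, cue_times, pre_s = 3, post_s = 1.5,
                           dataset_id = "dataset", condition = NA_character_) {
  stopifnot(fs > 0, length(cue_times) >= 1)
  npre <- round(pre_s * fs)
  npost <- round(post_s * fs)
  n <- length(virtual)
  cue_samples <- round_half_away(cue_times * fs)
  bad <- cue_samples - npre < 0 | cue_samples + npost > n
  if (any(bad)) {
    stop("cue(s) too close to a recording edge (s): ",
         paste(format(cue_times[bad]), collapse = ", "))
  }
  epochs <- t(vapply(cue_samples, function(cs) {
    virtual[(cs - npre + 1):(cs + npost)]
  }, numeric(npre + npost)))
  structure(
    list(
      dataset_id = dataset_id, condition = condition, epochs = epochs,
      fs = fs, cue_index = npre,
      time_ms = (seq_len(npre + npost) - 1 - npre) / fs * 1000
    ),
    class = "epoch_set"
  )
}

#' Preprocess a continuous recording into an epoch set
#'
#' The full chain: band-pass each channel, spatially filter to the Cz-centred
#' virtual channel, and extract cue-locked epochs.
#'
#' @param rec continuous recording (list with `channel_names`, `data`, `fs`).
#' @param cue_times cue onsets, s.
#' @param spec a [filter_spec()].
#' @param centre,neighbours Laplacian electrodes.
#' @param pre_s,post_s epoch window, s.
#' @param dataset_id,condition metadata for the resulting epoch set.
#' @return An `epoch_set`.
#' @export
preprocess_recording <- function(rec, cue_times, spec = filter_spec(),
                                 centre = "Cz",
                                 neighbours = c("Fz", "Pz", "C3", "C4"),
                                 pre_s = 3, post_s = 1.5,
                                 dataset_id = "dataset",
                                 condition = NA_character_) {
  filtered <- rec
  filtered$data <- t(apply(rec$data, 1, butterworth_bandpass, fs = rec$fs,
                           spec = spec))
  virtual <- large_laplacian(filtered, centre, neighbours)
  extract_epochs(virtual, rec$fs, cue_times, pre_s, post_s,
                 dataset_id = dataset_id, condition = condition)
}

#' Read a continuous recording from delimited text
#'
#' Expects a delimited matrix whose first row holds channel names, one column
#' per channel, one row per sample (µV). The sampling rate is not part of the
#' matrix and must be supplied.
#'
#' @param path file path.
#' @param fs sampling rate, Hz.
#' @param sep field separator.
#' @return Continuous recording list (`channel_names`, `data`, `fs`,
#'   `start_time`).
#' @export
read_continuous_text <- function(path, fs, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  list(channel_names = colnames(df), data = t(as.matrix(df)), fs = fs,
       start_time = 0)
}

#' Write / read an epoch set as delimited text plus JSON metadata
#'
#' The epoch matrix (rows = epochs) goes to `<path>`; sampling rate, cue
#' index, condition and dataset id go to `<path>.json`.
#'
#' @param es an `epoch_set`.
#' @param path output path for the matrix.
#' @param sep field separator.
#' @return `path`, invisibly (`write_epochs`); an `epoch_set`
#'   (`read_epochs`).
#' @export
write_epochs <- function(es, path, sep = "\t") {
  utils::write.table(es$epochs, path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  meta <- list(dataset_id = es$dataset_id, condition = es$condition,
               fs = es$fs, cue_index = es$cue_index)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path, sep = "\t") {
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
  dimnames(m) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- ncol(m)
  structure(
    list(dataset_id = meta$dataset_id, condition = meta$condition,
         epochs = m, fs = meta$fs, cue_index = meta$cue_index,
         time_ms = (seq_len(n) - 1 - meta$cue_index) / meta$fs * 1000),
    class = "epoch_set"
  )
}
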