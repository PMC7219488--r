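#' Cosine similarity index
#'
#' `dot(u, v) / (||u|| ||v||)` with L2 norms; the morphology-agreement score
#' between an epoch and a reference waveform, in \[-1, 1\].
#'
#' @param u,v numeric vectors of equal length, both with non-zero norm.
#' @return A number in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("u and v must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero-norm input")
  max(-1, min(1, sum(u * v) / (nu * nv)))
}

#' Per-epoch cosine similarity against the dataset average
#'
#' For every epoch: cosine similarity between that epoch and the average of
#' ALL epochs in the dataset (not any accepted subset) — the dataset average
#' stands in for the expected MRCP morphology. Zero-norm epochs are flagged
#' invalid (`cs = NA`) with a warning and are meant to be excluded downstream.
#'
#' @param epochs an `epoch_set` with at least 2 epochs.
#' @return Data frame: `dataset_id`, `condition`, `epoch_index` (1-based),
#'   `cs`, `valid`.
#' @export
similarity_table <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  m <- epochs$epochs
  if (nrow(m) < 2) stop("need at least 2 epochs")
  u <- colMeans(m)
  if (sqrt(sum(u^2)) == 0) stop("grand average has zero norm")
  norms <- sqrt(rowSums(m^2))
  valid <- norms > 0
  cs <- rep(NA_real_, nrow(m))
  cs[valid] <- pmax(-1, pmin(1, (m[valid, , drop = FALSE] %*% u) /
                               (norms[valid] * sqrt(sum(u^2)))))
  if (any(!valid)) {
    warning(sum(!valid), " zero-norm epoch(s) flagged invalid in ",
            epochs$dataset_id)
  }
  data.frame(
    dataset_id = epochs$dataset_id, condition = epochs$condition,
    epoch_index = seq_len(nrow(m)), cs = cs, valid = valid,
    stringsAsFactors = FALSE
  )
}

#' Average the epochs a rater included
#'
#' Element-wise mean over the accepted epochs of one (rater, session)
#' acceptance record — the average MRCP the rater labels.
#'
#' @param epochs an `epoch_set`.
#' @param acc acceptance records for this dataset: data frame with
#'   `epoch_index` and logical `accept` (one row per epoch).
#' @return An `average_mrcp`: list with `dataset_id`, `samples` (µV),
#'   `n_included`, `fs`, `cue_index`, `time_ms`.
#' @export
average_included <- function(epochs, acc) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- acc$epoch_index[acc$accept]
  if (length(keep) == 0) stop("no epochs included")
  structure(
    list(
      dataset_id = epochs$dataset_id,
      samples = colMeans(epochs$epochs[keep, , drop = FALSE]),
      n_included = length(keep), fs = epochs$fs,
      cue_index = epochs$cue_index, time_ms = epochs$time_ms
    ),
    class = "average_mrcp"
  )
}

#' Grand average over all epochs
#'
#' @param epochs an `epoch_set`.
#' @return An `average_mrcp` over every epoch.
#' @export
grand_average <- function(epochs) {
  acc <- data.frame(epoch_index = seq_len(nrow(epochs$epochs)), accept = TRUE)
  average_included(epochs, acc)
}

#' Locate the peak negativity of an average MRCP
#'
#' The PN is the most negative sample of the average within the search
#' window; ties resolve to the earliest sample. Latency is reported in ms
#' relative to the cue (negative = pre-cue). The default window, -2000 to
#' +1500 ms, covers the full plausible MRCP time course (the negative ramp
#' begins about 1.5--2 s before movement).
#'
#' @param avg an `average_mrcp`.
#' @param window_ms `c(lo, hi)` search window, ms relative to cue.
#' @return A `pn_label`: list with `dataset_id`, `pn_ms`, `pn_amplitude`
#'   (µV), `pn_index` (0-based sample index within the epoch).
#' @export
label_pn <- function(avg, window_ms = c(-2000, 1500)) {
  stopifnot(inherits(avg, "average_mrcp"), length(window_ms) == 2)
  sel <- which(avg$time_ms >= window_ms[1] & avg$time_ms <= window_ms[2])
  if (length(sel) == 0) stop("PN window outside the epoch time axis")
  y <- avg$samples[sel]
  if (diff(range(y)) == 0) stop("constant signal in window: no defined PN")
  i <- sel[which.min(y)]
  structure(
    list(dataset_id = avg$dataset_id, pn_ms = avg$time_ms[i],
         pn_amplitude = avg$samples[i], pn_index = i - 1L),
    class = "pn_label"
  )
}

#' Matched-epoch indicator table
#'
#' An epoch is "matched" either intra-rater — the same rater accepted it at
#' two named sessions — or inter-rater — every rater accepted it at one named
#' session. Reject--reject pairs are NOT matched: matching is defined through
#' acceptance only.
#'
#' @param acceptances data frame of decisions (`dataset_id`, `rater_id`,
#'   `session`, `epoch_index`, `accept`), covering every required
#'   (rater, session, epoch).
#' @param mode `list(type = "intra", rater, s1, s2)` or
#'   `list(type = "inter", session)`.
#' @return Data frame: `dataset_id`, `epoch_index`, `comparison`, `matched`.
#' @export
matched_table <- function(acceptances, mode) {
  stopifnot(is.list(mode), mode$type %in% c("intra", "inter"))
  a <- acceptances
  if (mode$type == "intra") {
    s1 <- a[a$rater_id == mode$rater & a$session == mode$s1, ]
    s2 <- a[a$rater_id == mode$rater & a$session == mode$s2, ]
    key1 <- paste(s1$dataset_id, s1$epoch_index)
    key2 <- paste(s2$dataset_id, s2$epoch_index)
    if (!setequal(key1, key2) || anyDuplicated(key1) || anyDuplicated(key2)) {
      stop(sprintf("incomplete decisions for rater %s at sessions %d/%d",
                   mode$rater, mode$s1, mode$s2))
    }
    s2 <- s2[match(key1, key2), ]
    data.frame(
      dataset_id = s1$dataset_id, epoch_index = s1$epoch_index,
      comparison = sprintf("intra_%s_s%d_s%d", mode$rater, mode$s1, mode$s2),
      matched = s1$accept & s2$accept, stringsAsFactors = FALSE
    )
  } else {
    s <- a[a$session == mode$session, ]
    raters <- unique(a$rater_id)
    counts <- stats::aggregate(
      cbind(n_dec = rep(1L, nrow(s)), n_acc = as.integer(s$accept)) ~
        dataset_id + epoch_index, data = s, FUN = sum
    )
    if (any(counts$n_dec != length(raters))) {
      bad <- counts[counts$n_dec != length(raters), ][1, ]
      stop(sprintf(
        "missing decision(s) at session %d for dataset %s epoch %d",
        mode$session, bad$dataset_id, bad$epoch_index))
    }
    data.frame(
      dataset_id = counts$dataset_id, epoch_index = counts$epoch_index,
      comparison = sprintf("inter_s%d", mode$session),
      matched = counts$n_acc == length(raters), stringsAsFactors = FALSE
    )
  }
}
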