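#' Deterministic sub-stream seeds
#'
#' Derives a reproducible child seed from a master seed and an arbitrary
#' key path (condition, dataset, rater, session, ...). Every stochastic
#' operation in the package draws from a sub-stream keyed by the entities it
#' concerns, so e.g. adding raters to a study leaves the dataset noise
#' untouched.
#'
#' @param seed master integer seed.
#' @param ... key components (coerced to character) identifying the entity.
#' @return An integer in \[0, 2^31 - 2\] suitable for [set.seed()].
#' @examples
#' substream_seed(1, "dataset", "healthy_voluntary", 3)
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  # 31-bit polynomial rolling hash; stable across platforms
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Evaluate an expression under a private RNG sub-stream
#'
#' Sets the RNG to `seed` for the duration of `expr` and restores the caller's
#' RNG state afterwards, so package internals never perturb the user's stream.
#'
#' @param seed integer seed for the sub-stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_substream <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
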