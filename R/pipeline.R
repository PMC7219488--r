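#' Run the end-to-end reliability pipeline
#'
#' Executes the requested stages in order — `simulate` (datasets +
#' evaluations), `reliability` (ICC/SEM tables per condition and design) and
#' `associations` (cosine similarity across conditions; matched-epoch
#' logistic trends) — writing each stage's tables under `out_dir` and
#' returning them. Deterministic for a fixed `config$seed`: re-running with
#' the same configuration reproduces every number.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   writing.
#' @param stages prefix of `c("simulate", "reliability", "associations")`.
#' @return A report bundle: list with `similarity`, `acceptance`, `labels`,
#'   `similarity_summary`, `reliability` (all designs x conditions),
#'   `association` (LMM + Tukey; GLMM slopes) and `provenance`.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir = NULL,
                         stages = c("simulate", "reliability",
                                    "associations")) {
  order_ <- c("simulate", "reliability", "associations")
  stages <- match.arg(stages, order_, several.ok = TRUE)
  if (!identical(stages, order_[seq_along(stages)])) {
    stop("stages must form a prefix of: ", paste(order_, collapse = " -> "))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }

  bundle <- list(provenance = list(
    seed = config$seed,
    n_datasets_per_condition = config$n_datasets_per_condition,
    n_epochs = config$n_epochs, fs = config$fs,
    package_version = as.character(utils::packageVersion("mrcprel"))
  ))

  study <- simulate_study(config)
  ev <- simulate_evaluations(study, config)
  bundle$similarity <- ev$similarity
  bundle$acceptance <- ev$acceptance
  bundle$labels <- ev$labels
  agg <- stats::aggregate(cs ~ condition, data = ev$similarity,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  bundle$similarity_summary <- data.frame(
    condition = agg$condition, mean_cs = agg$cs[, "mean"],
    sd_cs = agg$cs[, "sd"], stringsAsFactors = FALSE
  )
  emit(ev$similarity, "similarity")
  emit(ev$acceptance, "acceptance")
  emit(ev$labels, "pn_labels")
  emit(bundle$similarity_summary, "similarity_summary")
  if (!"reliability" %in% stages) {
    return(finish_bundle(bundle, out_dir))
  }

  rel <- list()
  for (cond in names(config$condition_params)) {
    for (design in c("intra_session", "inter_session", "inter_rater")) {
      rel[[length(rel) + 1L]] <- reliability_report(ev$labels, design, cond)
    }
  }
  bundle$reliability <- do.call(rbind, rel)
  emit(bundle$reliability, "reliability")
  if (!"associations" %in% stages) {
    return(finish_bundle(bundle, out_dir))
  }

  sim <- ev$similarity[ev$similarity$valid, ]
  sim$condition <- factor(sim$condition,
                          levels = names(config$condition_params))
  lmm <- fit_lmm_random_intercept(sim, "cs", "condition", "dataset_id")
  tuk <- pairwise_tukey(lmm, "condition")

  matched <- matched_epoch_data(ev, sessions = c(1, 2))
  matched$condition <- factor(matched$condition,
                              levels = names(config$condition_params))
  glmm <- fit_glmm_logit_random_intercept(
    matched, "matched", c("cs", "condition", "cs:condition"), "dataset_id",
    quad_points = 7)
  slopes <- simple_slopes(glmm, "cs", "condition")
  bundle$association <- list(
    lmm = lmm, tukey = tuk, glmm = glmm, cs_trends = slopes
  )
  emit(lmm$coefficients, "lmm_coefficients")
  emit(tuk, "tukey_contrasts")
  emit(glmm$coefficients, "glmm_coefficients")
  emit(slopes, "cs_trends")
  finish_bundle(bundle, out_dir)
}

finish_bundle <- function(bundle, out_dir) {
  if (!is.null(out_dir)) {
    jsonlite::write_json(bundle$provenance,
                         file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  bundle
}

#' Assemble matched-epoch model data from simulated evaluations
#'
#' Joins the intra-rater matched indicators (acceptance at both of two
#' sessions) with each epoch's cosine similarity and each rater's
#' experience, producing the analysis table for the matched-probability
#' logistic models.
#'
#' @param ev result of [simulate_evaluations()].
#' @param sessions the two sessions defining the intra-rater match.
#' @return Data frame: `dataset_id`, `condition`, `rater_id`,
#'   `epoch_index`, `cs`, `experience`, `matched` (0/1).
#' @export
matched_epoch_data <- function(ev, sessions = c(1, 2)) {
  acc <- ev$acceptance
  raters <- unique(acc$rater_id)
  exp_years <- stats::setNames(
    acc$experience[match(raters, acc$rater_id)], raters)
  rows <- list()
  for (r in raters) {
    mt <- matched_table(acc, list(type = "intra", rater = r,
                                  s1 = sessions[1], s2 = sessions[2]))
    key <- paste(mt$dataset_id, mt$epoch_index)
    a1 <- acc[acc$rater_id == r & acc$session == sessions[1], ]
    idx <- match(key, paste(a1$dataset_id, a1$epoch_index))
    rows[[length(rows) + 1L]] <- data.frame(
      dataset_id = mt$dataset_id, condition = a1$condition[idx],
      rater_id = r, epoch_index = mt$epoch_index, cs = a1$cs[idx],
      experience = unname(exp_years[r]),
      matched = as.integer(mt$matched), stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Validate pipeline input tables
#'
#' Schema and completeness checks for the delimited inputs the pipeline
#' consumes. Returns a machine-readable violation list (empty when
#' everything is valid); unreadable files become violations, not errors.
#'
#' @param epochs optional epoch matrix (or path to one) to check against the
#'   expected `n_epochs` x `n_samples` shape.
#' @param labels optional PN label table (data frame or path): needs columns
#'   `dataset_id`, `condition`, `rater_id`, `session`, `pn_ms` and a complete
#'   dataset x rater x session grid.
#' @param acceptance optional acceptance table (data frame or path): needs
#'   `dataset_id`, `rater_id`, `session`, `epoch_index`, `accept`.
#' @param n_epochs,n_samples expected epoch matrix shape.
#' @return Data frame with columns `input`, `violation` (zero rows if
#'   valid).
#' @export
validate_inputs <- function(epochs = NULL, labels = NULL, acceptance = NULL,
                            n_epochs = 50, n_samples = 2250) {
  v <- list()
  note <- function(input, msg) {
    v[[length(v) + 1L]] <<- data.frame(input = input, violation = msg,
                                       stringsAsFactors = FALSE)
  }
  load_df <- function(x, input) {
    if (is.character(x)) {
      tryCatch(suppressWarnings(utils::read.csv(x, stringsAsFactors = FALSE)),
               error = function(e) {
                 note(input, paste("unreadable file:", conditionMessage(e)))
                 NULL
               })
    } else x
  }
  if (!is.null(epochs)) {
    m <- if (is.character(epochs)) {
      tryCatch(as.matrix(utils::read.table(epochs)),
               error = function(e) {
                 note("epochs", paste("unreadable file:",
                                      conditionMessage(e)))
                 NULL
               })
    } else as.matrix(epochs)
    if (!is.null(m)) {
      if (nrow(m) != n_epochs) {
        note("epochs", sprintf("expected %d epochs, found %d",
                               n_epochs, nrow(m)))
      }
      if (ncol(m) != n_samples) {
        note("epochs", sprintf("expected %d samples per epoch, found %d",
                               n_samples, ncol(m)))
      }
      if (anyNA(m)) note("epochs", "matrix contains missing values")
    }
  }
  if (!is.null(labels)) {
    lab <- load_df(labels, "labels")
    if (!is.null(lab)) {
      need <- c("dataset_id", "condition", "rater_id", "session", "pn_ms")
      miss <- setdiff(need, names(lab))
      if (length(miss) > 0) {
        note("labels", paste("missing column(s):", paste(miss, collapse = ", ")))
      } else {
        full <- expand.grid(dataset_id = unique(lab$dataset_id),
                            rater_id = unique(lab$rater_id),
                            session = unique(lab$session),
                            stringsAsFactors = FALSE)
        have <- paste(lab$dataset_id, lab$rater_id, lab$session)
        want <- paste(full$dataset_id, full$rater_id, full$session)
        gone <- full[!want %in% have, ]
        for (i in seq_len(nrow(gone))) {
          note("labels", sprintf("missing label cell (%s, %s, session %s)",
                                 gone$dataset_id[i], gone$rater_id[i],
                                 gone$session[i]))
        }
      }
    }
  }
  if (!is.null(acceptance)) {
    acc <- load_df(acceptance, "acceptance")
    if (!is.null(acc)) {
      need <- c("dataset_id", "rater_id", "session", "epoch_index", "accept")
      miss <- setdiff(need, names(acc))
      if (length(miss) > 0) {
        note("acceptance",
             paste("missing column(s):", paste(miss, collapse = ", ")))
      } else if (anyDuplicated(paste(acc$dataset_id, acc$rater_id,
                                     acc$session, acc$epoch_index))) {
        note("acceptance", "duplicate (dataset, rater, session, epoch) rows")
      }
    }
  }
  if (length(v) == 0) {
    data.frame(input = character(), violation = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, v)
  }
}
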