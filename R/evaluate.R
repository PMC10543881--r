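# Dilution-series evaluation and the end-to-end pipeline.

#' Linear concordance of predictions with a dilution series
#'
#' Regresses predicted tumour content (y) on the spike-in concentration of
#' patient plasma (x), with and without an intercept. The with-intercept
#' coefficient of determination uses the usual centred total sum of
#' squares, `R^2 = 1 - RSS/TSS`; the through-origin fit reports the
#' uncentred convention `R^2 = 1 - RSS0 / sum(y^2)` (the two conventions
#' disagree and are not comparable — both are reported).
#'
#' @param concentration Numeric vector of distinct concentrations in
#'   `[0, 1]`, length at least 2.
#' @param prediction Predicted tumour content, same length.
#' @return An object of class `regression_report`: `slope`, `intercept`,
#'   `r2_with_intercept`, `slope_origin`, `r2_through_origin`, `n`.
#' @export
evaluate_dilution <- function(concentration, prediction) {
  x <- as.numeric(concentration)
  y <- as.numeric(prediction)
  if (length(x) < 2L || length(x) != length(y)) {
    stop("need >= 2 (concentration, prediction) pairs", call. = FALSE)
  }
  if (anyDuplicated(x)) stop("concentrations must be distinct",
                             call. = FALSE)
  if (stats::var(x) == 0) stop("constant concentration", call. = FALSE)
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  fit0 <- stats::lm(y ~ x - 1)
  rss0 <- sum(stats::residuals(fit0)^2)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r2_with_intercept = 1 - rss / tss,
         slope_origin = unname(stats::coef(fit0)[1L]),
         r2_through_origin = 1 - rss0 / sum(y^2),
         n = length(x)),
    class = "regression_report"
  )
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(
    paste0("<regression_report> n = %d\n",
           "  with intercept:  slope %.3f, intercept %.3f, R^2 %.3f\n",
           "  through origin:  slope %.3f, R^2 %.3f\n"),
    x$n, x$slope, x$intercept, x$r2_with_intercept, x$slope_origin,
    x$r2_through_origin))
  invisible(x)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full tumour-content pipeline from manifests
#'
#' Orchestrates every stage on cohort manifests (see [read_manifest()]):
#' histograms are normalized and featurized; panel-labelled samples
#' (cohort A) get tumour-content labels from Dirichlet-process VAF
#' clustering, surrogate-labelled samples (cohort B) from their manifest
#' value (zero-valued labels dropped); stability selection runs on the
#' cohort-B features; the boosting model is tuned (bootstrap
#' cross-validation of `mstop`) and fitted on cohort A restricted to the
#' selected features; the test manifest is predicted, and rows carrying
#' `dilution` concentrations are evaluated for linear concordance.
#'
#' @param train_manifest,test_manifest Manifest CSV paths.
#' @param seed Integer seed governing every stochastic stage.
#' @param stability Optional [stability_config()]; defaults to B = 50
#'   pairs, `pfer = 1`, cutoff 0.75, seeded from `seed`.
#' @param mstop_grid Candidate boosting iteration counts.
#' @param folds Bootstrap folds for tuning.
#' @param nu Boosting step length.
#' @param crp_iters Gibbs sweeps per cohort-A sample.
#' @param levels Wavelet decomposition depth.
#' @return An object of class `fraglift_run`: `report`
#'   (a `regression_report`, or NULL when the test manifest carries no
#'   concentrations), `model`, `cv`, `stability`, `labels`,
#'   `predictions` (data frame `sample_id, concentration, prediction`),
#'   `selected`.
#' @export
pipeline_end_to_end <- function(train_manifest, test_manifest,
                                seed = 1L,
                                stability = NULL,
                                mstop_grid = 0:500,
                                folds = 25L,
                                nu = 0.1,
                                crp_iters = 2000L,
                                levels = 6L) {
  train <- stage("load", read_manifest(train_manifest))
  test <- stage("load", read_manifest(test_manifest))

  featurize <- function(man) {
    profs <- lapply(seq_len(nrow(man)), function(i) {
      normalize_histogram(read_histogram(man$histogram_path[i],
                                         man$sample_id[i]))
    })
    feature_matrix(profs, levels = levels)
  }
  X_train <- stage("features", featurize(train))
  X_test <- stage("features", featurize(test))

  labels <- stage("labels", {
    out <- lapply(seq_len(nrow(train)), function(i) {
      src <- train$label_source[i]
      if (src == "panel") {
        mut <- read_mutations(train$label_value_or_mutation_path[i])
        lab <- panel_label(mut, iters = crp_iters,
                           seed = seed + i)
        data.frame(sample_id = train$sample_id[i], value = lab$value,
                   source = "panel", stringsAsFactors = FALSE)
      } else if (src == "surrogate") {
        data.frame(sample_id = train$sample_id[i],
                   value = as.numeric(train$label_value_or_mutation_path[i]),
                   source = "surrogate", stringsAsFactors = FALSE)
      } else {
        NULL
      }
    })
    do.call(rbind, out)
  })
  n_zero <- sum(labels$source == "surrogate" & labels$value <= 0)
  if (n_zero > 0L) {
    message(n_zero, " surrogate label(s) with zero tumour content dropped")
    labels <- labels[!(labels$source == "surrogate" & labels$value <= 0), ]
  }

  idx_B <- labels$sample_id[labels$source == "surrogate"]
  idx_A <- labels$sample_id[labels$source == "panel"]

  stab <- stage("stability", {
    if (length(idx_B) < 4L) {
      stop("need >= 4 surrogate-labelled samples for stability selection")
    }
    cfg <- if (is.null(stability)) {
      stability_config(seed = seed)
    } else {
      stability
    }
    yB <- labels$value[match(idx_B, labels$sample_id)]
    run_stability(X_train[idx_B, , drop = FALSE], yB, cfg, nu = nu)
  })
  selected <- stab$selected
  if (length(selected) == 0L) {
    stop("[stage stability] no feature passed the cutoff", call. = FALSE)
  }

  yA <- labels$value[match(idx_A, labels$sample_id)]
  XA <- X_train[idx_A, selected, drop = FALSE]
  cv <- stage("tune", {
    if (length(idx_A) < 2L) stop("need >= 2 panel-labelled samples")
    tune_mstop(XA, yA, grid = mstop_grid, folds = folds, nu = nu,
               seed = seed)
  })
  model <- stage("train", fit_boost(XA, yA, nu = nu,
                                    mstop = max(1L, cv$mstop_opt),
                                    seed = seed))

  pred <- stage("predict",
                predict(model, X_test[, selected, drop = FALSE]))
  conc <- suppressWarnings(
    as.numeric(test$label_value_or_mutation_path))
  predictions <- data.frame(sample_id = test$sample_id,
                            concentration = ifelse(
                              test$label_source == "dilution", conc,
                              NA_real_),
                            prediction = pred,
                            stringsAsFactors = FALSE)
  report <- NULL
  has_conc <- !is.na(predictions$concentration)
  if (sum(has_conc) >= 2L) {
    report <- stage("evaluate",
                    evaluate_dilution(predictions$concentration[has_conc],
                                      predictions$prediction[has_conc]))
  }
  structure(
    list(report = report, model = model, cv = cv, stability = stab,
         labels = labels, predictions = predictions, selected = selected,
         seed = seed),
    class = "fraglift_run"
  )
}

#' @export
print.fraglift_run <- function(x, ...) {
  cat(sprintf(
    "<fraglift_run> %d feature(s) selected; mstop = %d\n",
    length(x$selected), x$model$mstop))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
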