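# Complementary-pairs stability selection with the boosting learner and a
# per-family expected-false-positive (PFER) budget.

#' Stability-selection configuration
#'
#' Exactly two of `q` (per-run selection count), `pfer` (expected number
#' of falsely selected features tolerated) and `cutoff` (selection-
#' frequency threshold in (0.5, 1]) must be supplied; the third is derived
#' from the error bound by [derive_threshold()]. The default budget is one
#' expected false positive at a 0.75 frequency cutoff.
#'
#' @param B Number of complementary half-sample pairs (default 50).
#' @param q Number of features each boosting run may select.
#' @param pfer Per-family expected-false-positive budget.
#' @param cutoff Selection-frequency threshold.
#' @param bound Error bound relating the three; only the
#'   Meinshausen--Buhlmann bound (`"MB"`) is implemented.
#' @param seed Integer seed for the half-sample draws.
#' @return An object of class `stability_config`.
#' @export
stability_config <- function(B = 50L, q = NULL, pfer = 1.0, cutoff = 0.75,
                             bound = "MB", seed = 1L) {
  bound <- match.arg(bound)
  n_set <- sum(!vapply(list(q, pfer, cutoff), is.null, logical(1)))
  if (n_set != 2L) {
    stop("exactly two of q, pfer, cutoff must be set (got ", n_set, ")",
         call. = FALSE)
  }
  structure(
    list(B = as.integer(B), q = q, pfer = pfer, cutoff = cutoff,
         bound = bound, seed = seed),
    class = "stability_config"
  )
}

#' Derive the free stability-selection parameter from the error bound
#'
#' Under the Meinshausen--Buhlmann bound the expected number of falsely
#' selected features satisfies `pfer <= q^2 / ((2*cutoff - 1) * p)` for
#' `p` features. Whichever of `q`, `pfer`, `cutoff` was left unset in the
#' config is filled in: `q` as the largest integer respecting the budget,
#' `pfer` and `cutoff` by direct inversion.
#'
#' @param config A [stability_config()] with exactly one unset member.
#' @param p Number of candidate features.
#' @return The config with all three members set (class
#'   `stability_config`).
#' @export
derive_threshold <- function(config, p) {
  stopifnot(inherits(config, "stability_config"), p > 0)
  q <- config$q
  pfer <- config$pfer
  cutoff <- config$cutoff
  if (!is.null(cutoff) && (cutoff <= 0.5 || cutoff > 1)) {
    stop("cutoff must lie in (0.5, 1]", call. = FALSE)
  }
  if (is.null(q)) {
    q <- floor(sqrt(pfer * (2 * cutoff - 1) * p))
    if (q < 1) {
      stop("bound infeasible: increase pfer or decrease cutoff",
           call. = FALSE)
    }
  } else if (is.null(pfer)) {
    pfer <- q^2 / ((2 * cutoff - 1) * p)
  } else {
    cutoff <- (q^2 / (pfer * p) + 1) / 2
    if (cutoff <= 0.5 || cutoff > 1) {
      stop("derived cutoff outside (0.5, 1]: change q or pfer",
           call. = FALSE)
    }
  }
  config$q <- as.integer(q)
  config$pfer <- pfer
  config$cutoff <- cutoff
  config
}

# One complementary pair: a random partition of the sample indices into
# two disjoint halves of size floor(n/2); with odd n the left-over index
# (random per pair) sits out of both.
draw_pair <- function(n) {
  half <- n %/% 2L
  perm <- sample.int(n)
  list(perm[seq_len(half)], perm[half + seq_len(half)])
}

#' Complementary-pairs stability selection
#'
#' For each of `B` pairs, the (even-truncated) sample index set is
#' partitioned at random into two complementary halves of size
#' `floor(n/2)`; with odd `n` one sample is left out of both halves,
#' chosen at random per pair. On each half, [fit_boost()] is run until
#' `q` distinct features have entered the model (capped at `10*q`
#' iterations), and the entered feature set is recorded. Selection
#' frequencies are proportions over the `2B` runs, and features at or
#' above the cutoff are selected; the Meinshausen--Buhlmann bound then
#' controls the expected number of falsely selected features at `pfer`.
#'
#' @param X Feature matrix with column names, at least 4 rows.
#' @param y Response in (0, 1).
#' @param config A [stability_config()]; unset member derived via
#'   [derive_threshold()].
#' @param nu Boosting step length.
#' @return An object of class `stability_result`: `frequencies` (named,
#'   multiples of 1/(2B)), `selected`, `config`.
#' @export
run_stability <- function(X, y, config = stability_config(), nu = 0.1) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 4L) stop("need at least 4 samples", call. = FALSE)
  config <- derive_threshold(config, p)
  q <- config$q
  if (q >= p) stop("q must be smaller than the number of features",
                   call. = FALSE)
  run <- function() {
    counts <- stats::setNames(numeric(p), colnames(X))
    for (b in seq_len(config$B)) {
      for (h in draw_pair(n)) {
        fit <- fit_boost(X[h, , drop = FALSE], y[h], nu = nu,
                         mstop = 10L * q, qstop = q)
        entered <- unique(fit$path$feature)
        counts[entered] <- counts[entered] + 1
      }
    }
    counts / (2 * config$B)
  }
  freq <- withr::with_seed(config$seed, run())
  structure(
    list(frequencies = freq,
         selected = names(freq)[freq >= config$cutoff],
         config = config),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "<stability_result> B = %d pairs, q = %d, pfer = %.3g, cutoff = %.2f\n",
    x$config$B, x$config$q, x$config$pfer, x$config$cutoff))
  if (length(x$selected)) {
    cat("selected:", paste(x$selected, collapse = ", "), "\n")
  } else {
    cat("selected: none\n")
  }
  invisible(x)
}

#' Write a stability report
#'
#' Writes `feature,frequency,selected` as CSV and the resolved
#' configuration as a JSON sidecar (`<path>.config.json`).
#'
#' @param result A `stability_result`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(result, path) {
  stopifnot(inherits(result, "stability_result"))
  df <- data.frame(feature = names(result$frequencies),
                   frequency = unname(result$frequencies),
                   selected = names(result$frequencies) %in%
                     result$selected)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(result$config[c("B", "q", "pfer", "cutoff",
                                       "bound", "seed")],
                       paste0(path, ".config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
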