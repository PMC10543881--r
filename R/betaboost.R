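# Component-wise gradient boosting of a beta-regression likelihood with a
# logit link for the mean and a scalar precision refreshed each iteration.

#' Negative log-likelihood of the beta distribution (mean/precision form)
#'
#' Density `f(y; mu, phi) = Gamma(phi) / (Gamma(mu*phi) *
#' Gamma((1-mu)*phi)) * y^(mu*phi-1) * (1-y)^((1-mu)*phi-1)` on (0, 1).
#' All arguments are recycled; each must lie strictly inside its range.
#'
#' @param y Observations in (0, 1).
#' @param mu Means in (0, 1).
#' @param phi Precisions > 0.
#' @return Vector of negative log-density values.
#' @export
beta_negloglik <- function(y, mu, phi) {
  if (any(y <= 0 | y >= 1)) stop("y must lie strictly in (0, 1)",
                                 call. = FALSE)
  if (any(mu <= 0 | mu >= 1)) stop("mu must lie strictly in (0, 1)",
                                   call. = FALSE)
  if (any(phi <= 0)) stop("phi must be positive", call. = FALSE)
  beta_nll_raw(y, mu, phi)
}

# Unchecked kernel used in fitting loops.
beta_nll_raw <- function(y, mu, phi) {
  -(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
      (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y))
}

# The logistic mean can saturate numerically for extreme linear
# predictors; keep it strictly inside (0, 1) for the likelihood.
clamp_mu <- function(mu) pmin(pmax(mu, 1e-10), 1 - 1e-10)

# Maximize the beta log-likelihood over phi for fixed mu, on
# log(phi) in [-4, 8]. Only the lgamma terms depend on phi beyond the
# linear sufficient statistic, so they are the only per-candidate work.
refresh_phi <- function(y, mu, suff = sum(mu * log(y) +
                                            (1 - mu) * log1p(-y))) {
  n <- length(y)
  f <- function(lp) {
    phi <- exp(lp)
    sum(lgamma(mu * phi) + lgamma((1 - mu) * phi)) - n * lgamma(phi) -
      phi * suff
  }
  exp(stats::optimize(f, c(-4, 8), tol = 1e-6)$minimum)
}

#' Fit a component-wise boosted beta regression
#'
#' Features are standardized to mean 0, sd 1 (constant columns dropped
#' with a warning) and the linear predictor for the logit of the mean
#' starts at `offset = qlogis(mean(y))`. Each iteration computes the
#' negative gradient of the summed [beta_negloglik()] with respect to the
#' linear predictor, least-squares-fits every feature singly to it,
#' advances the best-fitting feature's coefficient by `nu` times its
#' fitted slope, and then refreshes the precision `phi` by
#' one-dimensional likelihood maximization. Only features that are ever
#' selected acquire nonzero coefficients, giving sparse linear models
#' with coefficient paths.
#'
#' @param X Numeric feature matrix with column names, no missing values.
#' @param y Response strictly inside (0, 1); boundary values are rejected
#'   (squeeze labels upstream).
#' @param nu Step length (default 0.1).
#' @param mstop Number of boosting iterations.
#' @param qstop Optional early stop: halt once this many distinct features
#'   have entered the model (used by stability selection).
#' @param seed Recorded for provenance; the fit itself is deterministic.
#' @return An object of class `boosted_beta_model`: `offset`,
#'   `coefficients` (standardized scale), `phi`, `mstop` (iterations
#'   actually run), `nu`, `path` (per-iteration feature, increment, phi,
#'   and mean training risk), `standardization`, `feature_names`, `seed`.
#' @export
fit_boost <- function(X, y, nu = 0.1, mstop = 100L, qstop = NULL,
                      seed = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have column names", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (any(y <= 0 | y >= 1)) {
    stop("y must lie strictly in (0, 1); squeeze labels upstream",
         call. = FALSE)
  }
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  keep <- scl > 0
  if (!any(keep)) stop("all feature columns are constant", call. = FALSE)
  if (any(!keep)) {
    warning("dropping constant feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
  }
  Xs <- scale(X[, keep, drop = FALSE], center = ctr[keep],
              scale = scl[keep])
  xnames <- colnames(Xs)
  xss <- colSums(Xs^2)

  offset <- stats::qlogis(mean(y))
  eta <- rep(offset, n)
  coef <- stats::setNames(numeric(length(xnames)), xnames)
  logity <- stats::qlogis(y)
  mu <- clamp_mu(stats::plogis(eta))
  phi <- refresh_phi(y, mu)
  path <- vector("list", mstop)
  m_done <- 0L
  for (m in seq_len(mstop)) {
    # negative gradient of the summed NLL w.r.t. eta
    u <- phi * (logity - digamma(mu * phi) +
                  digamma((1 - mu) * phi)) * mu * (1 - mu)
    xu <- as.numeric(crossprod(Xs, u))
    slopes <- xu / xss
    best <- which.max(slopes^2 * xss)     # largest least-squares SS gain
    coef[best] <- coef[best] + nu * slopes[best]
    eta <- eta + nu * slopes[best] * Xs[, best]
    mu <- clamp_mu(stats::plogis(eta))
    phi <- refresh_phi(y, mu)
    path[[m]] <- list(feature = xnames[best],
                      increment = nu * slopes[best], phi = phi,
                      risk = mean(beta_nll_raw(y, mu, phi)))
    m_done <- m
    if (!is.null(qstop) && sum(coef != 0) >= qstop) break
  }
  path <- path[seq_len(m_done)]
  structure(
    list(offset = offset,
         coefficients = coef,
         phi = phi,
         mstop = m_done,
         nu = nu,
         path = data.frame(
           iter = seq_len(m_done),
           feature = vapply(path, `[[`, character(1), "feature"),
           increment = vapply(path, `[[`, numeric(1), "increment"),
           phi = vapply(path, `[[`, numeric(1), "phi"),
           risk = vapply(path, `[[`, numeric(1), "risk"),
           stringsAsFactors = FALSE
         ),
         standardization = data.frame(feature = xnames,
                                      center = unname(ctr[keep]),
                                      scale = unname(scl[keep]),
                                      stringsAsFactors = FALSE),
         feature_names = xnames,
         seed = seed),
    class = "boosted_beta_model"
  )
}

#' @export
print.boosted_beta_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf(paste0("<boosted_beta_model> %d iteration(s), nu = %g, ",
                     "%d active feature(s), phi = %.3f\n"),
              x$mstop, x$nu, nz, x$phi))
  invisible(x)
}

#' Predict tumour content from a boosted beta model
#'
#' Applies the fit-time standardization and logit-linear predictor;
#' predictions are `plogis(offset + sum(coef * standardized feature))`
#' and therefore always lie in (0, 1).
#'
#' @param object A `boosted_beta_model`.
#' @param newdata Matrix or data frame containing every model feature;
#'   extra columns are ignored with a warning.
#' @param ... Unused.
#' @return Numeric vector of predicted means in (0, 1).
#' @export
predict.boosted_beta_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  miss <- setdiff(object$feature_names, colnames(X))
  if (length(miss)) {
    stop("newdata lacks model feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(colnames(X), object$feature_names)
  if (length(extra)) {
    warning(length(extra), " extra column(s) ignored", call. = FALSE)
  }
  X <- X[, object$feature_names, drop = FALSE]
  std <- object$standardization
  Xs <- sweep(sweep(X, 2L, std$center, "-"), 2L, std$scale, "/")
  eta <- object$offset + as.numeric(Xs %*% object$coefficients)
  stats::plogis(eta)
}

# Out-of-sample mean risk along the boosting path of `model`, evaluated at
# each iteration count in `grid` (entries beyond the realized path reuse
# its endpoint).
path_risk <- function(model, X_new, y_new, grid) {
  std <- model$standardization
  X <- as.matrix(X_new)[, model$feature_names, drop = FALSE]
  Xs <- sweep(sweep(X, 2L, std$center, "-"), 2L, std$scale, "/")
  eta <- rep(model$offset, nrow(Xs))
  phi0 <- refresh_phi(y_new, clamp_mu(stats::plogis(eta)))
  risks <- numeric(length(grid))
  gi <- 1L
  m_total <- nrow(model$path)
  for (m in 0L:max(grid)) {
    if (m > 0L && m <= m_total) {
      f <- model$path$feature[m]
      eta <- eta + model$path$increment[m] * Xs[, f]
    }
    if (gi <= length(grid) && grid[gi] == m) {
      phi <- if (m == 0L) phi0 else model$path$phi[min(m, m_total)]
      risks[gi] <- mean(beta_nll_raw(y_new, clamp_mu(stats::plogis(eta)),
                                     phi))
      gi <- gi + 1L
    }
  }
  risks
}

#' Tune the number of boosting iterations by bootstrap cross-validation
#'
#' Draws `folds` bootstrap resamples of the data (size n, with
#' replacement), fits the boosting path once per resample, and evaluates
#' mean out-of-bag [beta_negloglik()] at every candidate `mstop` in
#' `grid`. Risks are averaged across folds and the grid point with the
#' lowest mean risk is chosen; ties go to the smallest `mstop`
#' (parsimony). Resamples with an empty out-of-bag set are redrawn.
#'
#' @param X Feature matrix with column names.
#' @param y Response in (0, 1), length at least 10.
#' @param grid Sorted ascending vector of candidate iteration counts
#'   (default 0..500).
#' @param folds Number of bootstrap resamples (default 25).
#' @param nu Step length passed to [fit_boost()].
#' @param seed Integer seed making the resamples reproducible.
#' @return An object of class `cv_result`: `folds`, `grid`, `risks`
#'   (fold x grid matrix), `mean_risk`, `mstop_opt`.
#' @export
tune_mstop <- function(X, y, grid = 0:500, folds = 25L, nu = 0.1,
                       seed = 1L) {
  if (length(grid) == 0L) stop("empty mstop grid", call. = FALSE)
  grid <- as.integer(grid)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be sorted ascending without ties", call. = FALSE)
  }
  n <- length(y)
  if (n < 10L) stop("need at least 10 samples to tune mstop", call. = FALSE)
  run <- function() {
    risks <- matrix(NA_real_, folds, length(grid))
    for (b in seq_len(folds)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), idx)
        if (length(oob) > 0L) break
      }
      fit <- fit_boost(X[idx, , drop = FALSE], y[idx], nu = nu,
                       mstop = max(grid))
      risks[b, ] <- path_risk(fit, X[oob, , drop = FALSE], y[oob], grid)
    }
    risks
  }
  risks <- withr::with_seed(seed, run())
  mean_risk <- colMeans(risks)
  structure(
    list(folds = as.integer(folds), grid = grid, risks = risks,
         mean_risk = mean_risk,
         mstop_opt = grid[which.min(mean_risk)],
         seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d bootstrap folds; optimal mstop = %d\n",
              x$folds, x$mstop_opt))
  invisible(x)
}

#' Serialize / restore a boosted beta model as JSON
#'
#' The JSON file stores the offset, coefficient map, precision, step
#' length, stopping iteration, standardization table, feature names and
#' seed provenance at full double precision, so restored models reproduce
#' predictions bit-for-bit.
#'
#' @param model A `boosted_beta_model`.
#' @param path JSON file path.
#' @return `path` invisibly for the writer; the model for the reader.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "boosted_beta_model"))
  obj <- list(
    format = "fraglift_boosted_beta_model",
    version = 1L,
    offset = model$offset,
    coefficients = as.list(model$coefficients),
    phi = model$phi,
    mstop = model$mstop,
    nu = model$nu,
    standardization = model$standardization,
    feature_names = model$feature_names,
    seed = model$seed,
    path = model$path
  )
  # digits = 17 is the smallest count that round-trips every double
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 17L,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "fraglift_boosted_beta_model")) {
    stop("not a fraglift model file: ", path, call. = FALSE)
  }
  structure(
    list(offset = obj$offset,
         coefficients = unlist(obj$coefficients),
         phi = obj$phi,
         mstop = as.integer(obj$mstop),
         nu = obj$nu,
         path = as.data.frame(obj$path),
         standardization = as.data.frame(obj$standardization),
         feature_names = obj$feature_names,
         seed = obj$seed),
    class = "boosted_beta_model"
  )
}
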