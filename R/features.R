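# Fourier features of the detrended 81-141 bp window, and the combined
# feature vector.

#' Quadratic detrending of the log profile over 81--141 bp
#'
#' Fits `log(p_j) = b0 + b1*j + b2*j^2` by ordinary least squares over the
#' fragment lengths j = 81..141 and returns the 61 residuals indexed
#' n = j - 81. The residuals isolate the ~10 bp nucleosomal oscillation
#' from the smooth trend of the distribution.
#'
#' @param profile A `fragment_profile` whose support contains 81--141 bp.
#' @param window Inclusive bp window, default `c(81, 141)`.
#' @return An object of class `detrend_fit` with `coefficients`
#'   (`beta0`, `beta1`, `beta2`), `residuals` (length `diff(window) + 1`),
#'   `fitted` and `window`.
#' @export
detrend_window <- function(profile, window = c(81L, 141L)) {
  y <- profile_window(profile, window[1L], window[2L])
  if (any(!is.finite(y))) {
    stop("non-finite log proportions in detrend window", call. = FALSE)
  }
  j <- window[1L]:window[2L]
  fit <- stats::lm.fit(cbind(1, j, j^2), y)
  structure(
    list(coefficients = stats::setNames(fit$coefficients,
                                        c("beta0", "beta1", "beta2")),
         residuals = unname(fit$residuals),
         fitted = unname(fit$fitted.values),
         window = as.integer(window)),
    class = "detrend_fit"
  )
}

#' Discrete Fourier magnitudes of detrending residuals
#'
#' Computes the unnormalized negative-exponent DFT
#' `F_k = sum_n e_n exp(-2*pi*i*k*n/N)` of the residual vector
#' (N = 61 for the default window) and returns the magnitudes `|F_k|` for
#' k = 1..floor(N/2), named `"F1".."F30"`. `F_0` vanishes because OLS
#' residuals with an intercept are centred, and conjugate symmetry makes
#' `|F_{N-k}| = |F_k|`, so the first half of the spectrum is the complete
#' non-redundant feature set.
#'
#' @param fit A `detrend_fit`, or a numeric residual vector.
#' @return An object of class `fourier_features` with the complex spectrum
#'   `F` (k = 0..N-1) and named `magnitudes`.
#' @export
fourier_features <- function(fit) {
  eps <- if (inherits(fit, "detrend_fit")) fit$residuals else as.numeric(fit)
  n <- length(eps)
  if (n < 3L) stop("residual vector too short", call. = FALSE)
  f <- stats::fft(eps)
  k <- seq_len(n %/% 2L)
  structure(
    list(F = f,
         magnitudes = stats::setNames(Mod(f)[k + 1L], paste0("F", k))),
    class = "fourier_features"
  )
}

#' Extract the full fragmentomic feature vector of a sample
#'
#' Concatenates the Fourier magnitudes of the detrended 81--141 bp window
#' ([fourier_features()]) with the Daubechies-10 wavelet coefficients of
#' the 81--336 bp window ([wavelet_features()]). Feature names are stable
#' across samples and releases: `"F1".."F30"` followed by
#' `"W{scale}_{location}"` ordered by scale then location; serialized
#' models refer to these names.
#'
#' @param profile A `fragment_profile` covering 81--336 bp.
#' @param levels Wavelet decomposition depth (default 6).
#' @return An object of class `feature_vector`: list with `sample_id` and
#'   the named numeric `values` (286 entries at defaults).
#' @export
extract_features <- function(profile, levels = 6L) {
  fou <- fourier_features(detrend_window(profile))
  wav <- wavelet_features(profile, levels = levels)
  structure(
    list(sample_id = profile$sample_id,
         values = c(fou$magnitudes, wav$coefficients)),
    class = "feature_vector"
  )
}

#' Build a feature matrix for a list of profiles
#'
#' @param profiles List of `fragment_profile` objects.
#' @param levels Wavelet decomposition depth passed to
#'   [extract_features()].
#' @return Numeric matrix, one row per sample (rownames = sample ids),
#'   columns in the fixed feature order.
#' @export
feature_matrix <- function(profiles, levels = 6L) {
  rows <- lapply(profiles, function(p) extract_features(p, levels)$values)
  nm <- names(rows[[1L]])
  for (r in rows) {
    if (!identical(names(r), nm)) {
      stop("inconsistent feature names across samples", call. = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(profiles, function(p) p$sample_id, character(1L))
  out
}

#' Write / read a feature matrix as CSV
#'
#' Rows are samples, the first column is `sample_id`, remaining columns are
#' the named features.
#'
#' @param X Feature matrix with sample-id rownames.
#' @param path CSV path.
#' @return `path` invisibly for the writer; the matrix for the reader.
#' @export
write_feature_matrix <- function(X, path) {
  df <- data.frame(sample_id = rownames(X), X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1L, drop = FALSE])
  rownames(X) <- df$sample_id
  X
}
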