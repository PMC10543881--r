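# Decimated periodized discrete wavelet transform with the 10-tap
# Daubechies filter, chosen because its length matches the ~10 bp
# oscillation period of nucleosome-protected cfDNA.

# Scaling (low-pass) filter of the Daubechies wavelet with 5 vanishing
# moments (filter length 10), in the convention where sum(g) = sqrt(2).
db10_scaling <- c(
  0.00333572528547377125, -0.0125807519990819988, -0.00624149021279827437,
  0.0775714938400457188, -0.0322448695846383748, -0.242294887066382025,
  0.138428145901320743, 0.724308528437772936, 0.603829269797189649,
  0.160102397974192928
)

# Quadrature-mirror wavelet (high-pass) filter: h_l = (-1)^(l+1) g_{L-1-l}.
db10_wavelet <- rev(db10_scaling) * (-1)^seq_along(db10_scaling)

# One pyramid step: circularly filter x with `filt` and downsample by two,
# out_t = sum_l filt_l x_{(2t+1-l) mod N}, t = 0..N/2-1 (the convention of
# the classical pyramid algorithm for the decimated DWT).
dwt_step <- function(x, filt) {
  n <- length(x)
  half <- n %/% 2L
  idx <- outer(2L * seq_len(half) - 1L, seq_along(filt) - 1L, `-`) %% n + 1L
  as.numeric(matrix(x[idx], nrow = half) %*% filt)
}

#' Daubechies-10 wavelet features of the log profile over 81--336 bp
#'
#' Applies a decimated, orthonormal, periodized discrete wavelet transform
#' (pyramid algorithm) with the length-10 Daubechies filter to the log
#' proportions over the 256 fragment lengths 81..336 bp. All detail
#' coefficients for scales 1..`levels` and the final approximation
#' coefficients are returned, named `"W{scale}_{location}"` with
#' 1-based locations; the approximation scale is labelled `levels + 1`.
#' The transform is orthonormal, so total coefficient energy equals the
#' energy of the input window.
#'
#' @param profile A `fragment_profile` covering 81--336 bp, or a numeric
#'   vector whose length is divisible by `2^levels`.
#' @param levels Decomposition depth (default 6; at most `log2` of the
#'   window length).
#' @param boundary Boundary rule; only `"periodic"` (circular filtering)
#'   is implemented.
#' @param window Inclusive bp window, default `c(81, 336)` (256 points).
#' @return An object of class `wavelet_features` with the named
#'   `coefficients`, `levels`, `filter` and `boundary`.
#' @export
wavelet_features <- function(profile, levels = 6L, boundary = "periodic",
                             window = c(81L, 336L)) {
  boundary <- match.arg(boundary)
  x <- if (inherits(profile, "fragment_profile")) {
    unname(profile_window(profile, window[1L], window[2L]))
  } else {
    as.numeric(profile)
  }
  n <- length(x)
  levels <- as.integer(levels)
  if (n < 2L || n %% 2L^levels != 0L) {
    stop(sprintf("window length %d is not divisible by 2^%d", n, levels),
         call. = FALSE)
  }
  if (levels < 1L || 2L^levels > n) {
    stop("levels must be in 1..log2(window length)", call. = FALSE)
  }
  v <- x
  coefs <- numeric(0)
  for (j in seq_len(levels)) {
    d <- dwt_step(v, db10_wavelet)
    v <- dwt_step(v, db10_scaling)
    coefs <- c(coefs,
               stats::setNames(d, paste0("W", j, "_", seq_along(d))))
  }
  coefs <- c(coefs,
             stats::setNames(v, paste0("W", levels + 1L, "_",
                                       seq_along(v))))
  structure(
    list(coefficients = coefs, levels = levels,
         filter = "Daubechies length 10", boundary = boundary),
    class = "wavelet_features"
  )
}
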