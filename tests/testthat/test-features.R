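# Quadratic detrending, Fourier magnitudes, and the combined feature
# vector.

test_that("detrending removes any quadratic trend exactly", {
  j <- 81:141
  logp <- -3 + 0.02 * j - 1e-4 * j^2
  fit <- detrend_window(profile_from_logp(logp))
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  expect_length(fit$residuals, 61)
})

test_that("detrending matches a normal-equations oracle on a cosine", {
  n <- 0:60
  logp <- -5 + cos(2 * pi * 6 * n / 61)
  fit <- detrend_window(profile_from_logp(logp))
  # independent oracle: solve the 61x3 normal equations directly
  j <- 81:141
  A <- cbind(1, j, j^2)
  beta <- solve(t(A) %*% A, t(A) %*% logp)
  expect_equal(fit$residuals, as.numeric(logp - A %*% beta),
               tolerance = 1e-8)
  # the exact-frequency cosine survives detrending nearly unchanged
  expect_gt(cor(fit$residuals, cos(2 * pi * 6 * n / 61)), 0.99)
})

test_that("OLS residuals sum to zero for arbitrary profiles", {
  for (seed in 1:5) {
    logp <- withr::with_seed(seed, rnorm(61, -6, 0.5))
    fit <- detrend_window(profile_from_logp(logp))
    expect_equal(sum(fit$residuals), 0, tolerance = 1e-9)
  }
})

test_that("an exact-frequency cosine concentrates at a single magnitude", {
  eps <- cos(2 * pi * 6 * (0:60) / 61)
  ff <- fourier_features(eps)
  expect_equal(unname(ff$magnitudes["F6"]), 30.5, tolerance = 1e-9)
  expect_lt(max(ff$magnitudes[-6]), 1e-9)
})

test_that("Fourier spectrum obeys F0 = 0, conjugate symmetry, Parseval,
           and matches the direct-summation oracle", {
  for (seed in 1:10) {
    eps <- withr::with_seed(seed, rnorm(61))
    eps <- eps - mean(eps)               # centred, as OLS residuals are
    ff <- fourier_features(eps)
    expect_lt(Mod(ff$F[1]), 1e-9)
    mods <- Mod(ff$F)
    expect_equal(mods[61 - (1:30) + 1], mods[(1:30) + 1],
                 tolerance = 1e-9)
    expect_equal(sum(mods^2), 61 * sum(eps^2), tolerance = 1e-6)
    expect_equal(ff$F, naive_dft(eps), tolerance = 1e-9)
  }
  expect_true(all(Mod(fourier_features(rep(0, 61))$F) == 0))
})

test_that("wavelet coefficients conserve energy and kill smooth trends", {
  # constant input: 5 vanishing moments annihilate every detail level
  wf <- wavelet_features(rep(2.5, 256))
  details <- wf$coefficients[!startsWith(names(wf$coefficients), "W7")]
  expect_lt(max(abs(details)), 1e-9)
  approx <- wf$coefficients[startsWith(names(wf$coefficients), "W7")]
  expect_equal(sum(approx^2), 256 * 2.5^2, tolerance = 1e-9)

  for (seed in 1:5) {
    x <- withr::with_seed(seed, rnorm(256))
    wf <- wavelet_features(x)
    expect_length(wf$coefficients, 256)
    expect_equal(sum(wf$coefficients^2), sum(x^2), tolerance = 1e-9)
  }
})

test_that("degree-4 polynomials yield zero interior detail coefficients", {
  n <- 0:255
  x <- 1 + 0.5 * n - 0.01 * n^2 + 1e-4 * n^3 - 1e-7 * n^4
  x <- x / max(abs(x))
  wf <- wavelet_features(x, levels = 1L)
  d1 <- wf$coefficients[startsWith(names(wf$coefficients), "W1_")]
  # periodic wrap-around touches the first ceil((L-2)/2) = 4 locations;
  # interior coefficients see a pure polynomial and must vanish
  interior <- d1[5:128]
  expect_lt(max(abs(interior)), 1e-8)
  expect_gt(max(abs(d1[1:4])), 1e-6)  # boundary wrap is genuinely nonzero
})

test_that("wavelet decomposition matches the transform-matrix oracle", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, rnorm(256))
    wf <- wavelet_features(x, levels = 6L)
    orc <- oracle_dwt(x, 6L)
    for (j in 1:6) {
      got <- wf$coefficients[startsWith(names(wf$coefficients),
                                        paste0("W", j, "_"))]
      expect_equal(unname(got), orc[[paste0("d", j)]], tolerance = 1e-9)
    }
    got_a <- wf$coefficients[startsWith(names(wf$coefficients), "W7_")]
    expect_equal(unname(got_a), orc$approx, tolerance = 1e-9)
  }
})

test_that("wavelet decomposition matches frozen reference coefficients", {
  # reference values computed with an independent periodized db5 DWT
  # implementation on x_n = sin(2*pi*n/10) + 0.01*n, n = 0..255
  n <- 0:255
  wf <- wavelet_features(sin(2 * pi * n / 10) + 0.01 * n)
  expect_equal(unname(wf$coefficients[paste0("W1_", 1:4)]),
               c(-1.00507378355, 0.268915286254, -0.222212298356,
                 0.075591441615), tolerance = 1e-9)
  expect_equal(unname(wf$coefficients[paste0("W6_", 1:4)]),
               c(2.901498584177, -1.054561880531, 0.0357698247,
                 1.991750137196), tolerance = 1e-9)
  expect_equal(unname(wf$coefficients[paste0("W7_", 1:4)]),
               c(6.859012129841, 11.328899982833, 18.213124076805,
                 4.783674252668), tolerance = 1e-9)
})

test_that("wavelet input constraints are enforced", {
  expect_error(wavelet_features(rnorm(255)), "not divisible")
  expect_error(wavelet_features(rnorm(256), levels = 9L), "not divisible")
  short <- profile_from_logp(rnorm(100), lo = 81L)
  expect_error(wavelet_features(short), "support must contain")
})

test_that("feature vectors are deterministic, scale-invariant and 286 long", {
  counts <- withr::with_seed(3, {
    stats::setNames(rpois(351, 40) + 1, 50:400)
  })
  h1 <- length_histogram("a", counts)
  h2 <- length_histogram("a", counts * 10)
  f1 <- extract_features(normalize_histogram(h1, 0))
  f2 <- extract_features(normalize_histogram(h1, 0))
  f3 <- extract_features(normalize_histogram(h2, 0))
  expect_identical(f1$values, f2$values)
  expect_identical(f1$values, f3$values)
  expect_length(f1$values, 286)
  expect_identical(names(f1$values)[1:30], paste0("F", 1:30))
  expect_identical(names(f1$values)[31:33], paste0("W1_", 1:3))
})

test_that("feature matrices round-trip through CSV", {
  profs <- list(random_profile(1, "s1"), random_profile(2, "s2"))
  X <- feature_matrix(profs)
  expect_identical(rownames(X), c("s1", "s2"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(X, path)
  X2 <- read_feature_matrix(path)
  expect_identical(colnames(X2), colnames(X))
  expect_equal(X2, X, tolerance = 1e-12)
})
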