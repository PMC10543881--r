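# Beta likelihood, component-wise boosting, bootstrap tuning and model
# serialization.

# simulate (X, y) from a sparse logit-linear beta-regression model
sim_beta_data <- function(n, p, beta1 = 2, phi = 20, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    mu <- plogis(beta1 * X[, 1L])
    y <- rbeta(n, mu * phi, (1 - mu) * phi)
    list(X = X, y = pmin(pmax(y, 1e-4), 1 - 1e-4))
  })
}

test_that("the beta negative log-likelihood matches closed forms", {
  # mu = 0.5, phi = 2 is Beta(1, 1): uniform, log-density 0 everywhere
  expect_equal(beta_negloglik(0.3, 0.5, 2), 0)
  expect_equal(beta_negloglik(0.9, 0.5, 2), 0)

  # independent log-gamma arithmetic oracle
  y <- 0.2; mu <- 0.2; phi <- 10
  a <- mu * phi; b <- (1 - mu) * phi
  oracle <- -((a - 1) * log(y) + (b - 1) * log(1 - y) -
                (lgamma(a) + lgamma(b) - lgamma(a + b)))
  expect_equal(beta_negloglik(y, mu, phi), oracle, tolerance = 1e-10)

  # density symmetry around swapping y and mu with their complements
  expect_equal(beta_negloglik(0.27, 0.61, 7.3),
               beta_negloglik(0.73, 0.39, 7.3))

  # normalization: density integrates to 1 for sampled (mu, phi)
  for (par in list(c(0.2, 5), c(0.7, 40), c(0.5, 0.8))) {
    dens <- function(t) exp(-beta_negloglik(t, par[1], par[2]))
    expect_equal(stats::integrate(dens, 0, 1, rel.tol = 1e-8)$value, 1,
                 tolerance = 1e-6)
  }

  expect_error(beta_negloglik(0, 0.5, 2), "strictly")
  expect_error(beta_negloglik(0.5, 1, 2), "strictly")
  expect_error(beta_negloglik(0.5, 0.5, 0), "positive")
})

test_that("boosting finds a planted signal feature", {
  first_hits <- 0L
  coef_hits <- 0L
  for (s in 1:10) {
    d <- sim_beta_data(200, 21, seed = s)
    fit <- fit_boost(d$X, d$y, mstop = 150)
    if (fit$path$feature[1L] == "x1") first_hits <- first_hits + 1L
    if (names(which.max(abs(fit$coefficients))) == "x1") {
      coef_hits <- coef_hits + 1L
    }
  }
  expect_gte(first_hits, 9L)
  expect_gte(coef_hits, 9L)
})

test_that("mstop = 0 yields the intercept-only model", {
  d <- sim_beta_data(50, 5, seed = 2)
  fit <- fit_boost(d$X, d$y, mstop = 0L)
  expect_true(all(fit$coefficients == 0))
  expect_equal(unique(predict(fit, d$X)), mean(d$y), tolerance = 1e-12)
})

test_that("training risk is non-increasing along the path", {
  for (s in 1:3) {
    d <- sim_beta_data(120, 10, seed = 10 + s)
    fit <- fit_boost(d$X, d$y, mstop = 100)
    expect_true(all(diff(fit$path$risk) <= 1e-8))
  }
})

test_that("single-feature boosting converges to the direct ML fit", {
  d <- sim_beta_data(300, 1, beta1 = 1.5, seed = 4)
  fit <- fit_boost(d$X, d$y, nu = 0.3, mstop = 5000L)
  xs <- (d$X[, 1] - mean(d$X[, 1])) / sd(d$X[, 1])
  # oracle: full 3-parameter likelihood maximization with optim
  nll <- function(par) {
    mu <- pmin(pmax(plogis(par[1] + par[2] * xs), 1e-12), 1 - 1e-12)
    sum(beta_negloglik(d$y, mu, exp(par[3])))
  }
  opt <- stats::optim(c(qlogis(mean(d$y)), 0.5, log(10)), nll,
                      method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(fit$coefficients), opt$par[2], tolerance = 1e-3)
  expect_equal(fit$phi, exp(opt$par[3]), tolerance = 1e-2)
})

test_that("simulated beta-regression parameters are recovered", {
  d <- sim_beta_data(500, 3, beta1 = 1.2, phi = 15, seed = 6)
  fit <- fit_boost(d$X, d$y, nu = 0.3, mstop = 4000L)
  # coefficient is on the standardized scale; x1 has sd ~ 1
  slope_raw <- unname(fit$coefficients["x1"]) / sd(d$X[, 1])
  expect_equal(slope_raw, 1.2, tolerance = 0.12)
  expect_equal(fit$phi, 15, tolerance = 0.25 * 15)
})

test_that("boundary responses and degenerate matrices are rejected", {
  d <- sim_beta_data(30, 3, seed = 8)
  y_bad <- d$y; y_bad[1] <- 1
  expect_error(fit_boost(d$X, y_bad, mstop = 5), "strictly in \\(0, 1\\)")
  Xc <- matrix(1, 30, 2, dimnames = list(NULL, c("c1", "c2")))
  expect_error(fit_boost(Xc, d$y, mstop = 5), "constant")
  Xmix <- cbind(d$X, const = 1)
  expect_warning(fit <- fit_boost(Xmix, d$y, mstop = 5), "constant")
  expect_false("const" %in% fit$feature_names)
})

test_that("prediction reproduces in-sample fits and validates columns", {
  d <- sim_beta_data(80, 6, seed = 9)
  fit <- fit_boost(d$X, d$y, mstop = 60)
  mu_hat <- plogis(fit$offset +
                     as.numeric(scale(d$X,
                                      center = fit$standardization$center,
                                      scale = fit$standardization$scale)
                                %*% fit$coefficients))
  expect_equal(predict(fit, d$X), mu_hat, tolerance = 1e-12)
  expect_true(all(predict(fit, d$X * 3) > 0 &
                    predict(fit, d$X * 3) < 1))
  expect_error(predict(fit, d$X[, -1]), "x1")
  Xe <- cbind(d$X, junk = rnorm(80))
  expect_warning(predict(fit, Xe), "extra")
})

test_that("bootstrap tuning picks no iterations under pure noise and
           some under strong signal", {
  noise <- withr::with_seed(21, {
    X <- matrix(rnorm(50 * 10), 50, 10,
                dimnames = list(NULL, paste0("n", 1:10)))
    list(X = X, y = pmin(pmax(rbeta(50, 2, 3), 1e-3), 1 - 1e-3))
  })
  cv0 <- tune_mstop(noise$X, noise$y, grid = 0:60, seed = 3)
  expect_lte(cv0$mstop_opt, 5L)

  d <- sim_beta_data(100, 5, seed = 22)
  cv1 <- tune_mstop(d$X, d$y, grid = 0:200, seed = 3)
  expect_gt(cv1$mstop_opt, 0L)
  expect_equal(cv1$mean_risk[match(cv1$mstop_opt, cv1$grid)],
               min(cv1$mean_risk))

  cv2 <- tune_mstop(d$X, d$y, grid = 0:200, seed = 3)
  expect_identical(cv1$risks, cv2$risks)
  expect_error(tune_mstop(d$X, d$y, grid = integer(0)), "empty")
})

test_that("model JSON serialization preserves predictions bit-for-bit", {
  d <- sim_beta_data(60, 6, seed = 4)
  fit <- fit_boost(d$X, d$y, mstop = 50, seed = 4L)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_identical(predict(back, d$X), predict(fit, d$X))
  expect_identical(back$coefficients, fit$coefficients)
  expect_identical(back$phi, fit$phi)
})
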