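make_two_profile_data <- function(n = 400, m = 4, sep = 4, seed = 5) {
  sc <- simulation_scenario(n, m = m, T_true = 2, separation = sep,
                            base_seed = seed)
  gen <- generate_dataset(sc, 1)
  list(X = standardize_columns(gen$values), gen = gen, sc = sc)
}

test_that("one-profile EM equals the closed-form Gaussian MLE", {
  set.seed(41)
  X <- standardize_columns(matrix(rnorm(150 * 3), 150, 3))
  fit <- fit_em(X, 1)
  expect_equal(as.numeric(fit$means), colMeans(X), tolerance = 1e-10)
  mle_var <- colMeans(X^2) - colMeans(X)^2
  expect_equal(fit$precisions, 1 / mle_var, tolerance = 1e-8)
  direct <- sum(vapply(1:3, function(j)
    sum(dnorm(X[, j], mean(X[, j]), sqrt(mle_var[j]), log = TRUE)),
    numeric(1)))
  expect_equal(fit$loglik, direct, tolerance = 1e-8)
  expect_equal(fit$n_params, 1L * 3L + 3L + 0L)
})

test_that("EM recovers two separated profiles and reports a consistent loglik", {
  d <- make_two_profile_data()
  fit <- fit_em(d$X, 2)
  truth <- standardized_truth(d$sc, d$gen)
  expect_lt(min_perm_error(fit$means, truth), 0.15)
  # independent density re-evaluation at the returned parameters
  ll <- lpa_loglik(d$X, fit$means, fit$precisions, fit$weights)
  expect_equal(ll$loglik, fit$loglik, tolerance = 1e-8)
  expect_equal(ll$resp, fit$resp, tolerance = 1e-6)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_equal(rowSums(fit$resp), rep(1, 400), tolerance = 1e-9)
})

test_that("EM log-likelihood matches the mclust EEI oracle", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  d <- make_two_profile_data(n = 300, seed = 9)
  fit <- fit_em(d$X, 2)
  mc <- Mclust(d$X, G = 2, modelNames = "EEI", verbose = FALSE)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-3)
})

test_that("EM log-likelihood trace is non-decreasing", {
  d <- make_two_profile_data(n = 200, sep = 1.5, seed = 13)
  for (T_ in 2:4) {
    fit <- fit_em(d$X, T_, n_restarts = 3, seed = T_)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("loglik and information criteria are label-permutation invariant", {
  d <- make_two_profile_data(n = 200, m = 3, sep = 3, seed = 2)
  fit <- fit_em(d$X, 3, n_restarts = 5)
  perm <- c(3, 1, 2)
  ll_perm <- lpa_loglik(d$X, fit$means[perm, ], fit$precisions,
                        fit$weights[perm])
  expect_equal(ll_perm$loglik, fit$loglik, tolerance = 1e-10)
})

test_that("information criteria follow their definitions", {
  fake <- list(loglik = -100, n_params = 2L * 11L + 11L + 1L)
  ic <- information_criteria(fake, n = 50)
  expect_equal(fake$n_params, 34L)
  expect_equal(ic$aic, 268)
  expect_equal(ic$bic, 200 + 34 * log(50))
  fake1 <- list(loglik = -100, n_params = 2L)
  ic1 <- information_criteria(fake1, n = 77)
  expect_equal(ic1$aic, 204)
  expect_equal(ic1$bic, 200 + 2 * log(77))
  # identity bic - aic = k (log n - 2) on a real fit
  d <- make_two_profile_data(n = 120, m = 3, seed = 3)
  fit <- fit_em(d$X, 2, n_restarts = 3)
  ic <- information_criteria(fit, 120)
  expect_equal(ic$bic - ic$aic, fit$n_params * (log(120) - 2),
               tolerance = 1e-10)
})

test_that("BLRT attains its minimum p-value on clearly two-profile data", {
  d <- make_two_profile_data(n = 400, sep = 4, seed = 17)
  res <- blrt(d$X, 1, n_boot = 99, seed = 1, n_restarts = 5)
  expect_equal(res$p_value, 1 / 100)
  expect_true(all(res$bootstrap_lrs < res$observed_lr))
  expect_error(blrt(d$X, 1, n_boot = 0), "at least 1")
})

test_that("BLRT type-I error stays near the nominal level on one-profile data", {
  set.seed(55)
  n_rep <- 200
  rejections <- 0L
  for (r in seq_len(n_rep)) {
    X <- standardize_columns(matrix(rnorm(300 * 4), 300, 4))
    res <- blrt(X, 1, n_boot = 39, seed = 1000 + r, n_restarts = 2,
                boot_restarts = 2)
    rejections <- rejections + (res$p_value <= 0.05)
  }
  rate <- rejections / n_rep
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("finite Bayesian LPA matches the conjugate shrinkage at T = 1", {
  set.seed(66)
  raw <- matrix(rnorm(40 * 2, mean = 1.2), 40, 2)   # deliberately uncentered
  fit <- fit_finite_bayes(raw, 1, seed = 1)
  v <- dpm_priors()$mean_variance_multiplier
  shrunk <- colSums(raw) / (1 / v + 40)
  expect_equal(as.numeric(fit$means), shrunk, tolerance = 1e-8)
  expect_equal(rowSums(fit$resp), rep(1, 40), tolerance = 1e-9)
  expect_true(all(diff(fit$elbo_trace) >= -1e-8))
})

test_that("ELBO model selection finds the generating profile count", {
  sc <- simulation_scenario(300, m = 4, T_true = 3, separation = 3,
                            base_seed = 77)
  hits <- 0L
  for (r in 1:6) {
    X <- standardize_columns(generate_dataset(sc, r)$values)
    sel <- select_profiles(X, "finite_bayes_elbo", T_max = 6,
                           seed = 80 + r, n_restarts = 5)
    hits <- hits + (sel$selected == 3L)
  }
  expect_gte(hits, 5L)
})

test_that("BIC selection recovers a single profile on unstructured data", {
  hits <- 0L
  for (r in 1:5) {
    set.seed(90 + r)
    X <- standardize_columns(matrix(rnorm(200 * 3), 200, 3))
    sel <- select_profiles(X, "bic", T_max = 4, seed = 90 + r,
                           n_restarts = 5)
    hits <- hits + (sel$selected == 1L)
  }
  expect_equal(hits, 5L)
  expect_error(select_profiles(X, "bic", T_max = 1), "at least 2")
  expect_error(select_profiles(X, "nonsense"), "arg")
})
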