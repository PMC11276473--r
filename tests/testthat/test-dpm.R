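test_that("DP partition prior matches exact urn products on tiny cases", {
  expect_equal(log_dp_prior(1L, alpha = 2.7), 0)
  expect_equal(log_dp_prior(c(1, 1, 1), alpha = 1), log(1 / 3))
  expect_equal(log_dp_prior(c(1, 2, 3), alpha = 1), log(1 / 6))
  expect_error(log_dp_prior(integer(0), 1), "empty")
  expect_error(log_dp_prior(c(1, 3), 1), "contiguous")
})

test_that("DP prior equals the sequential Polya-urn product on random assignments", {
  set.seed(21)
  for (r in 1:30) {
    n <- sample(2:12, 1)
    alpha <- runif(1, 0.1, 5)
    z <- to_rgs(sample.int(sample(1:4, 1), n, replace = TRUE))
    expect_equal(log_dp_prior(z, alpha), urn_log_prior(z, alpha),
                 tolerance = 1e-10)
  }
})

test_that("DP prior is exchangeable over participant order", {
  set.seed(22)
  z <- to_rgs(sample.int(3, 40, replace = TRUE))
  for (r in 1:10) {
    zp <- to_rgs(z[sample.int(40)])
    expect_equal(log_dp_prior(zp, 0.7), log_dp_prior(z, 0.7), tolerance = 1e-10)
  }
})

test_that("DP prior decreases as profiles proliferate under split-in-half growth", {
  split_sizes <- function(T_) {
    out <- 5000L
    for (k in seq_len(T_ - 1L)) {
      last <- out[length(out)]
      out <- c(out[-length(out)], floor(last / 2), ceiling(last / 2))
    }
    out
  }
  for (alpha in c(0.1, 1, 10)) {
    lp <- vapply(2:8, function(T_) {
      sizes <- split_sizes(T_)
      log_dp_prior(rep(seq_along(sizes), sizes), alpha)
    }, numeric(1))
    expect_true(all(diff(lp) < 0))
  }
})

test_that("extract_profiles applies the argmax-empty rule and size ordering", {
  fake_state <- function(resp, m = 2L) {
    K <- ncol(resp)
    structure(list(resp = resp,
                   mean_params = list(location = matrix(seq_len(m * K), m, K),
                                      variance = matrix(1, m, K)),
                   precision_params = cbind(shape = rep(2, m),
                                            rate = rep(1, m))),
              class = "variational_state")
  }
  # all mass on component 1
  ps <- extract_profiles(fake_state(cbind(rep(1, 5), 0, 0)))
  expect_equal(ps$T, 1L)
  expect_equal(ps$counts, 5L)
  # component 3 never argmax -> dropped even though it has mass
  resp <- rbind(c(0.5, 0.2, 0.3), c(0.2, 0.5, 0.3), c(0.6, 0.1, 0.3))
  ps <- extract_profiles(fake_state(resp))
  expect_equal(ps$T, 2L)
  expect_equal(ps$counts, c(2L, 1L))
  expect_equal(rowSums(ps$resp), rep(1, 3), tolerance = 1e-12)
  # counts (10, 50, 40) relabel to (50, 40, 10)
  resp <- diag(3)[rep(c(1, 2, 3), c(10, 50, 40)), ]
  ps <- extract_profiles(fake_state(resp))
  expect_equal(ps$counts, c(50L, 40L, 10L))
  # relabeled means follow the reordering of components (2, 3, 1)
  expect_equal(ps$means, t(matrix(1:6, 2, 3)[, c(2, 3, 1)]))
})

test_that("single-population data yields one retained profile", {
  set.seed(23)
  X <- standardize_columns(matrix(rnorm(200 * 4), 200, 4))
  fit <- fit_dpm(X, seed = 1, n_restarts = 5)
  expect_equal(fit$profiles$T, 1L)
  expect_equal(sum(fit$profiles$counts), 200L)
})

test_that("well-separated profiles are recovered with perfect agreement", {
  sc <- simulation_scenario(300, m = 4, T_true = 3, separation = 4,
                            base_seed = 31)
  gen <- generate_dataset(sc, 1)
  X <- standardize_columns(gen$values)
  fit <- fit_dpm(X, seed = 5)
  expect_equal(fit$profiles$T, 3L)
  hard <- hard_assign(fit$profiles$resp)
  expect_equal(adjusted_rand(hard, gen$true_labels), 1)
})

test_that("the ELBO trace is non-decreasing for every restart", {
  sc <- simulation_scenario(150, m = 3, T_true = 3, separation = 2,
                            base_seed = 8)
  X <- standardize_columns(generate_dataset(sc, 1)$values)
  for (k in c(2L, 5L, 10L)) {
    phi0 <- dpmlpa:::init_resp(X, 10L, seed = k, k_init = k)
    run <- dpmlpa:::dpm_vb_run(X, phi0, dpm_priors(), tol = 1e-6,
                               max_iter = 500L)
    expect_true(all(diff(run$elbo_trace) >= -1e-8))
  }
  fit <- fit_dpm(X, truncation = 10L, seed = 3, n_restarts = 4)
  expect_true(all(diff(fit$state$elbo_trace) >= -1e-8))
})

test_that("responsibility rows stay normalized and base rates sum to one", {
  sc <- simulation_scenario(120, m = 3, T_true = 2, separation = 3,
                            base_seed = 19)
  X <- standardize_columns(generate_dataset(sc, 1)$values)
  fit <- fit_dpm(X, truncation = 8L, seed = 2, n_restarts = 4)
  expect_equal(rowSums(fit$state$resp), rep(1, 120), tolerance = 1e-9)
  expect_equal(rowSums(fit$profiles$resp), rep(1, 120), tolerance = 1e-9)
  expect_equal(sum(fit$profiles$base_rates), 1, tolerance = 1e-9)
  expect_error(fit_dpm(matrix(c(NA, 1, 2, 3), 2, 2)), "non-finite")
  expect_error(fit_dpm(X, truncation = 1L), "truncation")
})

test_that("retained profile count is insensitive to doubling the truncation", {
  sc <- simulation_scenario(250, base_seed = 60)
  differing <- 0L
  for (r in 1:8) {
    X <- standardize_columns(generate_dataset(sc, r)$values)
    T20 <- fit_dpm(X, truncation = 20L, seed = 70 + r)$profiles$T
    T40 <- fit_dpm(X, truncation = 40L, seed = 70 + r)$profiles$T
    differing <- differing + (T20 != T40)
  }
  expect_lte(differing, 1L)
})
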