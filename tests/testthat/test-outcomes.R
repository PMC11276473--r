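test_that("hard assignment follows argmax with low-label tie-breaking", {
  expect_equal(hard_assign(diag(3)[c(2, 3, 1), ]), c(2L, 3L, 1L))
  expect_equal(hard_assign(rbind(c(0.5, 0.5))), 1L)
  expect_equal(hard_assign(rbind(c(0.2, 0.5, 0.3))), 2L)
})

test_that("partition enumeration counts equal Bell numbers through T = 8", {
  bells <- c(1, 2, 5, 15, 52, 203, 877, 4140)
  for (T_ in 1:8)
    expect_length(enumerate_partitions(T_), bells[T_])
  # restricted-growth form: first appearances in order
  for (p in enumerate_partitions(4)) {
    expect_equal(sort(unique(p$block_of)), seq_len(p$n_blocks))
    expect_equal(unique(p$block_of), seq_len(p$n_blocks))
  }
  expect_equal(format_partition(list(block_of = c(1L, 1L, 2L))), "{1,2},{3}")
  expect_error(enumerate_partitions(12, cap = 1e4), "cap")
})

test_that("closed-form partition evidence matches the quadrature oracle", {
  set.seed(101)
  priors <- list(outcome_priors(),
                 outcome_priors(2, 3, 0.5),
                 outcome_priors(0.5, 1, 2))
  cases <- list(
    list(y = c(0), labels = c(1L), T = 1L),
    list(y = c(0.4, -1.2, 0.8), labels = c(1L, 1L, 1L), T = 1L),
    list(y = rnorm(8), labels = rep(1:2, 4), T = 2L),
    list(y = c(rnorm(4), rnorm(4, 2), rnorm(4, -1)),
         labels = rep(1:3, each = 4), T = 3L),
    list(y = c(rnorm(10), NA, NA), labels = rep(1:3, 4), T = 3L))
  for (prior in priors) {
    for (cs in cases) {
      for (p in enumerate_partitions(cs$T)) {
        lo <- quad_log_evidence(cs$y, cs$labels, p, prior)
        cf <- log_partition_evidence(cs$y, cs$labels, p, prior)
        expect_lt(abs(expm1(cf - lo)), 1e-6)
      }
    }
  }
})

test_that("the all-one-block evidence is the single-mean null evidence", {
  set.seed(102)
  y <- rnorm(12)
  labels <- rep(1:3, 4)
  merged <- log_partition_evidence(y, labels, list(block_of = rep(1L, 3)))
  single <- log_partition_evidence(y, rep(1L, 12), list(block_of = 1L))
  expect_equal(merged, single, tolerance = 1e-12)
})

test_that("Bayes factor is reproducible from the partition search output", {
  set.seed(103)
  y <- c(rnorm(15), rnorm(15, 1))
  labels <- rep(1:2, each = 15)
  bf <- bayes_factor_anova(y, labels, 2)
  search <- posthoc_partition_search(y, labels, 2)
  tab <- search$partition_log_evidences
  l1 <- tab$log_evidence[tab$partition == "{1},{2}"]
  l0 <- tab$log_evidence[tab$partition == "{1,2}"]
  expect_equal(bf$log10_bf10, (l1 - l0) / log(10), tolerance = 1e-12)
  expect_equal(bf$bf10, 10^bf$log10_bf10)
  expect_error(bayes_factor_anova(y, labels, 1), "at least 2")
})

test_that("Bayes factor supports the null on exchangeable outcomes", {
  set.seed(104)
  negatives <- 0L
  for (r in 1:20) {
    y <- rnorm(40)
    labels <- rep(1:2, each = 20)
    negatives <- negatives + (bayes_factor_anova(y, labels, 2)$log10_bf10 < 0)
  }
  expect_gte(negatives, 15L)
})

test_that("Bayes factor strongly supports planted profile differences", {
  for (r in 1:3) {
    set.seed(110 + r)
    y <- c(rnorm(50, 0), rnorm(50, 3))
    y <- (y - mean(y)) / sd(y)
    labels <- rep(1:2, each = 50)
    expect_gt(bayes_factor_anova(y, labels, 2)$log10_bf10, 2)
  }
})

test_that("partition search groups the two equal profiles together", {
  for (r in 1:3) {
    set.seed(120 + r)
    y <- c(rnorm(60, 0), rnorm(60, 0), rnorm(60, 5))
    y <- (y - mean(y)) / sd(y)
    labels <- rep(1:3, each = 60)
    best <- posthoc_partition_search(y, labels, 3)$best_partition
    expect_equal(best$block_of, c(1L, 1L, 2L))
  }
})

test_that("posterior profile means apply the conjugate shrinkage", {
  # single profile, y = (2, 2): shrink ybar = 2 by one prior pseudo-obs
  post <- posterior_profile_means(c(2, 2), c(1L, 1L), 1L)
  expect_equal(post$mean, 4 / 3, tolerance = 1e-12)
  expect_lt(post$ci_lower, 4 / 3)
  expect_gt(post$ci_upper, 4 / 3)
  # symmetric data: location 0
  post <- posterior_profile_means(c(1, -1), c(1L, 1L), 1L)
  expect_equal(post$mean, 0, tolerance = 1e-12)
  # empty profile keeps the prior location
  post <- posterior_profile_means(c(1, 2, 3), c(1L, 1L, 1L), 2L)
  expect_equal(post$mean[2], 0)
  expect_equal(post$n, c(3L, 0L))
  # large-sample location approaches the profile average
  set.seed(130)
  y <- rnorm(500, 0.8, 0.5)
  post <- posterior_profile_means(y, rep(1L, 500), 1L)
  expect_equal(post$mean, mean(y) * 500 / 501, tolerance = 1e-10)
})

test_that("effect size r2 matches hand computation and affine invariance", {
  expect_equal(effect_size_r2(c(0, 2, 4, 6), c(1, 1, 2, 2), c(1, 5)),
               0.8)
  y <- c(1, 2, 3, 4)
  expect_equal(effect_size_r2(y, rep(1L, 4), mean(y)), 0)
  expect_equal(effect_size_r2(y, 1:4, y), 1)
  set.seed(140)
  y <- rnorm(30); labels <- rep(1:3, 10); mu <- c(-1, 0, 1)
  r2 <- effect_size_r2(y, labels, mu)
  expect_equal(effect_size_r2(2 * y + 3, labels, 2 * mu + 3), r2,
               tolerance = 1e-12)
  expect_error(effect_size_r2(c(1, 1), c(1L, 1L), 1), "zero total")
})

test_that("validate_outcome assembles a coherent report", {
  set.seed(150)
  resp <- diag(3)[rep(1:3, each = 40), ]
  y <- c(rnorm(40, -0.8), rnorm(40, 0), rnorm(40, 0.8))
  res <- validate_outcome(outcome_vector(y), resp)
  expect_s3_class(res, "anova_result")
  expect_equal(res$verdict, "supports_H1")
  expect_gt(res$r2, 0)
  expect_equal(res$bf10, 10^res$log10_bf10)
  expect_equal(nrow(res$profile_posteriors), 3L)
  # profile means ordered as planted
  expect_true(all(diff(res$profile_posteriors$mean) > 0))
  # an uninformative outcome is not declared conclusive in either direction
  y0 <- rnorm(120)
  res0 <- validate_outcome(outcome_vector(y0), resp)
  expect_true(res0$verdict %in% c("inconclusive", "supports_H0"))
})
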