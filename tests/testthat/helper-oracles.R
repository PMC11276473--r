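# Independent oracles used across the test files.

# Marginal likelihood of the blocked outcome model by nested numerical
# quadrature: for each block, integrate the block mean against its
# normal prior given the precision; then integrate the precision
# against its gamma prior.  Independent of the closed-form path.
quad_log_evidence <- function(y, labels, partition, prior = outcome_priors()) {
  obs <- if (inherits(y, "outcome_vector")) {
    keep <- !y$missing_mask
    list(y = y$values[keep], labels = labels[keep])
  } else {
    keep <- !is.na(y)
    list(y = y[keep], labels = labels[keep])
  }
  block <- partition$block_of[obs$labels]
  a0 <- prior$precision_shape; b0 <- prior$precision_rate
  v <- prior$mean_variance_multiplier
  blocks <- sort(unique(block))
  lik_given_xi <- function(xi) {
    out <- 1
    for (bk in blocks) {
      yb <- obs$y[block == bk]
      inner <- stats::integrate(function(th) {
        vapply(th, function(t0)
          prod(stats::dnorm(yb, t0, sqrt(1 / xi))) *
            stats::dnorm(t0, 0, sqrt(v / xi)), numeric(1))
      }, -Inf, Inf, rel.tol = 1e-12, abs.tol = 0)$value
      out <- out * inner
    }
    out
  }
  total <- stats::integrate(function(xis) {
    vapply(xis, function(xi) lik_given_xi(xi) * stats::dgamma(xi, a0, b0),
           numeric(1))
  }, 0, Inf, rel.tol = 1e-11, abs.tol = 0)$value
  log(total)
}

# Sequential Polya-urn evaluation of the partition prior: observation i
# joins an existing profile with probability n_t/(i-1+alpha) or founds
# a new one with probability alpha/(i-1+alpha).
urn_log_prior <- function(assignments, alpha) {
  lp <- 0
  counts <- integer(0)
  for (i in seq_along(assignments)) {
    z <- assignments[i]
    denom <- (i - 1) + alpha
    if (z > length(counts)) {
      lp <- lp + log(alpha / denom)
      counts <- c(counts, 1L)
    } else {
      lp <- lp + log(counts[z] / denom)
      counts[z] <- counts[z] + 1L
    }
  }
  lp
}

# relabel an arbitrary label vector to restricted-growth (first
# appearance order) form
to_rgs <- function(z) {
  u <- unique(z)
  match(z, u)
}

# Adjusted Rand index between two hard clusterings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  mx <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (mx - expected)
}

# smallest maximum absolute difference between two T x m mean matrices
# over all row permutations (exact, for small T)
min_perm_error <- function(est, truth) {
  T_ <- nrow(truth)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(T_)),
             function(p) max(abs(est - truth[p, , drop = FALSE])),
             numeric(1)))
}

# standardized-scale generating means for a scenario replicate
standardized_truth <- function(scenario, gen) {
  mu <- scenario_means(scenario)
  cm <- colMeans(gen$values)
  csd <- apply(gen$values, 2, stats::sd)
  sweep(sweep(mu, 2, cm, "-"), 2, csd, "/")
}
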