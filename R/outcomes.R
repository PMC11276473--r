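#' Prior specification for outcome analyses
#'
#' Normal-gamma conjugate prior for a profile-wise outcome model: a
#' shared outcome precision `xi_y ~ Gamma(shape, rate)` (default
#' Gamma(1, 1)) and per-profile outcome means
#' `mu_t | xi_y ~ N(0, v / xi_y)` with `v = mean_variance_multiplier`
#' (default 1). Appropriate for z-scored outcomes.
#'
#' @param precision_shape,precision_rate Gamma prior on the shared
#'   outcome precision. Defaults 1, 1.
#' @param mean_variance_multiplier Prior variance multiple for profile
#'   outcome means. Default 1.
#' @return List of class `outcome_priors`.
#' @export
outcome_priors <- function(precision_shape = 1, precision_rate = 1,
                           mean_variance_multiplier = 1) {
  vals <- c(precision_shape, precision_rate, mean_variance_multiplier)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all prior hyperparameters must be strictly positive")
  structure(list(precision_shape = precision_shape,
                 precision_rate = precision_rate,
                 mean_variance_multiplier = mean_variance_multiplier),
            class = "outcome_priors")
}

#' Hard profile assignment from responsibilities
#'
#' Maps each participant to the maximally probable profile; ties go to
#' the lowest profile label.
#'
#' @param resp n x T responsibility matrix.
#' @return Integer vector of length n with labels in `1..T`.
#' @export
hard_assign <- function(resp) {
  resp <- as.matrix(resp)
  max.col(resp, ties.method = "first")
}

# ---- set partitions --------------------------------------------------------

#' Enumerate all set partitions of 1..T
#'
#' Generates every partition of the profile labels in restricted-growth
#' form: block indices are contiguous `1..n_blocks` in order of first
#' appearance. The number of partitions is the Bell number B(T)
#' (1, 2, 5, 15, 52, 203, 877, 4140, ... for T = 1, 2, ...).
#'
#' @param T Number of items (profiles).
#' @param cap Refuse to enumerate more than this many partitions
#'   (default 1e6).
#' @return List of partitions; each is a list with `block_of` (length-T
#'   integer vector) and `n_blocks`.
#' @export
enumerate_partitions <- function(T, cap = 1e6) {
  T <- as.integer(T)
  if (T < 1L) stop("T must be at least 1")
  if (bell_number(T) > cap)
    stop("Bell(", T, ") exceeds the enumeration cap (", format(cap),
         "); merge profiles or raise `cap`")
  out <- vector("list", 0L)
  recurse <- function(prefix, maxb) {
    if (length(prefix) == T) {
      out[[length(out) + 1L]] <<- list(block_of = prefix,
                                       n_blocks = max(prefix))
      return(invisible(NULL))
    }
    for (bx in seq_len(maxb + 1L)) {
      recurse(c(prefix, bx), max(maxb, bx))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Bell number by the Bell-triangle recurrence (double precision)
bell_number <- function(T) {
  row <- 1
  for (k in seq_len(T - 1L)) row <- cumsum(c(row[length(row)], row))
  row[length(row)]
}

#' Format a partition in block notation
#'
#' @param partition A partition (list with `block_of`).
#' @return String such as `"{1,2},{3}"`.
#' @export
format_partition <- function(partition) {
  b <- partition$block_of
  paste(vapply(seq_len(max(b)), function(k) {
    paste0("{", paste(which(b == k), collapse = ","), "}")
  }, character(1)), collapse = ",")
}

# ---- conjugate evidence ----------------------------------------------------

# pull observed y and matching labels out of an outcome_vector (or
# plain numeric vector) given per-participant profile labels
observed_outcome <- function(y, labels) {
  if (inherits(y, "outcome_vector")) {
    keep <- !y$missing_mask
    list(y = y$values[keep], labels = as.integer(labels)[keep])
  } else {
    y <- as.numeric(y)
    keep <- !is.na(y)
    list(y = y[keep], labels = as.integer(labels)[keep])
  }
}

#' Log marginal likelihood of an outcome under a profile partition
#'
#' Closed-form evidence of the model in which all profiles within a
#' block of `partition` share one outcome mean, blocks have distinct
#' means, and all observations share one precision, under the
#' normal-gamma prior of [outcome_priors()]. Integrating the block
#' means given the precision and then the precision gives
#' \deqn{\log p(y) = \sum_b [-(n_b/2)\log 2\pi - \tfrac12 \log(1 + v n_b)]
#'   + a_0 \log b_0 - \log\Gamma(a_0) + \log\Gamma(a_0 + n/2)
#'   - (a_0 + n/2) \log(b_0 + \tfrac12 \sum_b Q_b)}
#' with \eqn{Q_b = \sum y^2 - v (\sum y)^2 / (1 + v n_b)} over the
#' observations in block b.
#'
#' The all-one-block partition is the evidence of the single-mean null
#' model; the all-distinct partition is the evidence of the full
#' profile-means model.
#'
#' @param y An [outcome_vector] or numeric vector (NA = missing).
#' @param labels Per-participant profile labels in `1..T`.
#' @param partition A partition of the profile labels (list with
#'   `block_of`).
#' @param prior An [outcome_priors] specification.
#' @return Natural-log marginal likelihood.
#' @export
log_partition_evidence <- function(y, labels, partition,
                                   prior = outcome_priors()) {
  obs <- observed_outcome(y, labels)
  if (length(obs$y) == 0L) stop("no observed outcome values")
  if (max(obs$labels) > length(partition$block_of))
    stop("labels exceed the partition domain")
  block <- partition$block_of[obs$labels]
  a0 <- prior$precision_shape; b0 <- prior$precision_rate
  v <- prior$mean_variance_multiplier
  n <- length(obs$y)
  nb <- tapply(obs$y, block, length)
  sb <- tapply(obs$y, block, sum)
  ssb <- tapply(obs$y, block, function(u) sum(u^2))
  Q <- ssb - v * sb^2 / (1 + v * nb)
  sum(-(nb / 2) * log(2 * pi) - 0.5 * log1p(v * nb)) +
    a0 * log(b0) - lgamma(a0) + lgamma(a0 + n / 2) -
    (a0 + n / 2) * log(b0 + sum(Q) / 2)
}

#' Bayes-factor ANOVA across profile outcome means
#'
#' Compares H0 (all T profile outcome means equal) against H1 (means
#' all distinct) by the ratio of marginal likelihoods,
#' `BF10 = p(y | H1) / p(y | H0)`, computed in closed form from the
#' conjugate normal-gamma structure. Positive `log10_bf10` supports
#' profile differences; by convention `|log10_bf10| < 0.5` is
#' inconclusive.
#'
#' @inheritParams log_partition_evidence
#' @param T Number of profiles (>= 2).
#' @return List with `log10_bf10` and `bf10`.
#' @export
bayes_factor_anova <- function(y, labels, T, prior = outcome_priors()) {
  T <- as.integer(T)
  if (T < 2L) stop("the alternative hypothesis needs at least 2 profiles")
  null_part <- list(block_of = rep(1L, T), n_blocks = 1L)
  full_part <- list(block_of = seq_len(T), n_blocks = T)
  l1 <- log_partition_evidence(y, labels, full_part, prior)
  l0 <- log_partition_evidence(y, labels, null_part, prior)
  log10_bf10 <- (l1 - l0) / log(10)
  list(log10_bf10 = log10_bf10, bf10 = 10^log10_bf10)
}

#' Posterior outcome means per profile with credible intervals
#'
#' Conjugate posterior of the profile-wise outcome model with hard
#' profile assignments: given the shared precision, each profile mean
#' is normal with posterior location `n_t * ybar_t / (1/v + n_t)`
#' (shrinkage of the profile average toward 0 by the prior
#' pseudo-observation weight `1/v`); marginalizing the Gamma posterior
#' of the precision makes each mean a scaled, shifted Student-t, from
#' which central 95% credible intervals are taken (2.5th to 97.5th
#' percentiles). A profile with no observed outcomes keeps the prior
#' location 0.
#'
#' @inheritParams log_partition_evidence
#' @param T Number of profiles.
#' @param ci_level Credible-interval mass (default 0.95).
#' @return Data frame with one row per profile: `profile`, `n`,
#'   `mean` (posterior location), `ci_lower`, `ci_upper`; attributes
#'   `precision_shape`/`precision_rate` give the Gamma posterior of the
#'   shared precision.
#' @export
posterior_profile_means <- function(y, labels, T, prior = outcome_priors(),
                                    ci_level = 0.95) {
  T <- as.integer(T)
  if (T < 1L) stop("T must be at least 1")
  obs <- observed_outcome(y, labels)
  if (any(obs$labels < 1L | obs$labels > T)) stop("labels must lie in 1..T")
  a0 <- prior$precision_shape; b0 <- prior$precision_rate
  v <- prior$mean_variance_multiplier
  n <- length(obs$y)
  nt <- vapply(seq_len(T), function(t) sum(obs$labels == t), numeric(1))
  st <- vapply(seq_len(T), function(t) sum(obs$y[obs$labels == t]), numeric(1))
  sst <- vapply(seq_len(T), function(t) sum(obs$y[obs$labels == t]^2), numeric(1))
  Q <- sst - v * st^2 / (1 + v * nt)
  an <- a0 + n / 2
  bn <- b0 + sum(Q) / 2
  loc <- st / (1 / v + nt)
  scale <- sqrt(bn / (an * (1 / v + nt)))
  qt_hi <- stats::qt(1 - (1 - ci_level) / 2, df = 2 * an)
  out <- data.frame(profile = seq_len(T), n = as.integer(nt), mean = loc,
                    ci_lower = loc - qt_hi * scale,
                    ci_upper = loc + qt_hi * scale)
  attr(out, "precision_shape") <- an
  attr(out, "precision_rate") <- bn
  out
}

#' Exhaustive partition post-hoc search
#'
#' Enumerates every set partition of the T profiles (the possible
#' post-hoc conclusions: which groups of profiles share an outcome
#' mean) and scores each by its closed-form marginal likelihood. The
#' maximum-evidence partition is the best description of the data;
#' ties go to the first partition in enumeration order.
#'
#' @inheritParams bayes_factor_anova
#' @param cap Enumeration cap passed to [enumerate_partitions()].
#' @return List with `best_partition` and `partition_log_evidences`
#'   (data frame of partition strings and log evidences, plus a
#'   `partitions` attribute holding the partition objects).
#' @export
posthoc_partition_search <- function(y, labels, T, prior = outcome_priors(),
                                     cap = 1e6) {
  parts <- enumerate_partitions(T, cap = cap)
  lev <- vapply(parts, function(p) log_partition_evidence(y, labels, p, prior),
                numeric(1))
  tab <- data.frame(partition = vapply(parts, format_partition, character(1)),
                    log_evidence = lev)
  attr(tab, "partitions") <- parts
  list(best_partition = parts[[which.max(lev)]],
       partition_log_evidences = tab)
}

#' Proportional-reduction-in-error effect size
#'
#' `r^2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)` where each
#' participant's prediction is their assigned profile's outcome mean.
#' Computed over observed outcomes only.
#'
#' @inheritParams log_partition_evidence
#' @param profile_means Length-T vector of profile outcome means.
#' @return Effect size in `[0, 1]` (may be slightly negative if the
#'   supplied means fit worse than the grand mean).
#' @export
effect_size_r2 <- function(y, labels, profile_means) {
  obs <- observed_outcome(y, labels)
  if (length(obs$y) < 2L) stop("need at least 2 observed outcome values")
  yhat <- profile_means[obs$labels]
  sst <- sum((obs$y - mean(obs$y))^2)
  if (sst == 0) stop("outcome has zero total sum of squares")
  1 - sum((obs$y - yhat)^2) / sst
}

#' Validate profiles against one outcome
#'
#' Full outcome analysis for a fitted profile model: hard assignment,
#' Bayes-factor ANOVA of profile differences, exhaustive partition
#' post-hoc search, per-profile posterior outcome means with 95%
#' credible intervals, and the r-squared effect size.
#'
#' @param y An [outcome_vector] (or numeric vector, NA = missing).
#' @param resp n x T responsibility matrix (e.g. `fit$profiles$resp`).
#' @param prior An [outcome_priors] specification.
#' @return List of class `anova_result`: `log10_bf10`, `bf10`, `r2`,
#'   `best_partition`, `partition_log_evidences`, `profile_posteriors`,
#'   `verdict` (`supports_H1`, `supports_H0` or `inconclusive` when
#'   `|log10_bf10| < 0.5`).
#' @export
validate_outcome <- function(y, resp, prior = outcome_priors()) {
  resp <- as.matrix(resp)
  T <- ncol(resp)
  labels <- hard_assign(resp)
  bf <- bayes_factor_anova(y, labels, T, prior)
  post <- posterior_profile_means(y, labels, T, prior)
  search <- posthoc_partition_search(y, labels, T, prior)
  r2 <- effect_size_r2(y, labels, post$mean)
  verdict <- if (abs(bf$log10_bf10) < 0.5) "inconclusive"
             else if (bf$log10_bf10 > 0) "supports_H1" else "supports_H0"
  structure(list(log10_bf10 = bf$log10_bf10, bf10 = bf$bf10, r2 = r2,
                 best_partition = search$best_partition,
                 partition_log_evidences = search$partition_log_evidences,
                 profile_posteriors = post,
                 verdict = verdict),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Bayes-factor ANOVA: log10(BF10) =", format(x$log10_bf10, digits = 4),
      "->", x$verdict, "\n")
  cat("r^2 =", format(x$r2, digits = 4),
      "| best partition:", format_partition(x$best_partition), "\n")
  invisible(x)
}
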