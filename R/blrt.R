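#' Bootstrap likelihood ratio test for T vs T+1 profiles
#'
#' Tests whether adding one more latent profile improves model fit. The
#' observed statistic is `2 * (loglik_{T+1} - loglik_T)` on the data;
#' its null distribution is approximated by a parametric bootstrap:
#' each replicate simulates a dataset of the same size from the fitted
#' T-profile model, refits both sizes, and records the resulting LR.
#' The p-value uses the add-one estimator
#' `(1 + #(LR_boot >= LR_obs)) / (n_boot + 1)`, which avoids p = 0 and
#' makes `1 / (n_boot + 1)` the smallest attainable value.
#'
#' @param data An [indicator_matrix] or numeric matrix (standardized).
#' @param T Null number of profiles (alternative is T + 1).
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param n_restarts Restarts for the fits on the observed data.
#' @param boot_restarts Restarts for each bootstrap refit (fewer, as is
#'   standard for bootstrap draws).
#' @param ... Passed to [fit_em()] (`tol`, `max_iter`, `var_floor`).
#' @return List of class `blrt_result`: `observed_lr`,
#'   `bootstrap_lrs`, `p_value`, `n_boot`, `T`.
#' @export
blrt <- function(data, T, n_boot = 100L, seed = 1L, n_restarts = 20L,
                 boot_restarts = 5L, ...) {
  if (n_boot < 1L) stop("n_boot must be at least 1")
  X <- if (inherits(data, "indicator_matrix")) data$values else as.matrix(data)
  fit0 <- fit_em(X, T, n_restarts = n_restarts, seed = seed, ...)
  fit1 <- fit_em(X, T + 1L, n_restarts = n_restarts, seed = seed + 1L, ...)
  observed_lr <- 2 * (fit1$loglik - fit0$loglik)
  boot_lrs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    bseed <- seed + 1000L * b
    Xb <- simulate_lpa(fit0, nrow(X), seed = bseed)
    b0 <- fit_em(Xb, T, n_restarts = boot_restarts, seed = bseed + 1L,
                 init = "random", ...)
    b1 <- fit_em(Xb, T + 1L, n_restarts = boot_restarts, seed = bseed + 2L,
                 init = "random", ...)
    boot_lrs[b] <- 2 * (b1$loglik - b0$loglik)
  }
  p <- (1 + sum(boot_lrs >= observed_lr)) / (n_boot + 1)
  structure(list(observed_lr = observed_lr, bootstrap_lrs = boot_lrs,
                 p_value = p, n_boot = as.integer(n_boot), T = as.integer(T)),
            class = "blrt_result")
}

#' @export
print.blrt_result <- function(x, ...) {
  cat("BLRT", x$T, "vs", x$T + 1L, "profiles: LR =",
      format(x$observed_lr, digits = 6), ", p =",
      format(x$p_value, digits = 4), "(", x$n_boot, "bootstraps )\n")
  invisible(x)
}

#' Simulate data from a fitted LPA model
#'
#' Parametric draw from a shared-diagonal Gaussian mixture: profile
#' labels from the mixing proportions, then independent normal
#' indicators around the profile means.
#'
#' @param fit An `lpa_fit` (or any list with `weights`, `means`,
#'   `precisions`).
#' @param n Number of rows to simulate.
#' @param seed Integer seed.
#' @return Numeric n x m matrix.
#' @export
simulate_lpa <- function(fit, n, seed = 1L) {
  set.seed(seed)
  m <- ncol(fit$means)
  z <- sample.int(nrow(fit$means), n, replace = TRUE, prob = fit$weights)
  fit$means[z, , drop = FALSE] +
    matrix(stats::rnorm(n * m, sd = rep(sqrt(1 / fit$precisions), each = n)), n, m)
}
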