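#' Fit conventional LPA by maximum likelihood (EM)
#'
#' Fits a T-profile Gaussian finite mixture with profile-specific means
#' and a shared diagonal covariance matrix (variances equal across
#' profiles, free across indicators) by expectation maximization. EM is
#' a local optimizer, so the fit is restarted from `n_restarts`
#' k-means-seeded initializations and the restart with the highest
#' log-likelihood is returned. A small variance floor guards against
#' degenerate likelihood spikes; a component whose responsibility mass
#' collapses below `1e-8 * n` despite re-initialization attempts flags
#' the fit as non-converged.
#'
#' @param data An [indicator_matrix] or numeric matrix (standardized).
#' @param T Number of latent profiles.
#' @param n_restarts Random restarts (default 20).
#' @param seed Integer seed.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations per restart.
#' @param var_floor Lower bound on the shared indicator variances.
#' @param init Restart initialization: `"kmeans"` (default) or the
#'   cheaper `"random"` nearest-random-rows start used for bootstrap
#'   refits.
#' @return List of class `lpa_fit`: `T`, `means` (T x m), `precisions`
#'   (m), `weights`, `resp`, `loglik`, `loglik_trace`, `n_params`,
#'   `converged`, `seed`.
#' @export
fit_em <- function(data, T, n_restarts = 20L, seed = 1L, tol = 1e-8,
                   max_iter = 2000L, var_floor = 1e-6, init = "kmeans") {
  X <- if (inherits(data, "indicator_matrix")) data$values else as.matrix(data)
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite values in data")
  T <- as.integer(T)
  if (T < 1L || T > nrow(X)) stop("T must be between 1 and n")
  n <- nrow(X); m <- ncol(X)
  if (T == 1L) n_restarts <- 1L
  best <- NULL
  for (r in seq_len(n_restarts)) {
    phi0 <- init_resp(X, T, seed = seed + (r - 1L), method = init)
    run <- .em_run_cpp(X, phi0, tol, max_iter, var_floor)
    if (is.finite(run$loglik) &&
        (is.null(best) || run$loglik > best$loglik))
      best <- run
  }
  if (is.null(best)) stop("every EM restart failed to produce a finite log-likelihood")
  structure(list(T = T,
                 means = best$mu,
                 precisions = as.numeric(1 / best$sigma2),
                 weights = as.numeric(best$weights),
                 resp = best$resp,
                 loglik = best$loglik,
                 loglik_trace = as.numeric(best$trace),
                 n_params = T * m + m + (T - 1L),
                 converged = isTRUE(best$converged) && !isTRUE(best$collapsed),
                 seed = seed),
            class = "lpa_fit")
}

#' @export
print.lpa_fit <- function(x, ...) {
  cat("LPA fit (EM):", x$T, "profile(s); loglik",
      format(x$loglik, digits = 8), "|", x$n_params, "parameters",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Mixture log-likelihood of an LPA model on a dataset
#'
#' Evaluates the observed-data log-likelihood of a shared-diagonal
#' Gaussian mixture at given parameters, plus the posterior membership
#' probabilities. Used for fit reporting and as a direct re-evaluation
#' check of EM output.
#'
#' @param X Numeric data matrix.
#' @param means T x m matrix of profile means.
#' @param precisions Length-m precision vector (inverse variances).
#' @param weights Length-T mixing proportions.
#' @return List with `loglik` and `resp`.
#' @export
lpa_loglik <- function(X, means, precisions, weights) {
  X <- as.matrix(X); means <- as.matrix(means)
  s2 <- 1 / precisions
  n <- nrow(X); T_ <- nrow(means)
  cst <- -0.5 * ncol(X) * log(2 * pi) - 0.5 * sum(log(s2))
  L <- -0.5 * (as.vector(X^2 %*% precisions) -
                 2 * X %*% t(means * rep(precisions, each = T_)) +
                 matrix(rowSums(means^2 * rep(precisions, each = T_)),
                        n, T_, byrow = TRUE)) + cst
  L <- sweep(L, 2L, log(weights), "+")
  mx <- L[cbind(seq_len(n), max.col(L, ties.method = "first"))]
  lse <- mx + log(rowSums(exp(L - mx)))
  list(loglik = sum(lse), resp = exp(L - lse))
}

#' Information criteria for an LPA fit
#'
#' AIC = -2 loglik + 2 k and BIC = -2 loglik + k log(n), with
#' k = T m + m + (T - 1) free parameters (profile means, shared
#' variances, mixing proportions). Lower values indicate better fit
#' balanced against complexity.
#'
#' @param fit An `lpa_fit`.
#' @param n Sample size.
#' @return Named list with `aic` and `bic`.
#' @export
information_criteria <- function(fit, n) {
  if (!is.finite(fit$loglik)) stop("log-likelihood is not finite")
  k <- fit$n_params
  list(aic = -2 * fit$loglik + 2 * k,
       bic = -2 * fit$loglik + k * log(n))
}
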