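# Variational inference for finite Bayesian LPA: the same
# shared-diagonal Gaussian mixture likelihood, but with a fixed number
# of profiles and a symmetric Dirichlet prior on the mixing
# proportions instead of the Dirichlet process.  Factors:
#   q(z) multinomial phi;  q(pi) Dirichlet(d);
#   q(mu_jt) Normal(M, S2);  q(xi_j) Gamma(a, b).
finite_vb_run <- function(X, phi0, priors, dirichlet_conc, tol, max_iter) {
  n <- nrow(X); m <- ncol(X); Tt <- ncol(phi0)
  a0 <- priors$precision_shape; b0 <- priors$precision_rate
  cv <- priors$mean_variance_multiplier
  d0 <- dirichlet_conc
  X2 <- X^2; sumX2 <- colSums(X2)

  phi <- phi0
  a <- rep(a0 + Tt / 2 + n / 2, m); b <- rep(b0 + n / 2, m)
  M <- matrix(0, m, Tt); S2 <- matrix(cv, m, Tt)
  Nt <- colSums(phi)
  d <- d0 + Nt
  Exi <- a / b
  S <- crossprod(X, phi)
  denom <- matrix(1 / cv + Nt, m, Tt, byrow = TRUE)
  M <- S / denom; S2 <- 1 / (Exi * denom)

  loglik_at_factors <- function(Exi, Elogxi) {
    Emu2 <- M^2 + S2
    -0.5 * (as.vector(X2 %*% Exi) -
              2 * X %*% (Exi * M) +
              matrix(colSums(Exi * Emu2), n, Tt, byrow = TRUE)) +
      0.5 * sum(Elogxi) - m / 2 * log(2 * pi)
  }

  elbo_trace <- numeric(0); elbo_prev <- -Inf; converged <- FALSE
  loglik <- NULL
  for (iter in seq_len(max_iter)) {
    Exi <- a / b; Elogxi <- digamma(a) - log(b)
    Elogpi <- digamma(d) - digamma(sum(d))

    if (is.null(loglik)) loglik <- loglik_at_factors(Exi, Elogxi)
    R <- sweep(loglik, 2L, Elogpi, "+")
    mx <- R[cbind(seq_len(n), max.col(R, ties.method = "first"))]
    phi <- exp(R - mx); phi <- phi / rowSums(phi)

    Nt <- colSums(phi)
    d <- d0 + Nt
    Elogpi <- digamma(d) - digamma(sum(d))
    S <- crossprod(X, phi)
    denom <- matrix(1 / cv + Nt, m, Tt, byrow = TRUE)
    M <- S / denom; S2 <- 1 / (Exi * denom)
    Emu2 <- M^2 + S2
    quad <- sumX2 - 2 * rowSums(M * S) + as.vector(Emu2 %*% Nt)
    a <- rep(a0 + Tt / 2 + n / 2, m)
    b <- b0 + rowSums(Emu2) / (2 * cv) + quad / 2
    Exi <- a / b; Elogxi <- digamma(a) - log(b)

    # ELBO
    loglik <- loglik_at_factors(Exi, Elogxi)
    term_lik <- sum(phi * loglik)
    term_z <- sum(colSums(phi) * Elogpi) - sum(xlogx(phi))
    term_pi <- (lgamma(Tt * d0) - Tt * lgamma(d0) + sum((d0 - 1) * Elogpi)) -
      (lgamma(sum(d)) - sum(lgamma(d)) + sum((d - 1) * Elogpi))
    term_mu <- sum(-0.5 * log(2 * pi * cv) + 0.5 * rep(Elogxi, Tt) -
                     (Exi * Emu2) / (2 * cv)) -
      sum(-0.5 * log(2 * pi * S2) - 0.5)
    term_xi <- sum(a0 * log(b0) - lgamma(a0) + (a0 - 1) * Elogxi - b0 * Exi) -
      sum(a * log(b) - lgamma(a) + (a - 1) * Elogxi - b * Exi)
    elbo <- term_lik + term_z + term_pi + term_mu + term_xi

    elbo_trace <- c(elbo_trace, elbo)
    if (is.finite(elbo_prev) && abs(elbo - elbo_prev) < tol * abs(elbo_prev)) {
      converged <- TRUE
      break
    }
    elbo_prev <- elbo
  }

  list(resp = phi, dirichlet_params = d,
       mean_params = list(location = M, variance = S2),
       precision_params = cbind(shape = a, rate = b),
       elbo_trace = elbo_trace,
       elbo = if (length(elbo_trace)) elbo_trace[length(elbo_trace)] else -Inf,
       converged = converged)
}

#' Fit finite Bayesian LPA by variational inference
#'
#' Bayesian LPA with a fixed number of profiles: the shared-diagonal
#' Gaussian mixture likelihood with a symmetric Dirichlet(1) prior on
#' the mixing proportions and the same conjugate priors on means and
#' precisions as DPM-LPA. Fit by mean-field coordinate ascent; the
#' final ELBO serves as the model-selection score across candidate
#' profile counts (argmax over T).
#'
#' @param data An [indicator_matrix] or numeric matrix (standardized).
#' @param T Number of profiles.
#' @param priors A [dpm_priors] specification (the alpha hyperprior is
#'   unused here).
#' @param dirichlet_conc Symmetric Dirichlet concentration (default 1).
#' @param seed Integer seed.
#' @param tol,max_iter,n_restarts Coordinate-ascent controls.
#' @return List of class `finite_bayes_fit`: posterior summaries
#'   (`means` = posterior mean locations, T x m; `precisions`;
#'   `weights` = posterior mean mixing proportions; `resp`), the final
#'   `elbo` and `elbo_trace`, `T`, `converged`, `seed`.
#' @export
fit_finite_bayes <- function(data, T, priors = dpm_priors(),
                             dirichlet_conc = 1, seed = 1L, tol = 1e-6,
                             max_iter = 1000L, n_restarts = 10L) {
  X <- if (inherits(data, "indicator_matrix")) data$values else as.matrix(data)
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite values in data")
  T <- as.integer(T)
  if (T < 1L) stop("T must be at least 1")
  if (T == 1L) n_restarts <- 1L
  best <- NULL
  for (r in seq_len(n_restarts)) {
    phi0 <- if (T == 1L) matrix(1, nrow(X), 1L) else
      init_resp(X, T, seed = seed + (r - 1L))
    run <- finite_vb_run(X, phi0, priors, dirichlet_conc, tol, max_iter)
    if (is.finite(run$elbo) && (is.null(best) || run$elbo > best$elbo))
      best <- run
  }
  if (is.null(best)) stop("every restart failed to produce a finite ELBO")
  structure(list(T = T,
                 means = t(best$mean_params$location),
                 precisions = as.numeric(best$precision_params[, "shape"] /
                                           best$precision_params[, "rate"]),
                 weights = as.numeric(best$dirichlet_params / sum(best$dirichlet_params)),
                 resp = best$resp,
                 elbo = best$elbo,
                 elbo_trace = best$elbo_trace,
                 converged = best$converged,
                 seed = seed),
            class = "finite_bayes_fit")
}

#' @export
print.finite_bayes_fit <- function(x, ...) {
  cat("finite Bayesian LPA fit:", x$T, "profile(s); ELBO",
      format(x$elbo, digits = 8),
      if (x$converged) "(converged)" else "(max iterations)", "\n")
  invisible(x)
}
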