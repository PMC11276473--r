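#' Prior specification for DPM-LPA and finite Bayesian LPA
#'
#' Conjugate priors for the mixture likelihood: per-indicator precisions
#' `xi_j ~ Gamma(shape, rate)` (shape-rate parameterization, so the
#' default Gamma(5, 5) has mean 1 -- appropriate for z-scored
#' indicators) and profile means `mu_{j,t} | xi_j ~ N(0, v / xi_j)`
#' with `v = mean_variance_multiplier`. The Dirichlet process
#' concentration parameter alpha carries a Gamma hyperprior and is
#' inferred from the data.
#'
#' @param precision_shape,precision_rate Gamma prior on each indicator
#'   precision. Defaults 5, 5.
#' @param mean_variance_multiplier Prior variance of a profile mean is
#'   this multiple of `1/xi_j`. Default 2.
#' @param alpha_shape,alpha_rate Gamma hyperprior on the concentration
#'   parameter. Defaults 1, 1.
#' @return List of class `dpm_priors`.
#' @export
dpm_priors <- function(precision_shape = 5, precision_rate = 5,
                       mean_variance_multiplier = 2,
                       alpha_shape = 1, alpha_rate = 1) {
  vals <- c(precision_shape, precision_rate, mean_variance_multiplier,
            alpha_shape, alpha_rate)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all prior hyperparameters must be strictly positive")
  structure(list(precision_shape = precision_shape,
                 precision_rate = precision_rate,
                 mean_variance_multiplier = mean_variance_multiplier,
                 alpha_shape = alpha_shape, alpha_rate = alpha_rate),
            class = "dpm_priors")
}

#' Log prior probability of a profile assignment under the Dirichlet process
#'
#' Polya-urn form of the Dirichlet process prior on a partition of n
#' participants into T occupied profiles:
#' `p(z) = alpha^T * prod_t (n_t - 1)! / (alpha (alpha+1) ... (n-1+alpha))`.
#' The prior is exchangeable (invariant to participant order) and favors
#' concentrating participants in few profiles.
#'
#' @param assignments Integer labels forming a contiguous relabeling
#'   `1..T`.
#' @param alpha Positive concentration parameter.
#' @return Natural-log prior probability.
#' @examples
#' log_dp_prior(c(1, 1, 1), alpha = 1) # log(1/3)
#' @export
log_dp_prior <- function(assignments, alpha) {
  if (length(assignments) == 0L) stop("empty assignment vector")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be strictly positive")
  z <- as.integer(assignments)
  counts <- tabulate(z)
  if (any(counts == 0L) || any(z < 1L))
    stop("assignments must be a contiguous relabeling 1..T")
  T_ <- length(counts)
  n <- length(z)
  T_ * log(alpha) + sum(lgamma(counts)) - (lgamma(n + alpha) - lgamma(alpha))
}

# ---- variational engine ----------------------------------------------------

# One coordinate-ascent run of truncated stick-breaking variational
# inference from initial responsibilities phi0.  Factors:
#   q(z_i) multinomial phi_i;  q(v_t) Beta(g1_t, g2_t) for t < Tt;
#   q(mu_jt) Normal(M_jt, S2_jt);  q(xi_j) Gamma(a_j, b_j);
#   q(alpha) Gamma(w1, w2).
# All updates are closed-form conjugate coordinate maximizers of the
# ELBO, so the ELBO trace is non-decreasing.
dpm_vb_run <- function(X, phi0, priors, tol, max_iter) {
  n <- nrow(X); m <- ncol(X); Tt <- ncol(phi0)
  a0 <- priors$precision_shape; b0 <- priors$precision_rate
  cv <- priors$mean_variance_multiplier
  s1 <- priors$alpha_shape; s2 <- priors$alpha_rate
  X2 <- X^2; sumX2 <- colSums(X2)

  phi <- phi0
  # initialize remaining factors from phi0 via their conjugate updates
  a <- rep(a0 + Tt / 2 + n / 2, m); b <- rep(b0 + n / 2, m)
  w1 <- s1 + Tt - 1; w2 <- s2
  M <- matrix(0, m, Tt); S2 <- matrix(cv, m, Tt)
  g1 <- rep(1, Tt - 1L); g2 <- rep(1, Tt - 1L)

  update_sticks <- function(Nt, Ealpha) {
    g1 <<- 1 + Nt[seq_len(Tt - 1L)]
    tail_mass <- rev(cumsum(rev(Nt)))        # sum_{s >= t} Nt_s
    g2 <<- Ealpha + tail_mass[-1L][seq_len(Tt - 1L)]
  }
  S <- NULL                                  # crossprod(X, phi), shared
  update_mu <- function(Nt, Exi) {
    S <<- crossprod(X, phi)                  # m x Tt
    denom <- matrix(1 / cv + Nt, m, Tt, byrow = TRUE)
    M <<- S / denom
    S2 <<- 1 / (Exi * denom)                 # Exi recycles over rows
  }
  update_xi <- function(Nt) {
    Emu2 <- M^2 + S2
    quad <- sumX2 - 2 * rowSums(M * S) + as.vector(Emu2 %*% Nt)
    a <<- rep(a0 + Tt / 2 + n / 2, m)
    b <<- b0 + rowSums(Emu2) / (2 * cv) + quad / 2
  }
  loglik_at_factors <- function(Exi, Elogxi) {
    Emu2 <- M^2 + S2
    -0.5 * (as.vector(X2 %*% Exi) -
              2 * X %*% (Exi * M) +
              matrix(colSums(Exi * Emu2), n, Tt, byrow = TRUE)) +
      0.5 * sum(Elogxi) - m / 2 * log(2 * pi)
  }

  # bootstrap the non-phi factors once from phi0
  Nt <- colSums(phi)
  Ealpha <- w1 / w2
  update_sticks(Nt, Ealpha)
  Exi <- a / b
  update_mu(Nt, Exi)
  update_xi(Nt)

  elbo_trace <- numeric(0)
  elbo_prev <- -Inf
  converged <- FALSE
  loglik <- NULL    # cached between the ELBO step and the next phi update

  for (iter in seq_len(max_iter)) {
    Exi <- a / b; Elogxi <- digamma(a) - log(b)
    Ealpha <- w1 / w2; Elogalpha <- digamma(w1) - log(w2)
    Elogv <- digamma(g1) - digamma(g1 + g2)
    Elog1mv <- digamma(g2) - digamma(g1 + g2)
    logw <- c(Elogv, 0) + c(0, cumsum(Elog1mv))   # length Tt

    # q(z): responsibilities (the log-density matrix is unchanged since
    # the previous iteration's ELBO evaluation, so reuse it)
    if (is.null(loglik)) loglik <- loglik_at_factors(Exi, Elogxi)
    R <- sweep(loglik, 2L, logw, "+")
    mx <- R[cbind(seq_len(n), max.col(R, ties.method = "first"))]
    phi <- exp(R - mx)
    phi <- phi / rowSums(phi)

    # remaining factors
    Nt <- colSums(phi)
    update_sticks(Nt, Ealpha)
    Elogv <- digamma(g1) - digamma(g1 + g2)
    Elog1mv <- digamma(g2) - digamma(g1 + g2)
    logw <- c(Elogv, 0) + c(0, cumsum(Elog1mv))
    update_mu(Nt, Exi)
    update_xi(Nt)
    Exi <- a / b; Elogxi <- digamma(a) - log(b)
    w1 <- s1 + Tt - 1
    w2 <- s2 - sum(Elog1mv)
    Ealpha <- w1 / w2; Elogalpha <- digamma(w1) - log(w2)

    # ---- ELBO at the current factors
    Emu2 <- M^2 + S2
    loglik <- loglik_at_factors(Exi, Elogxi)
    term_lik <- sum(phi * loglik)
    term_z <- sum(colSums(phi) * logw) - sum(xlogx(phi))
    term_v <- sum(Elogalpha + (Ealpha - 1) * Elog1mv) -
      sum((g1 - 1) * Elogv + (g2 - 1) * Elog1mv - lbeta(g1, g2))
    term_mu <- sum(-0.5 * log(2 * pi * cv) + 0.5 * rep(Elogxi, Tt) -
                     (Exi * Emu2) / (2 * cv)) -
      sum(-0.5 * log(2 * pi * S2) - 0.5)
    term_xi <- sum(a0 * log(b0) - lgamma(a0) + (a0 - 1) * Elogxi - b0 * Exi) -
      sum(a * log(b) - lgamma(a) + (a - 1) * Elogxi - b * Exi)
    term_alpha <- (s1 * log(s2) - lgamma(s1) + (s1 - 1) * Elogalpha - s2 * Ealpha) -
      (w1 * log(w2) - lgamma(w1) + (w1 - 1) * Elogalpha - w2 * Ealpha)
    elbo <- term_lik + term_z + term_v + term_mu + term_xi + term_alpha

    elbo_trace <- c(elbo_trace, elbo)
    if (is.finite(elbo_prev) &&
        abs(elbo - elbo_prev) < tol * abs(elbo_prev)) {
      converged <- TRUE
      break
    }
    elbo_prev <- elbo
  }

  list(resp = phi,
       stick_params = cbind(shape1 = g1, shape2 = g2),
       mean_params = list(location = M, variance = S2),
       precision_params = cbind(shape = a, rate = b),
       alpha_params = c(shape = w1, rate = w2),
       elbo_trace = elbo_trace,
       elbo = if (length(elbo_trace)) elbo_trace[length(elbo_trace)] else -Inf,
       converged = converged)
}

# Seeding coarseness per restart: every small cluster count is covered
# exactly (2, 3, 4, ...), with the last few restarts spread up to the
# truncation level.  Plausible profile counts under the DP prior are
# small, so missing one (e.g. seeding 2 and 4 but never 3) leaves
# coordinate ascent with no restart near the dominant mode.
restart_ladder <- function(truncation, n_restarts) {
  if (n_restarts == 1L) return(truncation)
  n_low <- max(1L, n_restarts - 3L)
  low <- pmin(truncation, seq(2L, by = 1L, length.out = n_low))
  n_high <- n_restarts - n_low
  high <- round(seq(max(low), truncation, length.out = n_high + 1L))[-1L]
  pmin(truncation, c(low, high))
}

# Soft initial responsibilities with Dirichlet jitter, seeded from a
# hard partition.  method "kmeans" runs one k-means pass; "random"
# assigns each point to its nearest of k_init randomly drawn data rows
# (the cheap emEM-style start used for bootstrap refits).  k_init
# controls the coarseness of the seeding partition (it may be smaller
# than the number of components K, leaving the rest to the jitter);
# restarts at varying coarseness protect coordinate ascent from
# fragmented local optima.
init_resp <- function(X, K, seed, k_init = K, method = "kmeans") {
  set.seed(seed)
  n <- nrow(X)
  hard <- if (k_init > n) {
    sample.int(K, n, replace = TRUE)
  } else if (method == "random") {
    centers <- X[sample.int(n, k_init), , drop = FALSE]
    d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") -
      2 * tcrossprod(X, centers)
    max.col(-d2, ties.method = "first")
  } else {
    km <- tryCatch(
      stats::kmeans(jitter(X, amount = 1e-8), centers = k_init, nstart = 1L,
                    iter.max = 25L),
      error = function(e) NULL)
    if (is.null(km)) sample.int(k_init, n, replace = TRUE) else km$cluster
  }
  onehot <- matrix(0, n, K)
  onehot[cbind(seq_len(n), hard)] <- 1
  jit <- matrix(stats::rgamma(n * K, shape = 0.5), n, K)
  jit <- jit / rowSums(jit)
  phi0 <- 0.9 * onehot + 0.1 * jit
  phi0 / rowSums(phi0)
}

#' Fit DPM-LPA by mean-field variational inference
#'
#' Fits a Dirichlet process mixture of Gaussians with shared diagonal
#' covariance to standardized indicator data, using a truncated
#' stick-breaking variational family and coordinate ascent on the
#' evidence lower bound (ELBO). The number of latent profiles is not
#' fixed in advance: the DP prior leaves unneeded components empty, and
#' a component is retained only if it is the most probable profile for
#' at least one participant (see [extract_profiles()]).
#'
#' Coordinate ascent finds local optima, so the fit is restarted from
#' `n_restarts` k-means-seeded initializations (distinct sub-seeds
#' derived from `seed`) and the restart with the highest final ELBO is
#' returned. The restarts seed the responsibilities from k-means
#' partitions of varying coarseness (every cluster count from 2 up
#' covered exactly, then spread to `truncation`): seeding every
#' restart at full truncation tends to trap coordinate ascent in
#' fragmented local optima in which a true profile is split across
#' components or a handful of outliers claim their own component.
#'
#' @param data An [indicator_matrix] (standardized) or numeric matrix.
#' @param priors A [dpm_priors] specification.
#' @param truncation Truncation level of the stick-breaking family
#'   (maximum representable profiles). Default 20.
#' @param seed Integer seed.
#' @param tol Relative ELBO change declaring convergence. Default 1e-6.
#' @param max_iter Maximum coordinate-ascent sweeps per restart.
#' @param n_restarts Number of random restarts. Default 10.
#' @return List of class `dpm_fit`: `state` (variational factors and
#'   `elbo_trace`), `profiles` (a `profile_set`, see
#'   [extract_profiles()]), `elbo`, `seed`, `priors`, `truncation`,
#'   `converged`.
#' @export
fit_dpm <- function(data, priors = dpm_priors(), truncation = 20L,
                    seed = 1L, tol = 1e-6, max_iter = 1000L,
                    n_restarts = 10L) {
  X <- if (inherits(data, "indicator_matrix")) data$values else as.matrix(data)
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite values in data")
  if (truncation < 2L) stop("truncation must be at least 2")
  ks <- restart_ladder(as.integer(truncation), as.integer(n_restarts))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    phi0 <- init_resp(X, truncation, seed = seed + (r - 1L), k_init = ks[r])
    run <- dpm_vb_run(X, phi0, priors, tol = tol, max_iter = max_iter)
    if (is.finite(run$elbo) && (is.null(best) || run$elbo > best$elbo))
      best <- run
  }
  if (is.null(best))
    stop("no restart produced a finite ELBO (n_restarts = ", n_restarts,
         ", truncation = ", truncation, ")")
  state <- structure(best[c("resp", "stick_params", "mean_params",
                            "precision_params", "alpha_params",
                            "elbo_trace")],
                     class = "variational_state")
  structure(list(state = state,
                 profiles = extract_profiles(state),
                 elbo = best$elbo,
                 converged = best$converged,
                 seed = seed, priors = priors,
                 truncation = as.integer(truncation)),
            class = "dpm_fit")
}

#' Extract non-empty profiles from a variational state
#'
#' A stick-breaking component is considered empty unless it is the
#' maximally probable profile for at least one participant; empty
#' components are dropped, the retained profiles are relabeled in
#' decreasing order of the number of participants assigned to them
#' (profile 1 is the largest), and responsibilities are renormalized
#' over the retained profiles. Argmax ties go to the lowest component
#' index; size ties keep the original component order.
#'
#' @param state A `variational_state` (from [fit_dpm()]).
#' @return List of class `profile_set`: `T`, `means` (T x m),
#'   `precisions` (m), `base_rates`, `resp` (n x T, renormalized),
#'   `counts`.
#' @export
extract_profiles <- function(state) {
  phi <- state$resp
  hard <- max.col(phi, ties.method = "first")
  counts_all <- tabulate(hard, nbins = ncol(phi))
  keep <- which(counts_all >= 1L)
  ord <- keep[order(counts_all[keep], decreasing = TRUE)]  # stable: ties keep index order
  resp <- phi[, ord, drop = FALSE]
  resp <- resp / rowSums(resp)
  means <- t(state$mean_params$location[, ord, drop = FALSE])
  prec <- state$precision_params[, "shape"] / state$precision_params[, "rate"]
  structure(list(T = length(ord),
                 means = means,
                 precisions = as.numeric(prec),
                 base_rates = colMeans(resp),
                 resp = resp,
                 counts = counts_all[ord]),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat("profile_set:", x$T, "retained profile(s); counts:",
      paste(x$counts, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.dpm_fit <- function(x, ...) {
  cat("DPM-LPA fit: truncation", x$truncation, "->", x$profiles$T,
      "retained profile(s); ELBO", format(x$elbo, digits = 8),
      if (x$converged) "(converged)" else "(max iterations)", "\n")
  invisible(x)
}
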