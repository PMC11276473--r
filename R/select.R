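#' Select the number of profiles for conventional or finite-Bayes LPA
#'
#' Fits models with 1 to `T_max` profiles and selects the count by the
#' requested criterion:
#' \describe{
#'   \item{bic, aic}{argmin of the criterion over T.}
#'   \item{blrt}{sequential stopping: the smallest T whose bootstrap
#'     likelihood ratio test against T + 1 is non-significant at
#'     `level`; if every test rejects, `T_max` is selected.}
#'   \item{finite_bayes_elbo}{argmax of the variational evidence lower
#'     bound over T.}
#' }
#' A per-T table of criterion values is returned for reporting.
#'
#' @param data An [indicator_matrix] or numeric matrix (standardized).
#' @param criterion One of `"bic"`, `"aic"`, `"blrt"`,
#'   `"finite_bayes_elbo"`.
#' @param T_max Largest profile count considered (>= 2).
#' @param seed Integer seed.
#' @param n_restarts EM/VB restarts per T.
#' @param level Significance level for the sequential BLRT.
#' @param n_boot Bootstrap replicates per BLRT.
#' @param priors Priors for the finite-Bayes criterion.
#' @param ... Further arguments passed to the fitting functions.
#' @return List of class `profile_selection`: `selected` (chosen T),
#'   `criterion`, `table` (data frame of per-T values).
#' @export
select_profiles <- function(data, criterion = c("bic", "aic", "blrt",
                                                "finite_bayes_elbo"),
                            T_max = 8L, seed = 1L, n_restarts = 20L,
                            level = 0.05, n_boot = 100L,
                            priors = dpm_priors(), ...) {
  criterion <- match.arg(criterion)
  if (T_max < 2L) stop("T_max must be at least 2")
  X <- if (inherits(data, "indicator_matrix")) data$values else as.matrix(data)
  n <- nrow(X)
  Ts <- seq_len(T_max)

  if (criterion %in% c("bic", "aic")) {
    tab <- data.frame(T = Ts, loglik = NA_real_, aic = NA_real_, bic = NA_real_)
    for (T_ in Ts) {
      fit <- fit_em(X, T_, n_restarts = n_restarts, seed = seed + 100L * T_, ...)
      ic <- information_criteria(fit, n)
      tab[T_, c("loglik", "aic", "bic")] <- c(fit$loglik, ic$aic, ic$bic)
    }
    selected <- Ts[which.min(tab[[criterion]])]
  } else if (criterion == "finite_bayes_elbo") {
    tab <- data.frame(T = Ts, elbo = NA_real_)
    for (T_ in Ts) {
      fit <- fit_finite_bayes(X, T_, priors = priors,
                              seed = seed + 100L * T_, ...)
      tab$elbo[T_] <- fit$elbo
    }
    selected <- Ts[which.max(tab$elbo)]
  } else { # blrt: sequential stopping
    tab <- data.frame(T = Ts, blrt_p = NA_real_)
    selected <- T_max
    for (T_ in seq_len(T_max - 1L)) {
      res <- blrt(X, T_, n_boot = n_boot, seed = seed + 100L * T_,
                  n_restarts = n_restarts, ...)
      tab$blrt_p[T_] <- res$p_value
      if (res$p_value > level) {
        selected <- T_
        break
      }
    }
  }
  structure(list(selected = selected, criterion = criterion, table = tab),
            class = "profile_selection")
}

#' @export
print.profile_selection <- function(x, ...) {
  cat("selected", x$selected, "profile(s) by", x$criterion, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
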