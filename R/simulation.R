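#' Define a class-enumeration simulation scenario
#'
#' Generative design for benchmarking how accurately different LPA
#' methods recover the true number of latent profiles. The default
#' scenario has 10 indicator variables and 5 equal-size latent profiles
#' whose mean vectors lie on a line, with unit within-profile variance,
#' adjacent profiles separated by 1.5 within-profile standard
#' deviations on every indicator, and 50 replicate datasets per
#' condition.
#'
#' Two operationalizations of "adjacent profiles separated by s
#' standard deviations" are available. The default,
#' `separation_mode = "per_indicator"`, applies the full gap `s` on
#' every indicator (adjacent-profile Mahalanobis distance
#' `s * sqrt(m)`). `separation_mode = "mahalanobis"` instead spreads
#' the gap across indicators so the adjacent-profile Mahalanobis
#' distance is `s` itself (per-indicator gap `s / sqrt(m)`), a much
#' harder enumeration problem at the same nominal separation.
#'
#' @param n Sample size (divisible by `T_true` when `balanced`).
#' @param m Number of indicators. Default 10.
#' @param T_true True number of profiles. Default 5.
#' @param separation Adjacent-profile separation. Default 1.5.
#' @param balanced Equal profile sizes? Default TRUE.
#' @param replicates Datasets per condition. Default 50.
#' @param base_seed Seed; replicate r uses `base_seed + r`.
#' @param separation_mode `"per_indicator"` (default) or
#'   `"mahalanobis"`.
#' @return List of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n, m = 10L, T_true = 5L, separation = 1.5,
                                balanced = TRUE, replicates = 50L,
                                base_seed = 1L,
                                separation_mode = c("per_indicator",
                                                    "mahalanobis")) {
  separation_mode <- match.arg(separation_mode)
  if (!is.finite(separation) || separation <= 0) stop("separation must be positive")
  if (n < 2L || m < 1L || T_true < 1L) stop("invalid scenario dimensions")
  if (replicates < 1L) stop("replicates must be at least 1")
  if (balanced && n %% T_true != 0L)
    stop("n must be divisible by T_true for a balanced scenario")
  structure(list(n = as.integer(n), m = as.integer(m),
                 T_true = as.integer(T_true), separation = separation,
                 balanced = isTRUE(balanced),
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed),
                 separation_mode = separation_mode),
            class = "simulation_scenario")
}

#' Profile mean vectors implied by a scenario
#'
#' Equally spaced collinear means, centered at zero: profile t has mean
#' `(t - (T_true + 1)/2) * delta` on every indicator, where `delta` is
#' `separation` (per-indicator mode) or `separation / sqrt(m)`
#' (Mahalanobis mode).
#'
#' @param scenario A [simulation_scenario].
#' @return `T_true x m` matrix of generating means.
#' @export
scenario_means <- function(scenario) {
  delta <- if (scenario$separation_mode == "mahalanobis")
    scenario$separation / sqrt(scenario$m) else scenario$separation
  offsets <- (seq_len(scenario$T_true) - (scenario$T_true + 1) / 2) * delta
  matrix(offsets, scenario$T_true, scenario$m)
}

#' Generate one replicate dataset from a scenario
#'
#' Draws profile labels (exactly `n / T_true` per profile when
#' balanced, multinomial otherwise), then independent unit-variance
#' normal indicators around the profile means. Deterministic given
#' `(base_seed, replicate_index)`. The returned values are raw
#' (unstandardized); the analysis pipeline z-scores them via
#' [standardize_columns()] / [indicator_matrix()].
#'
#' @param scenario A [simulation_scenario].
#' @param replicate_index Replicate number (seed offset).
#' @return List with `values` (n x m matrix) and `true_labels`.
#' @export
generate_dataset <- function(scenario, replicate_index = 1L) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$base_seed + as.integer(replicate_index))
  n <- scenario$n; m <- scenario$m; Tt <- scenario$T_true
  labels <- if (scenario$balanced) {
    sample(rep(seq_len(Tt), each = n %/% Tt))
  } else {
    sample.int(Tt, n, replace = TRUE)
  }
  mu <- scenario_means(scenario)
  values <- mu[labels, , drop = FALSE] + matrix(stats::rnorm(n * m), n, m)
  list(values = values, true_labels = labels)
}

#' Benchmark class-enumeration accuracy across methods
#'
#' For each scenario and replicate, generates a dataset, standardizes
#' it, and records the profile count selected by each method:
#' \describe{
#'   \item{dpm}{number of retained (non-empty) DPM-LPA profiles.}
#'   \item{em_bic}{BIC argmin over EM fits with `1..T_max` profiles.}
#'   \item{em_blrt}{sequential bootstrap likelihood ratio test.}
#'   \item{finite_bayes}{ELBO argmax over finite-Bayes fits.}
#' }
#'
#' @param scenarios A [simulation_scenario] or list of them.
#' @param methods Subset of `c("dpm", "em_bic", "em_blrt",
#'   "finite_bayes")`.
#' @param T_max Largest profile count for the selection-based methods.
#' @param truncation DPM-LPA truncation level.
#' @param em_restarts,dpm_restarts Restarts per fit.
#' @param n_boot,level BLRT controls.
#' @param progress Print one line per replicate to stderr?
#' @return List of class `benchmark_table`: `results` (one row per
#'   method x replicate: method, n, replicate, selected_T, correct) and
#'   `summary` (percent correct per method x n).
#' @export
run_benchmark <- function(scenarios, methods = c("dpm", "em_bic"),
                          T_max = 8L, truncation = 20L,
                          em_restarts = 20L, dpm_restarts = 10L,
                          n_boot = 100L, level = 0.05,
                          progress = FALSE) {
  if (inherits(scenarios, "simulation_scenario")) scenarios <- list(scenarios)
  if (length(scenarios) == 0L || length(methods) == 0L)
    stop("need at least one scenario and one method")
  known <- c("dpm", "em_bic", "em_blrt", "finite_bayes")
  if (!all(methods %in% known))
    stop("unknown method(s): ", paste(setdiff(methods, known), collapse = ", "))
  rows <- list()
  for (sc in scenarios) {
    for (r in seq_len(sc$replicates)) {
      gen <- generate_dataset(sc, r)
      X <- standardize_columns(gen$values)
      s <- sc$base_seed + r
      for (mth in methods) {
        sel <- switch(
          mth,
          dpm = fit_dpm(X, truncation = truncation, seed = s + 100000L,
                        n_restarts = dpm_restarts)$profiles$T,
          em_bic = select_profiles(X, "bic", T_max = T_max,
                                   seed = s + 200000L,
                                   n_restarts = em_restarts)$selected,
          em_blrt = select_profiles(X, "blrt", T_max = T_max,
                                    seed = s + 300000L,
                                    n_restarts = em_restarts,
                                    n_boot = n_boot, level = level)$selected,
          finite_bayes = select_profiles(X, "finite_bayes_elbo",
                                         T_max = T_max, seed = s + 400000L,
                                         n_restarts = dpm_restarts)$selected)
        rows[[length(rows) + 1L]] <-
          data.frame(method = mth, n = sc$n, replicate = r,
                     selected_T = sel, correct = sel == sc$T_true)
      }
      if (progress)
        message("n=", sc$n, " replicate ", r, "/", sc$replicates, " done")
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(correct ~ method + n, data = results,
                              FUN = function(z) 100 * mean(z))
  names(summary)[names(summary) == "correct"] <- "percent_correct"
  structure(list(results = results, summary = summary),
            class = "benchmark_table")
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat("class-enumeration benchmark (% correct):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
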