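#' Serialize a fitted model to JSON
#'
#' Writes profile means, precisions, base rates / weights, counts, the
#' full responsibility matrix, the ELBO or log-likelihood trace, and
#' the run configuration (seed, priors, truncation) so that a fit can
#' be reloaded and reused (e.g. by the `outcomes` command) without
#' refitting.
#'
#' @param fit A `dpm_fit`, `lpa_fit` or `finite_bayes_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  payload <- if (inherits(fit, "dpm_fit")) {
    list(model = "dpm",
         T = fit$profiles$T,
         means = fit$profiles$means,
         precisions = fit$profiles$precisions,
         base_rates = fit$profiles$base_rates,
         counts = fit$profiles$counts,
         resp = fit$profiles$resp,
         elbo_trace = fit$state$elbo_trace,
         elbo = fit$elbo,
         converged = fit$converged,
         seed = fit$seed,
         truncation = fit$truncation,
         priors = unclass(fit$priors))
  } else if (inherits(fit, "lpa_fit")) {
    list(model = "em",
         T = fit$T,
         means = fit$means,
         precisions = fit$precisions,
         weights = fit$weights,
         resp = fit$resp,
         loglik = fit$loglik,
         loglik_trace = fit$loglik_trace,
         n_params = fit$n_params,
         converged = fit$converged,
         seed = fit$seed)
  } else if (inherits(fit, "finite_bayes_fit")) {
    list(model = "finite_bayes",
         T = fit$T,
         means = fit$means,
         precisions = fit$precisions,
         weights = fit$weights,
         resp = fit$resp,
         elbo_trace = fit$elbo_trace,
         elbo = fit$elbo,
         converged = fit$converged,
         seed = fit$seed)
  } else stop("unsupported fit object of class ", paste(class(fit), collapse = "/"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Reload a serialized fit
#'
#' @param path JSON file written by [write_fit_json()].
#' @return Named list with matrices restored (`means`, `resp`).
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path)) stop("fit file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$means <- matrix(unlist(x$means), nrow = x$T, byrow = FALSE)
  if (is.list(x$resp)) x$resp <- do.call(rbind, x$resp)
  x$resp <- as.matrix(x$resp)
  x
}
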