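#' Classification entropy of a membership probability vector
#'
#' Shannon entropy (natural log) of one participant's profile-membership
#' probabilities. Low entropy means the model is confident about that
#' participant's profile; the maximum, `log(T)` nats, is attained by the
#' uniform vector. The limit convention `0 * log(0) = 0` applies.
#'
#' @param phi Nonnegative numeric vector summing to 1.
#' @param tol Tolerance for the sum-to-one check. The default is strict;
#'   loosen it to evaluate rounded probability vectors as printed (e.g.
#'   `c(0.33, 0.33, 0.33)`).
#' @return Entropy in nats.
#' @examples
#' classification_entropy(c(0.9, 0.07, 0.03)) # ~0.39
#' @export
classification_entropy <- function(phi, tol = 1e-9) {
  phi <- as.numeric(phi)
  if (any(!is.finite(phi)) || any(phi < 0))
    stop("membership probabilities must be finite and nonnegative")
  if (abs(sum(phi) - 1) > tol)
    stop("membership probabilities must sum to 1 (got ", format(sum(phi)), ")")
  -sum(xlogx(phi))
}

# x * log(x) with the 0 log 0 = 0 convention (clamping keeps the
# product exactly 0 at x = 0 without branching)
xlogx <- function(x) x * log(pmax(x, .Machine$double.xmin))

#' Proportional entropy reduction of a classification
#'
#' Compares the total classification entropy of a model across
#' participants to the maximum possible (`n * log(T)` nats) and reports
#' the proportional reduction: 1 means every participant is assigned
#' with total confidence, 0 means the classification is uninformative.
#' Values below about 0.8 are conventionally taken to indicate that the
#' model cannot classify participants accurately.
#'
#' @param resp n x T responsibility matrix; each row a probability vector.
#' @param tol Row sum-to-one tolerance.
#' @return Entropy reduction in `[0, 1]`.
#' @export
entropy_reduction <- function(resp, tol = 1e-9) {
  resp <- as.matrix(resp)
  T_ <- ncol(resp)
  if (T_ < 2L) stop("entropy reduction is undefined for a single profile (max entropy 0)")
  if (any(!is.finite(resp)) || any(resp < 0))
    stop("responsibilities must be finite and nonnegative")
  if (any(abs(rowSums(resp) - 1) > tol))
    stop("each responsibility row must sum to 1")
  total <- -sum(xlogx(resp))
  1 - total / (nrow(resp) * log(T_))
}

#' Precision-weighted (Mahalanobis) distance between two profile means
#'
#' `sqrt(sum_j xi_j * (mu_a_j - mu_b_j)^2)`: the Euclidean distance
#' between two profiles' indicator-mean vectors scaled by the shared
#' per-indicator precisions. 0 means the profiles are identical; larger
#' values mean more distinct profiles.
#'
#' @param mu_a,mu_b Numeric mean vectors of equal length.
#' @param xi Strictly positive precision vector of the same length.
#' @return Nonnegative distance.
#' @export
mahalanobis_distance <- function(mu_a, mu_b, xi) {
  if (length(mu_a) != length(mu_b) || length(mu_a) != length(xi))
    stop("mu_a, mu_b and xi must have equal length")
  if (any(!is.finite(xi)) || any(xi <= 0))
    stop("precisions must be strictly positive")
  sqrt(sum(xi * (mu_a - mu_b)^2))
}

#' Pairwise profile-distinctiveness summary
#'
#' Computes the precision-weighted distance between every pair of
#' profiles in a fitted model, plus the minimum (the two most similar
#' profiles) and mean over unordered pairs. Works for any fit exposing a
#' `T x m` mean matrix `means` and shared precision vector `precisions`
#' (DPM-LPA profile sets, EM and finite-Bayes fits).
#'
#' @param profiles A `profile_set`, `lpa_fit`, or a list with `means`
#'   and `precisions`.
#' @return List of class `distance_summary`: `pairwise` (T x T matrix),
#'   `min_offdiag`, `mean_offdiag`.
#' @export
distance_summary <- function(profiles) {
  mu <- as.matrix(profiles$means)
  xi <- as.numeric(profiles$precisions)
  T_ <- nrow(mu)
  if (T_ < 2L) stop("need at least 2 profiles for a distance summary")
  d <- matrix(0, T_, T_)
  for (a in seq_len(T_ - 1L)) {
    for (b in seq.int(a + 1L, T_)) {
      d[a, b] <- d[b, a] <- mahalanobis_distance(mu[a, ], mu[b, ], xi)
    }
  }
  off <- d[upper.tri(d)]
  structure(list(pairwise = d, min_offdiag = min(off), mean_offdiag = mean(off)),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat("profile distances: min", format(x$min_offdiag, digits = 4),
      "| mean", format(x$mean_offdiag, digits = 4), "over",
      length(x$pairwise[upper.tri(x$pairwise)]), "pairs\n")
  invisible(x)
}
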