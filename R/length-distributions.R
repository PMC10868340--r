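# Truncated discrete length distributions for indel events. All three
# candidate families share support {1, ..., truncation} and are renormalized
# after truncation, so that models with different functional forms are
# compared over the same range of event lengths.

#' Truncated indel length distribution
#'
#' Constructs one of the three candidate indel length distributions: Zipf
#' (discrete power law \eqn{P(k) \propto k^{-a}}), geometric, or Poisson.
#' Each distribution is truncated at `truncation` sites and renormalized,
#' i.e. conditioned on the event length not exceeding the truncation point.
#' The support starts at 1: an indel of length zero is not an event, so the
#' Poisson family is additionally conditioned on \eqn{k \ge 1}.
#'
#' @param family One of `"zipf"`, `"geometric"`, `"poisson"`.
#' @param parameter Positive real: the Zipf exponent, the geometric success
#'   probability (in (0, 1]), or the Poisson rate.
#' @param truncation Maximum indel length in sites (default 150).
#' @return An object of class `length_distribution` carrying the
#'   precomputed pmf over `1:truncation` and its mean.
#' @examples
#' d <- length_distribution("zipf", 2)
#' sum(length_pmf(d, 1:150))  # 1
#' @export
length_distribution <- function(family = c("zipf", "geometric", "poisson"),
                                parameter, truncation = 150L) {
  family <- match.arg(family)
  stopifnot(is.numeric(parameter), length(parameter) == 1L, parameter > 0)
  if (family == "geometric" && parameter > 1)
    stop("geometric success probability must lie in (0, 1]")
  truncation <- as.integer(truncation)
  stopifnot(truncation >= 1L)
  pmf <- pmf_vector(family, parameter, truncation)
  structure(
    list(family = family, parameter = parameter, truncation = truncation,
         pmf = pmf, mean = sum(seq_len(truncation) * pmf)),
    class = "length_distribution")
}

# Unnormalized weights -> renormalized pmf over 1..truncation.
pmf_vector <- function(family, parameter, truncation) {
  k <- seq_len(truncation)
  w <- switch(family,
    zipf      = k^(-parameter),
    geometric = stats::dgeom(k - 1L, prob = parameter),
    poisson   = stats::dpois(k, lambda = parameter))
  s <- sum(w)
  if (!is.finite(s) || s <= 0)
    stop("degenerate length distribution: all truncated mass is zero")
  w / s
}

#' @export
print.length_distribution <- function(x, ...) {
  cat(sprintf("Truncated %s length distribution (parameter %.6g, <= %d sites)\n",
              x$family, x$parameter, x$truncation))
  cat(sprintf("  mean length: %.4f sites\n", x$mean))
  invisible(x)
}

#' Probability mass of a truncated length distribution
#'
#' @param dist A [length_distribution()].
#' @param k Integer vector of lengths, each within `1:dist$truncation`.
#' @return Probabilities `P(length = k | length <= truncation)`.
#' @export
length_pmf <- function(dist, k) {
  stopifnot(inherits(dist, "length_distribution"))
  k <- as.integer(k)
  if (any(k < 1L | k > dist$truncation))
    stop("length outside the distribution's support 1..", dist$truncation)
  dist$pmf[k]
}

#' Mean of a truncated length distribution
#'
#' @param dist A [length_distribution()].
#' @return The expected indel length, `sum(k * pmf(k))` over the truncated
#'   support.
#' @export
mean_length <- function(dist) {
  stopifnot(inherits(dist, "length_distribution"))
  dist$mean
}

#' Invert the truncated mean to the native parameter
#'
#' Finds the distribution parameter whose truncated mean equals
#' `target_mean`. The truncated means are strictly monotone in the parameter
#' for every family (decreasing for Zipf and geometric, increasing for
#' Poisson), so a bracketing root search converges. This is how the shared
#' mean-length prior is mapped onto each family's own parameter.
#'
#' @param family One of `"zipf"`, `"geometric"`, `"poisson"`.
#' @param target_mean Desired mean length, in sites.
#' @param truncation Maximum indel length (default 150).
#' @param tol Absolute tolerance on the achieved mean (default 1e-9).
#' @return The scalar parameter value.
#' @export
parameter_for_mean <- function(family = c("zipf", "geometric", "poisson"),
                               target_mean, truncation = 150L, tol = 1e-9) {
  family <- match.arg(family)
  truncation <- as.integer(truncation)
  interval <- switch(family,
    zipf      = c(0, 60),
    geometric = c(1e-12, 1),
    poisson   = c(1e-12, 4 * truncation))
  f <- function(p) {
    pmf <- pmf_vector(family, max(p, 1e-12), truncation)
    sum(seq_len(truncation) * pmf) - target_mean
  }
  lo <- f(interval[1]); hi <- f(interval[2])
  if (sign(lo) == sign(hi))
    stop(sprintf("target mean %.4g not achievable for the %s family truncated at %d",
                 target_mean, family, truncation))
  root <- stats::uniroot(f, interval, tol = tol * 1e-3,
                         f.lower = lo, f.upper = hi)$root
  root <- max(root, 1e-12)
  if (family == "geometric") root <- min(root, 1)
  achieved <- f(root) + target_mean
  if (abs(achieved - target_mean) > 1e-6)
    stop("root search failed to reach the target mean")
  root
}

#' Sample indel lengths
#'
#' Draws event lengths from a truncated length distribution using R's
#' global random number generator.
#'
#' @param dist A [length_distribution()].
#' @param n Number of draws.
#' @return Integer vector of lengths in `1:dist$truncation`.
#' @export
sample_length <- function(dist, n = 1L) {
  stopifnot(inherits(dist, "length_distribution"))
  sample.int(dist$truncation, size = n, replace = TRUE, prob = dist$pmf)
}
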