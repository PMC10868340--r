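# Posterior predictive adequacy. Model selection only ranks the candidate
# models relative to one another; the adequacy test asks whether the
# selected model can reproduce the empirical gap pattern at all. Each of
# the 27 empirical statistics receives a posterior predictive p-value (its
# percentile rank in a predictive simulation cloud), and the adequacy
# match (AM) score is the fraction of p-values inside [0.025, 0.975].

#' Percentile rank of an observed value in a simulated cloud
#'
#' Uses mid-ranks for ties and offsets the rank by one half over n + 1, so
#' the p-value can never be exactly 0 or 1 even when the observation lies
#' outside the simulated range.
#'
#' @param observed Scalar observed value.
#' @param simulated Numeric vector of simulated values.
#' @return p in (0, 1).
#' @export
percentile_rank <- function(observed, simulated) {
  n <- length(simulated)
  stopifnot(n >= 1L)
  r <- sum(simulated < observed) + 0.5 * sum(simulated == observed)
  (r + 0.5) / (n + 1)
}

#' Adequacy report from a vector of posterior predictive p-values
#'
#' @param pvalues Numeric vector of 27 p-values in `[0, 1]`.
#' @param n_predictive Number of predictive simulations behind the
#'   p-values (NA when constructed directly).
#' @param seed Seed used for the predictive simulations, if any.
#' @param interval Central interval defining adequacy (default
#'   `c(0.025, 0.975)`).
#' @return An object of class `adequacy_report` with the p-values and the
#'   AM score (fraction of p-values inside the interval; each p-value
#'   outside it lowers the score by exactly 1/27).
#' @export
adequacy_report <- function(pvalues, n_predictive = NA_integer_,
                            seed = NA_integer_, interval = c(0.025, 0.975)) {
  stopifnot(length(pvalues) == N_SUMMARY_STATS,
            all(pvalues >= 0 & pvalues <= 1))
  if (is.null(names(pvalues))) names(pvalues) <- summary_stat_names()
  inside <- pvalues >= interval[1] & pvalues <= interval[2]
  structure(
    list(pvalues = pvalues, am = sum(inside) / N_SUMMARY_STATS,
         interval = interval, n_predictive = n_predictive, seed = seed),
    class = "adequacy_report")
}

#' @export
print.adequacy_report <- function(x, ...) {
  cat(sprintf("Adequacy match (AM) score: %.1f%% (%d of %d statistics inside [%g, %g])\n",
              100 * x$am, round(x$am * N_SUMMARY_STATS), N_SUMMARY_STATS,
              x$interval[1], x$interval[2]))
  invisible(x)
}

#' Posterior predictive p-values for the selected model
#'
#' Takes the `m_nearest` simulations of the selected model closest to the
#' empirical alignment (reusing the classification distances), resamples
#' their parameter sets uniformly with replacement `n_predictive` times,
#' simulates an alignment from each resampled parameter set, and computes
#' the percentile rank of every empirical statistic in the resulting
#' predictive distributions.
#'
#' @param empirical_stats 27-vector of empirical summary statistics.
#' @param tables Reference tables used for classification.
#' @param result The [classify()] result.
#' @param tree Rooted `phylo` (the dataset's tree).
#' @param n_predictive Number of predictive simulations (paper scale
#'   10000; desk scale 500-1000).
#' @param m_nearest Number of closest selected-model simulations whose
#'   parameters are resampled (default 50).
#' @param correction Optional `correction_model` applied to predictive
#'   statistics, matching the treatment of the reference tables.
#' @param seed Optional integer seed.
#' @return An `adequacy_report`.
#' @export
posterior_predictive <- function(empirical_stats, tables, result, tree,
                                 n_predictive = 10000L, m_nearest = 50L,
                                 correction = NULL, seed = NULL) {
  stopifnot(inherits(result, "classification_result"))
  if (!is.null(seed)) set.seed(seed)
  sel <- result$selected_model
  tb <- tables[[sel]]
  idx <- which(result$labels == sel)
  if (length(idx) < m_nearest)
    stop("selected model has fewer than m_nearest simulations in its table")
  idx <- idx[order(result$distances[idx], idx)][seq_len(m_nearest)]
  rows <- result$model_row[idx]
  pick <- rows[sample.int(m_nearest, n_predictive, replace = TRUE)]
  sims <- matrix(NA_real_, n_predictive, N_SUMMARY_STATS)
  for (i in seq_len(n_predictive)) {
    model <- model_from_params(tb$family, tb$variant,
                               as.numeric(tb$params[pick[i], ]) |>
                                 stats::setNames(colnames(tb$params)))
    sims[i, ] <- compute_summary_statistics(simulate_msa(tree, model))
  }
  if (!is.null(correction)) sims <- apply_correction(correction, sims)
  p <- vapply(seq_len(N_SUMMARY_STATS), function(j)
    percentile_rank(empirical_stats[[j]], sims[, j]), numeric(1))
  names(p) <- summary_stat_names()
  adequacy_report(p, n_predictive = n_predictive,
                  seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Flag statistics with extreme posterior predictive p-values
#'
#' @param report An [adequacy_report()].
#' @return Data frame of flagged statistics with their p-values and the
#'   direction of the discrepancy (`"low"` or `"high"`); empty when the AM
#'   score is 1.
#' @export
flag_inadequate <- function(report) {
  stopifnot(inherits(report, "adequacy_report"))
  p <- report$pvalues
  low <- p < report$interval[1]
  high <- p > report$interval[2]
  data.frame(statistic = names(p)[low | high],
             p_value = unname(p[low | high]),
             direction = c("low", "high")[1L + high[low | high]])
}
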