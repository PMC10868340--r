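# Indel model structure and priors. A model couples insertion and deletion
# rates (events per substitution per site) with a length distribution for
# each event type, plus the root sequence length. The SIM variant ties the
# two event types to one shared (rate, length) pair; RIM draws them
# independently.

MODEL_FAMILIES <- c("zipf", "geometric", "poisson")
MODEL_VARIANTS <- c("SIM", "RIM")
PARAM_NAMES <- c("root_length", "log10_total_rate", "log10_rate_ratio",
                 "total_rate", "insertion_rate", "deletion_rate",
                 "ins_mean", "del_mean", "ins_param", "del_param")

#' Fixed order of the six candidate model labels
#'
#' Family x variant labels, in the order used for tie-breaking and for
#' reporting counts. Labels look like `"zipf-SIM"`.
#'
#' @param families Families to include.
#' @param variants Variants to include.
#' @return Character vector of labels.
#' @export
model_labels <- function(families = MODEL_FAMILIES, variants = MODEL_VARIANTS) {
  as.vector(t(outer(families, variants, paste, sep = "-")))
}

#' Indel model
#'
#' @param family Length-distribution family shared by both event types.
#' @param variant `"SIM"` (insertions and deletions share one rate and one
#'   length distribution) or `"RIM"` (independent parameters).
#' @param insertion_rate,deletion_rate Event rates per substitution per site.
#' @param insertion_length,deletion_length [length_distribution()] objects.
#' @param root_length Root sequence length in sites (positive integer).
#' @return An object of class `indel_model`.
#' @export
indel_model <- function(family, variant, insertion_rate, deletion_rate,
                        insertion_length, deletion_length, root_length) {
  family <- match.arg(family, MODEL_FAMILIES)
  variant <- match.arg(variant, MODEL_VARIANTS)
  stopifnot(insertion_rate >= 0, deletion_rate >= 0,
            inherits(insertion_length, "length_distribution"),
            inherits(deletion_length, "length_distribution"),
            root_length >= 1)
  if (variant == "SIM") {
    if (insertion_rate != deletion_rate ||
        !identical(insertion_length[c("family", "parameter", "truncation")],
                   deletion_length[c("family", "parameter", "truncation")]))
      stop("SIM requires identical insertion and deletion parameters")
  }
  structure(
    list(family = family, variant = variant,
         insertion_rate = insertion_rate, deletion_rate = deletion_rate,
         insertion_length = insertion_length, deletion_length = deletion_length,
         root_length = as.integer(root_length),
         label = paste(family, variant, sep = "-")),
    class = "indel_model")
}

#' @export
print.indel_model <- function(x, ...) {
  cat(sprintf("Indel model %s\n", x$label))
  cat(sprintf("  insertion rate %.4g, deletion rate %.4g (events/substitution/site)\n",
              x$insertion_rate, x$deletion_rate))
  cat(sprintf("  insertion mean length %.3f, deletion mean length %.3f\n",
              x$insertion_length$mean, x$deletion_length$mean))
  cat(sprintf("  root length %d sites\n", x$root_length))
  invisible(x)
}

#' Prior configuration
#'
#' Uniform priors shared by all six candidate models. The root length prior
#' is anchored on the empirical alignment: uniform between
#' `root_length_low_factor * SSA` and `root_length_high_factor * LSA`, where
#' SSA and LSA are the shortest and longest ungapped sequence lengths. The
#' total indel rate and the insertion/deletion rate ratio are log10-uniform,
#' and the mean indel length is uniform, mapped to each family's native
#' parameter by [parameter_for_mean()].
#'
#' @param root_length_low_factor,root_length_high_factor Multipliers applied
#'   to SSA and LSA (defaults 0.8 and 1.1).
#' @param log10_total_rate Bounds of the log10 of insertion rate plus
#'   deletion rate (default `c(-4, -1)`).
#' @param log10_rate_ratio Bounds of the log10 of insertion rate over
#'   deletion rate (default `c(-1, 1)`); see Details for the orientation.
#' @param mean_length Bounds of the mean indel length in sites
#'   (default `c(1.5, 25)`).
#' @param truncation Truncation point of every length distribution
#'   (fixed at 150 sites by default).
#' @details The rate ratio is oriented as insertion/deletion; since its
#'   prior is symmetric about zero on the log scale the orientation does not
#'   change the model space, only the reported sign.
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(root_length_low_factor = 0.8,
                         root_length_high_factor = 1.1,
                         log10_total_rate = c(-4, -1),
                         log10_rate_ratio = c(-1, 1),
                         mean_length = c(1.5, 25),
                         truncation = 150L) {
  stopifnot(root_length_low_factor > 0, root_length_high_factor > 0,
            length(log10_total_rate) == 2L, diff(log10_total_rate) >= 0,
            length(log10_rate_ratio) == 2L, diff(log10_rate_ratio) >= 0,
            length(mean_length) == 2L, diff(mean_length) >= 0,
            mean_length[1] > 1)
  structure(
    list(root_length_low_factor = root_length_low_factor,
         root_length_high_factor = root_length_high_factor,
         log10_total_rate = log10_total_rate,
         log10_rate_ratio = log10_rate_ratio,
         mean_length = mean_length,
         truncation = as.integer(truncation)),
    class = "prior_config")
}

# Draw one (rate, length-distribution) parameter set for one event type.
draw_event_params <- function(prior, family) {
  m <- stats::runif(1L, prior$mean_length[1], prior$mean_length[2])
  p <- parameter_for_mean(family, m, prior$truncation)
  list(mean = m, parameter = p,
       dist = length_distribution(family, p, prior$truncation))
}

#' Draw an indel model from the prior
#'
#' Samples the root length, the total rate and rate ratio (decomposed into
#' insertion and deletion rates), and the length-distribution parameter(s)
#' for one candidate model. Under SIM a single draw of (total rate, mean
#' length) is shared by insertions and deletions, with the rate split
#' equally; under RIM the ratio and a second length draw make the two event
#' types independent.
#'
#' @param prior A [prior_config()].
#' @param family,variant Candidate model identity.
#' @param ssa,lsa Shortest and longest ungapped sequence lengths of the
#'   empirical alignment, anchoring the root length prior.
#' @return An `indel_model` with a `params` attribute: the raw prior draws
#'   (root length, log10 total rate, log10 ratio, means and native length
#'   parameters), used for posterior summaries and predictive resampling.
#' @export
sample_model <- function(prior, family, variant, ssa, lsa) {
  family <- match.arg(family, MODEL_FAMILIES)
  variant <- match.arg(variant, MODEL_VARIANTS)
  stopifnot(inherits(prior, "prior_config"), ssa >= 1, ssa <= lsa)
  lo <- ceiling(prior$root_length_low_factor * ssa)
  hi <- floor(prior$root_length_high_factor * lsa)
  if (hi < lo) stop("empty root length prior: check SSA/LSA")
  root_length <- sample.int(hi - lo + 1L, 1L) + lo - 1L

  u_rate <- stats::runif(1L, prior$log10_total_rate[1], prior$log10_total_rate[2])
  total_rate <- 10^u_rate
  if (variant == "SIM") {
    u_ratio <- 0
    ins_rate <- del_rate <- total_rate / 2
    ins <- draw_event_params(prior, family)
    del <- ins
  } else {
    u_ratio <- stats::runif(1L, prior$log10_rate_ratio[1], prior$log10_rate_ratio[2])
    q <- 10^u_ratio
    ins_rate <- total_rate * q / (1 + q)
    del_rate <- total_rate / (1 + q)
    ins <- draw_event_params(prior, family)
    del <- draw_event_params(prior, family)
  }
  model <- indel_model(family, variant, ins_rate, del_rate,
                       ins$dist, del$dist, root_length)
  attr(model, "params") <- c(
    root_length = root_length, log10_total_rate = u_rate,
    log10_rate_ratio = u_ratio, total_rate = total_rate,
    insertion_rate = ins_rate, deletion_rate = del_rate,
    ins_mean = ins$mean, del_mean = del$mean,
    ins_param = ins$parameter, del_param = del$parameter)
  model
}

# Rebuild an indel_model from a stored parameter draw (one row of a
# reference table), without re-running the mean inversion.
model_from_params <- function(family, variant, params, truncation = 150L) {
  ins_dist <- length_distribution(family, params[["ins_param"]], truncation)
  del_dist <- if (variant == "SIM") ins_dist else
    length_distribution(family, params[["del_param"]], truncation)
  indel_model(family, variant,
              params[["insertion_rate"]], params[["deletion_rate"]],
              ins_dist, del_dist, params[["root_length"]])
}
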