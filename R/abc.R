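# Rejection-ABC model selection. Reference tables of prior draws paired
# with (corrected) summary statistics are built per candidate model; the
# empirical alignment is classified by the model labels of its k nearest
# simulations under the Mahalanobis distance, with SIM/RIM grouped into
# families for the posterior support.

#' Build per-model reference tables
#'
#' For each candidate model (family x variant) draws `n_per_model`
#' parameter sets from the prior, simulates an alignment along the tree for
#' each, computes the 27 summary statistics, and applies the alignment-bias
#' correction if one is supplied.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param prior A [prior_config()].
#' @param ssa,lsa Root-length prior anchors from the empirical alignment.
#' @param families,variants Candidate model grid.
#' @param n_per_model Simulations per model (paper scale 500500; desk scale
#'   a few thousand).
#' @param correction `NULL`, a single `correction_model`, or a named list
#'   of per-model-label correction models.
#' @param seed Optional integer seed for reproducibility.
#' @return A list of `reference_table` objects, one per model label, each
#'   holding the parameter draws and the row-aligned statistics matrix.
#' @export
build_reference <- function(tree, prior, ssa, lsa,
                            families = MODEL_FAMILIES,
                            variants = MODEL_VARIANTS,
                            n_per_model = 5000L, correction = NULL,
                            seed = NULL) {
  check_phylogeny(tree)
  n_per_model <- as.integer(n_per_model)
  if (!is.null(seed)) set.seed(seed)
  labels <- model_labels(families, variants)
  tables <- vector("list", length(labels))
  names(tables) <- labels
  for (lab in labels) {
    parts <- strsplit(lab, "-", fixed = TRUE)[[1L]]
    family <- parts[1L]; variant <- parts[2L]
    params <- matrix(NA_real_, n_per_model, length(PARAM_NAMES))
    stats_m <- matrix(NA_real_, n_per_model, N_SUMMARY_STATS)
    for (i in seq_len(n_per_model)) {
      model <- sample_model(prior, family, variant, ssa, lsa)
      params[i, ] <- attr(model, "params")[PARAM_NAMES]
      stats_m[i, ] <- compute_summary_statistics(simulate_msa(tree, model))
    }
    colnames(params) <- PARAM_NAMES
    colnames(stats_m) <- summary_stat_names()
    corr <- if (is.list(correction) && !inherits(correction, "correction_model"))
      correction[[lab]] else correction
    if (!is.null(corr)) stats_m <- apply_correction(corr, stats_m)
    tables[[lab]] <- structure(
      list(label = lab, family = family, variant = variant,
           params = as.data.frame(params), stats = stats_m,
           n = n_per_model, seed = seed),
      class = "reference_table")
  }
  tables
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("Reference table %s: %d simulations x %d statistics\n",
              x$label, x$n, ncol(x$stats)))
  invisible(x)
}

#' Mahalanobis distance between two statistic vectors
#'
#' @param x,y Numeric vectors of equal length.
#' @param cov_inverse Symmetric positive-definite inverse covariance.
#' @return `sqrt((x - y)' cov_inverse (x - y))`.
#' @export
mahalanobis_distance <- function(x, y, cov_inverse) {
  d <- as.numeric(x) - as.numeric(y)
  stopifnot(length(d) == nrow(cov_inverse), nrow(cov_inverse) == ncol(cov_inverse))
  sqrt(drop(t(d) %*% cov_inverse %*% d))
}

# Regularized inverse of the statistics covariance. Several statistics are
# near-collinear by construction (e.g. column count, LSA, SSA, average
# length), so the pooled covariance is rank-deficient and a plain solve()
# would load the distance onto numerical-noise directions. Deterministic
# fix: eigendecompose and floor the spectrum at `tol` times the leading
# eigenvalue before inverting, i.e. Mahalanobis distance in a spectrally
# stabilized metric.
guarded_inverse <- function(C, tol = 1e-10) {
  e <- eigen(C, symmetric = TRUE)
  if (max(e$values) <= 0) stop("covariance matrix has no positive spectrum")
  vals <- pmax(e$values, tol * max(e$values))
  e$vectors %*% (t(e$vectors) / vals)
}

# Pool the reference tables into one matrix with per-row provenance and a
# ready inverse covariance over the active (non-constant, non-excluded)
# statistic columns. Reused across many classifications of the same tables.
prepare_reference <- function(tables,
                              covariance = c("pooled", "per_model", "identity"),
                              exclude_features = NULL) {
  covariance <- match.arg(covariance)
  S <- do.call(rbind, lapply(tables, function(tb) tb$stats))
  labels <- rep(vapply(tables, `[[`, "", "label"),
                vapply(tables, `[[`, 0L, "n"))
  model_row <- unlist(lapply(tables, function(tb) seq_len(tb$n)),
                      use.names = FALSE)
  active <- which(apply(S, 2L, stats::var) > 0)
  if (length(dropped <- setdiff(seq_len(ncol(S)), active)))
    warning("dropping zero-variance statistics from the distance: ",
            paste(summary_stat_names()[dropped], collapse = ", "))
  active <- setdiff(active, exclude_features)
  if (length(active) < 1L) stop("no informative statistics left")
  C <- switch(covariance,
    pooled = stats::cov(S[, active, drop = FALSE]),
    per_model = Reduce(`+`, lapply(tables, function(tb)
      stats::cov(tb$stats[, active, drop = FALSE]))) / length(tables),
    identity = diag(length(active)))
  list(S = S, labels = labels, model_row = model_row,
       active = active, cov_inverse = guarded_inverse(C),
       covariance = covariance)
}

# Squared Mahalanobis distances from every pooled row to x.
reference_distances <- function(prep, x) {
  D <- sweep(prep$S[, prep$active, drop = FALSE], 2L, x[prep$active])
  sqrt(pmax(rowSums((D %*% prep$cov_inverse) * D), 0))
}

#' Summarize nearest-neighbor counts into a model-selection call
#'
#' Given the number of nearest simulations per candidate model, selects the
#' variant-level winner (modal label, ties broken by the fixed label order
#' of [model_labels()]), groups SIM and RIM into families, and reports the
#' family posterior supports (grouped counts over k).
#'
#' @param counts Named integer vector of nearest-neighbor counts, names
#'   being model labels like `"zipf-RIM"`.
#' @return List with `counts`, `k`, `selected_model`, `selected_family`,
#'   and `family_support`.
#' @export
classify_counts <- function(counts) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  fam <- vapply(strsplit(names(counts), "-", fixed = TRUE), `[[`, "", 1L)
  families <- intersect(MODEL_FAMILIES, unique(fam))
  order_ref <- model_labels(families)
  counts <- counts[order(match(names(counts), order_ref))]
  fam <- vapply(strsplit(names(counts), "-", fixed = TRUE), `[[`, "", 1L)
  k <- sum(counts)
  grouped <- vapply(families, function(f) sum(counts[fam == f]), numeric(1))
  list(counts = counts, k = k,
       selected_model = names(counts)[which.max(counts)],
       selected_family = families[which.max(grouped)],
       family_support = grouped / k)
}

#' Classify an alignment by rejection ABC
#'
#' Estimates the statistic covariance from the pooled simulations of all
#' candidate models, computes the Mahalanobis distance from the empirical
#' statistics to every simulation, selects the `k` nearest (ties at the
#' k-th distance broken by simulation index), and classifies by the modal
#' model label, grouping SIM/RIM for the family-level posterior support.
#'
#' @param empirical_stats 27-vector of the empirical alignment's summary
#'   statistics.
#' @param tables Reference tables from [build_reference()].
#' @param k Number of accepted simulations (default 100).
#' @param covariance `"pooled"` (default), `"per_model"`, or `"identity"`
#'   (Euclidean distance).
#' @param exclude_features Integer indices of statistics to drop from the
#'   distance (feature-ablation support).
#' @param prep Precomputed [prepare_reference] output, to reuse across many
#'   classifications of the same tables.
#' @return An object of class `classification_result`.
#' @export
classify <- function(empirical_stats, tables, k = 100L,
                     covariance = c("pooled", "per_model", "identity"),
                     exclude_features = NULL, prep = NULL) {
  if (is.null(prep))
    prep <- prepare_reference(tables, match.arg(covariance), exclude_features)
  stopifnot(length(empirical_stats) == N_SUMMARY_STATS)
  N <- nrow(prep$S)
  if (N < k) stop("reference tables hold fewer than k simulations")
  d <- reference_distances(prep, as.numeric(empirical_stats))
  ord <- order(d, seq_len(N))  # deterministic tie-break by pooled row index
  nn <- ord[seq_len(k)]
  counts <- table(factor(prep$labels[nn], levels = names(tables)))
  call <- classify_counts(stats::setNames(as.integer(counts), names(counts)))
  structure(
    c(call,
      list(neighbors = data.frame(rank = seq_len(k), index = nn,
                                  label = prep$labels[nn],
                                  model_row = prep$model_row[nn],
                                  distance = d[nn]),
          distances = d, labels = prep$labels, model_row = prep$model_row,
          features_used = prep$active, covariance = prep$covariance)),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("Selected model: %s (family %s)\n",
              x$selected_model, x$selected_family))
  cat("Nearest-neighbor counts:\n")
  print(x$counts)
  cat("Family posterior support:\n")
  print(round(x$family_support, 3))
  invisible(x)
}

#' Posterior summaries of the selected model's parameters
#'
#' Takes the `k` simulations of the selected variant-level model that are
#' closest to the empirical alignment (the ABC-accepted draws) and
#' summarizes each parameter by its mean, standard deviation, and 5/50/95%
#' quantiles.
#'
#' @param result A [classify()] result.
#' @param tables The reference tables used for classification.
#' @param k Number of accepted draws (defaults to the classification `k`).
#' @return List with `draws` (data frame of accepted parameter rows) and
#'   `summary` (one row per parameter).
#' @export
estimate_posteriors <- function(result, tables, k = NULL) {
  stopifnot(inherits(result, "classification_result"))
  if (is.null(k)) k <- result$k
  sel <- result$selected_model
  idx <- which(result$labels == sel)
  idx <- idx[order(result$distances[idx], idx)]
  idx <- idx[seq_len(min(k, length(idx)))]
  draws <- tables[[sel]]$params[result$model_row[idx], , drop = FALSE]
  qs <- t(vapply(draws, function(v)
    c(mean = mean(v), sd = stats::sd(v),
      stats::quantile(v, c(0.05, 0.5, 0.95), names = FALSE)),
    numeric(5)))
  colnames(qs) <- c("mean", "sd", "q05", "q50", "q95")
  list(model = sel, draws = draws,
       summary = data.frame(parameter = rownames(qs), qs, row.names = NULL))
}

#' Self-classification experiment (confusion matrix)
#'
#' Simulates labeled test alignments from every length-distribution family
#' (half SIM, half RIM), classifies each against reference tables built
#' from the same priors, and tabulates the family-level confusion matrix
#' and per-family accuracies. Test alignments are rejection-sampled to
#' pass the dataset filter (at least `min_unique_gaps` unique gaps) so the
#' experiment mirrors the inclusion rule applied to empirical data.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param prior A [prior_config()].
#' @param ssa,lsa Root-length prior anchors.
#' @param n_test_per_family Test alignments per family (split evenly
#'   between SIM and RIM).
#' @param n_per_model Reference simulations per model.
#' @param k Accepted neighbors per classification.
#' @param require_valid Apply the unique-gap filter to test alignments.
#' @param min_unique_gaps Unique-gap threshold for the test corpus.
#' @param tables,corpus Optional prebuilt reference tables / labeled corpus
#'   (see [make_labeled_corpus()]) to reuse.
#' @param seed Optional integer seed.
#' @return An object of class `confusion_report` with the 3x3 family
#'   confusion matrix, per-family accuracies, and their minimum.
#' @export
self_test_confusion <- function(tree, prior, ssa, lsa,
                                n_test_per_family = 30L, n_per_model = 5000L,
                                k = 100L, require_valid = TRUE,
                                min_unique_gaps = 20L,
                                tables = NULL, corpus = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tables))
    tables <- build_reference(tree, prior, ssa, lsa, n_per_model = n_per_model)
  if (is.null(corpus))
    corpus <- make_labeled_corpus(tree, prior, n_test_per_family, ssa, lsa,
                                  require_valid = require_valid,
                                  min_unique_gaps = min_unique_gaps)
  prep <- prepare_reference(tables)
  predicted <- vapply(seq_len(nrow(corpus$stats)), function(i)
    classify(corpus$stats[i, ], tables, k = k, prep = prep)$selected_family,
    character(1))
  truth <- factor(corpus$labels$family, levels = MODEL_FAMILIES)
  predicted <- factor(predicted, levels = MODEL_FAMILIES)
  confusion <- table(truth = truth, predicted = predicted)
  acc <- diag(confusion) / pmax(rowSums(confusion), 1L)
  structure(
    list(confusion = confusion, per_family_accuracy = acc,
         min_accuracy = min(acc), overall_accuracy = mean(predicted == truth),
         n_test_per_family = n_test_per_family, n_per_model = n_per_model,
         k = k, seed = seed),
    class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("Family-level confusion matrix (rows = truth):\n")
  print(x$confusion)
  cat(sprintf("Per-family accuracy: %s\n",
              paste(sprintf("%s %.1f%%", names(x$per_family_accuracy),
                            100 * x$per_family_accuracy), collapse = ", ")))
  cat(sprintf("Minimum accuracy: %.1f%%\n", 100 * x$min_accuracy))
  invisible(x)
}

#' Feature ablation of the classification scheme
#'
#' Reruns the self-classification experiment with one statistic at a time
#' excluded from the distance and reports the resulting accuracy drop. The
#' reference tables and test corpus are reused across exclusions so that
#' only the distance changes.
#'
#' @param tables Reference tables from [build_reference()].
#' @param corpus A labeled corpus from [make_labeled_corpus()].
#' @param features Statistic indices to ablate (default all 27).
#' @param k Accepted neighbors per classification.
#' @return Data frame with one row per excluded feature: accuracy with the
#'   feature removed and the delta versus the full set.
#' @export
feature_ablation <- function(tables, corpus, features = seq_len(N_SUMMARY_STATS),
                             k = 100L) {
  acc_with <- function(exclude) {
    prep <- prepare_reference(tables, exclude_features = exclude)
    pred <- vapply(seq_len(nrow(corpus$stats)), function(i)
      classify(corpus$stats[i, ], tables, k = k, prep = prep)$selected_family,
      character(1))
    mean(pred == corpus$labels$family)
  }
  baseline <- acc_with(NULL)
  acc <- vapply(features, acc_with, numeric(1))
  data.frame(feature = features, name = summary_stat_names()[features],
             accuracy = acc, baseline = baseline, delta = acc - baseline)
}
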