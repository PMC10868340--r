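# Synthetic fixtures: trees, labeled simulation corpora, and the dataset
# validators applied to empirical alignments before analysis.

#' Generate a synthetic rooted tree
#'
#' Builds a rooted tree of a requested shape with branch lengths rescaled
#' to a target total, as a stand-in for an empirical phylogeny.
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param total_length Target sum of branch lengths, in substitutions per
#'   site.
#' @param shape `"balanced"` (n a power of two), `"caterpillar"`,
#'   `"star"`, or `"coalescent"` (random coalescent; deterministic under
#'   `seed`).
#' @param seed Optional integer seed.
#' @return A rooted `phylo` with branch lengths.
#' @export
make_tree <- function(n_taxa, total_length = 2,
                      shape = c("coalescent", "balanced", "caterpillar", "star"),
                      seed = NULL) {
  shape <- match.arg(shape)
  stopifnot(n_taxa >= 2, total_length > 0)
  if (!is.null(seed)) set.seed(seed)
  tree <- switch(shape,
    coalescent = ape::rcoal(n_taxa),
    balanced = {
      if (log2(n_taxa) %% 1 != 0)
        stop("balanced shape requires a power-of-two taxon count")
      ape::stree(n_taxa, "balanced")
    },
    caterpillar = ape::stree(n_taxa, "left"),
    star = {
      # a star has a basal polytomy; mark the root explicitly so the
      # rootedness check accepts it
      st <- ape::stree(n_taxa, "star"); st$root.edge <- 0; st
    })
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(1, nrow(tree$edge))
  tree$edge.length <- tree$edge.length * total_length / sum(tree$edge.length)
  tree$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  check_phylogeny(tree)
  tree
}

#' Validate a dataset against the analysis inclusion filters
#'
#' Empirical analyses are restricted to alignments whose tree has total
#' branch length above `min_total_branch_length` (the ABC scheme's
#' accuracy degrades on shorter trees) and that contain at least
#' `min_unique_gaps` unique gaps (the statistics are gap-pattern
#' functions).
#'
#' @param msa An alignment (`true_msa`, character matrix, or logical gap
#'   mask).
#' @param tree The associated rooted `phylo`.
#' @param min_total_branch_length Threshold on the summed branch lengths
#'   (default 1).
#' @param min_unique_gaps Threshold on the unique-gap count (default 20).
#' @return List with `pass` (logical), `reasons` (character), and the
#'   measured `total_branch_length` and `unique_gaps`.
#' @export
validate_dataset <- function(msa, tree, min_total_branch_length = 1,
                             min_unique_gaps = 20L) {
  check_phylogeny(tree)
  tbl <- sum(tree$edge.length)
  ug <- nrow(unique_gaps(find_gap_blocks(msa)))
  reasons <- character(0)
  if (tbl <= min_total_branch_length)
    reasons <- c(reasons, sprintf("total branch length %.4g <= %.4g",
                                  tbl, min_total_branch_length))
  if (ug < min_unique_gaps)
    reasons <- c(reasons, sprintf("unique gaps %d < %d", ug, min_unique_gaps))
  list(pass = length(reasons) == 0L, reasons = reasons,
       total_branch_length = tbl, unique_gaps = ug)
}

#' Simulate a labeled test corpus
#'
#' Draws `n_per_family` alignments per length-distribution family, split
#' evenly between the SIM and RIM variants, with parameters from the
#' prior. When `require_valid` is set, draws failing the unique-gap filter
#' of [validate_dataset()] are rejected and redrawn, so the corpus mirrors
#' the datasets the analysis pipeline would accept.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param prior A [prior_config()].
#' @param n_per_family Alignments per family.
#' @param ssa,lsa Root-length prior anchors.
#' @param require_valid Rejection-sample to >= `min_unique_gaps` unique
#'   gaps.
#' @param min_unique_gaps Filter threshold (default 20).
#' @param max_tries Redraw budget per alignment before keeping the last
#'   draw with a warning.
#' @param keep_msa Also store the simulated `true_msa` objects.
#' @param seed Optional integer seed.
#' @return List with `stats` (matrix), `labels` (data frame: family,
#'   variant, label), `params` (matrix of generating draws), and
#'   optionally `msas`.
#' @export
make_labeled_corpus <- function(tree, prior, n_per_family, ssa, lsa,
                                require_valid = TRUE, min_unique_gaps = 20L,
                                max_tries = 400L, keep_msa = FALSE,
                                seed = NULL) {
  check_phylogeny(tree)
  if (!is.null(seed)) set.seed(seed)
  n_sim <- ceiling(n_per_family / 2)
  variants <- c(rep("SIM", n_sim), rep("RIM", n_per_family - n_sim))
  total <- n_per_family * length(MODEL_FAMILIES)
  stats_m <- matrix(NA_real_, total, N_SUMMARY_STATS,
                    dimnames = list(NULL, summary_stat_names()))
  params <- matrix(NA_real_, total, length(PARAM_NAMES),
                   dimnames = list(NULL, PARAM_NAMES))
  labels <- data.frame(family = character(total), variant = character(total),
                       label = character(total))
  msas <- if (keep_msa) vector("list", total) else NULL
  row <- 0L
  for (family in MODEL_FAMILIES) {
    for (v in variants) {
      row <- row + 1L
      for (try in seq_len(max_tries)) {
        model <- sample_model(prior, family, v, ssa, lsa)
        msa <- simulate_msa(tree, model)
        s <- compute_summary_statistics(msa)
        ok <- !require_valid || s[["n_unique_gaps"]] >= min_unique_gaps
        if (ok) break
      }
      if (!ok) warning("corpus draw kept after ", max_tries,
                       " tries without passing the unique-gap filter")
      stats_m[row, ] <- s
      params[row, ] <- attr(model, "params")[PARAM_NAMES]
      labels[row, ] <- list(family, v, paste(family, v, sep = "-"))
      if (keep_msa) msas[[row]] <- msa
    }
  }
  out <- list(stats = stats_m, labels = labels, params = params, seed = seed)
  if (keep_msa) out$msas <- msas
  out
}
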