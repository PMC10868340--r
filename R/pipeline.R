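# End-to-end orchestration: empirical statistics -> reference tables ->
# optional alignment-bias correction -> ABC classification -> posterior
# summaries -> adequacy test, with full provenance (config hash, master
# seed, stage seeds) embedded in every report.

#' Pipeline configuration
#'
#' Collects every tunable of the classification pipeline. The defaults are
#' the full-scale settings (500500 simulations per model, k = 100, 500
#' correction pairs, 10000 predictive simulations); desk-scale runs
#' override `n_per_model` and `n_predictive` downward.
#'
#' @param families,variants Candidate model grid.
#' @param n_per_model Reference simulations per model.
#' @param k Accepted nearest neighbors.
#' @param correction Enable alignment-bias correction.
#' @param aligner An [aligner_spec()] used when `correction` is on (NULL
#'   trains the correction on identity pairs, i.e. a no-op).
#' @param correction_training Training pairs per model for the correction.
#' @param n_predictive Predictive simulations for the adequacy test.
#' @param m_nearest Selected-model simulations resampled for prediction.
#' @param alphabet Residue alphabet used when realigning.
#' @param validate Enforce the dataset filters of [validate_dataset()]
#'   (when FALSE a failing dataset only triggers a warning).
#' @param seed Master seed; stage seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(families = MODEL_FAMILIES,
                            variants = MODEL_VARIANTS,
                            n_per_model = 500500L, k = 100L,
                            correction = FALSE, aligner = NULL,
                            correction_training = 500L,
                            n_predictive = 10000L, m_nearest = 50L,
                            alphabet = "protein", validate = TRUE,
                            seed = 1L) {
  stopifnot(n_per_model >= 1L, k >= 1L, k <= n_per_model,
            correction_training >= 2L, n_predictive >= 1L, m_nearest >= 1L)
  structure(
    list(families = families, variants = variants,
         n_per_model = as.integer(n_per_model), k = as.integer(k),
         correction = isTRUE(correction), aligner = aligner,
         correction_training = as.integer(correction_training),
         n_predictive = as.integer(n_predictive),
         m_nearest = as.integer(m_nearest), alphabet = alphabet,
         validate = isTRUE(validate), seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Number of reference simulations a configuration schedules
#'
#' @param config A [pipeline_config()].
#' @return `n_per_model` times the number of candidate models (the
#'   full-scale default schedules 6 x 500500 = 3003000 simulations).
#' @export
scheduled_simulations <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  config$n_per_model * length(config$families) * length(config$variants)
}

#' Derive a stage seed from the master seed
#'
#' Deterministic linear-congruential split: stage `i` gets
#' `(master * 48271 + i * 7919) mod (2^31 - 1) + 1`, so every pipeline
#' stage can be rerun independently and reproducibly.
#'
#' @param master Master integer seed.
#' @param stage Stage index (1 = reference tables, 2 = correction,
#'   3 = adequacy, ...).
#' @return An integer seed below 2^31.
#' @export
child_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 48271 + as.numeric(stage) * 7919) %%
               2147483647) + 1L
}

#' Run the full classification pipeline on one dataset
#'
#' Computes the empirical summary statistics and the SSA/LSA anchors,
#' builds the reference tables (with optional alignment-bias correction),
#' classifies the dataset, summarizes the accepted parameter draws, and
#' runs the posterior predictive adequacy test. All randomness derives
#' from the config's master seed.
#'
#' @param msa Alignment: path to a FASTA file or a character matrix.
#' @param tree Tree: path to a newick file or a `phylo`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the report is written as
#'   `report.json` plus TSV tables (nearest neighbors, posterior summary,
#'   adequacy p-values).
#' @return The report as a list (classification, posterior summary,
#'   adequacy, validation, provenance).
#' @export
run_classify <- function(msa, tree, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(msa) && length(msa) == 1L) msa <- read_msa(msa)
  if (is.character(tree) && length(tree) == 1L) tree <- read_phylogeny(tree)
  check_phylogeny(tree)

  val <- validate_dataset(msa, tree)
  if (!val$pass) {
    msg <- paste("dataset fails inclusion filters:",
                 paste(val$reasons, collapse = "; "))
    if (config$validate) stop(msg) else warning(msg)
  }
  lens <- ungapped_lengths(msa)
  ssa <- min(lens); lsa <- max(lens)
  emp <- compute_summary_statistics(msa)

  correction <- NULL
  if (config$correction) {
    set.seed(child_seed(config$seed, 2L))
    labels <- model_labels(config$families, config$variants)
    correction <- stats::setNames(lapply(labels, function(lab) {
      parts <- strsplit(lab, "-", fixed = TRUE)[[1L]]
      build_correction(tree, prior_config(), parts[1L], parts[2L], ssa, lsa,
                       n_pairs = config$correction_training,
                       aligner = config$aligner, alphabet = config$alphabet)
    }), labels)
  }

  tables <- build_reference(tree, prior_config(), ssa, lsa,
                            families = config$families,
                            variants = config$variants,
                            n_per_model = config$n_per_model,
                            correction = correction,
                            seed = child_seed(config$seed, 1L))
  result <- classify(emp, tables, k = config$k)
  posterior <- estimate_posteriors(result, tables)
  adequacy <- posterior_predictive(
    emp, tables, result, tree,
    n_predictive = config$n_predictive, m_nearest = config$m_nearest,
    correction = if (is.null(correction)) NULL else
      correction[[result$selected_model]],
    seed = child_seed(config$seed, 3L))

  report <- list(
    provenance = list(
      package = "indelfit",
      config = config[setdiff(names(config), "aligner")],
      config_hash = rlang::hash(config),
      master_seed = config$seed,
      stage_seeds = list(reference = child_seed(config$seed, 1L),
                         correction = child_seed(config$seed, 2L),
                         adequacy = child_seed(config$seed, 3L))),
    dataset = list(n_sequences = nrow(as_gap_mask(msa)),
                   ssa = ssa, lsa = lsa,
                   validation = val),
    empirical_stats = as.list(emp),
    classification = list(
      selected_model = result$selected_model,
      selected_family = result$selected_family,
      counts = as.list(result$counts),
      family_support = as.list(result$family_support),
      k = result$k),
    posterior = list(model = posterior$model,
                     summary = posterior$summary),
    adequacy = list(am = adequacy$am,
                    pvalues = as.list(adequacy$pvalues),
                    flagged = flag_inadequate(adequacy),
                    n_predictive = adequacy$n_predictive))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(result$neighbors, file.path(out_dir, "neighbors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(posterior$summary, file.path(out_dir, "posterior.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(statistic = names(adequacy$pvalues),
                 p_value = unname(adequacy$pvalues)),
      file.path(out_dir, "adequacy.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' Run the self-classification experiment from a configuration
#'
#' @param tree Tree: path, `phylo`, or `NULL` for the default 30-taxon
#'   fixture tree (total branch length 2).
#' @param ssa,lsa Root-length prior anchors for the synthetic corpus.
#' @param n_test_per_family Test alignments per family.
#' @param min_unique_gaps Unique-gap threshold for the test corpus.
#' @param config A [pipeline_config()] providing `n_per_model`, `k`, and
#'   the master seed.
#' @param out_dir Optional output directory for `confusion.json` and
#'   `confusion.tsv`.
#' @return The `confusion_report`.
#' @export
run_selftest <- function(tree = NULL, ssa = 900L, lsa = 1000L,
                         n_test_per_family = 30L, min_unique_gaps = 20L,
                         config = pipeline_config(n_per_model = 5000L),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(tree))
    tree <- make_tree(30L, 2, "coalescent", seed = child_seed(config$seed, 9L))
  if (is.character(tree) && length(tree) == 1L) tree <- read_phylogeny(tree)
  report <- self_test_confusion(tree, prior_config(), ssa, lsa,
                                n_test_per_family = n_test_per_family,
                                n_per_model = config$n_per_model,
                                k = config$k,
                                min_unique_gaps = min_unique_gaps,
                                seed = child_seed(config$seed, 1L))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(provenance = list(config_hash = rlang::hash(config),
                             master_seed = config$seed),
           confusion = as.data.frame(report$confusion),
           per_family_accuracy = as.list(report$per_family_accuracy),
           min_accuracy = report$min_accuracy,
           overall_accuracy = report$overall_accuracy),
      file.path(out_dir, "confusion.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(as.data.frame(report$confusion),
                       file.path(out_dir, "confusion.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}
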