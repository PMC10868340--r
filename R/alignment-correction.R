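# Alignment-bias correction. Simulated true MSAs are error-free, but an
# empirical MSA was inferred by an alignment program and carries its
# biases. Rather than realigning every reference simulation, a regression
# is trained on a few hundred (true, realigned) summary-statistic pairs
# per model and applied to the remaining simulations, mapping true-MSA
# statistics to their expected post-alignment values.

#' External aligner specification
#'
#' Describes the command used to realign simulated sequences. The default
#' targets the MAFFT command line; any program that reads FASTA on the
#' command line and writes aligned FASTA to stdout fits the template.
#'
#' @param command Executable name or path.
#' @param args Character vector of arguments placed before the input file.
#' @return An object of class `aligner_spec`.
#' @export
aligner_spec <- function(command = "mafft", args = c("--auto", "--quiet")) {
  structure(list(command = command, args = args), class = "aligner_spec")
}

#' Realign ungapped sequences with an external aligner
#'
#' @param sequences Named character vector of ungapped sequences, or a
#'   character alignment matrix (gaps are stripped first).
#' @param aligner An [aligner_spec()].
#' @return The program's alignment as a character matrix, with attributes
#'   `command` and `version` recording the invocation.
#' @export
realign <- function(sequences, aligner = aligner_spec()) {
  stopifnot(inherits(aligner, "aligner_spec"))
  if (is.matrix(sequences))
    sequences <- gsub("-", "", apply(sequences, 1L, paste, collapse = ""),
                      fixed = TRUE)
  if (!length(sequences)) stop("no sequences to align")
  exe <- Sys.which(aligner$command)
  if (!nzchar(exe))
    stop("aligner executable '", aligner$command, "' not found on PATH; ",
         "install it or pass a different aligner_spec()")
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_fasta(sequences, fin)
  status <- suppressWarnings(
    system2(exe, c(aligner$args, shQuote(fin)), stdout = fout, stderr = FALSE))
  if (!identical(status, 0L) || !file.exists(fout) || file.size(fout) == 0)
    stop("aligner '", aligner$command, "' failed (exit status ", status, ")")
  version <- tryCatch(
    paste(suppressWarnings(
      system2(exe, "--version", stdout = TRUE, stderr = TRUE)), collapse = " "),
    error = function(e) NA_character_)
  out <- read_msa(fout)
  attr(out, "command") <- paste(c(exe, aligner$args), collapse = " ")
  attr(out, "version") <- version
  out
}

#' Fit the true-to-realigned statistics correction
#'
#' Fits one least-squares regressor per output component, each taking all
#' 27 true-MSA statistics as inputs. Collinear or constant inputs are
#' handled by the pivoted QR (their coefficients are set to zero), and a
#' constant target degenerates to a constant predictor. When at least 50
#' pairs are available, a deterministic 20% holdout provides per-component
#' R-squared diagnostics before the final refit on all pairs.
#'
#' @param true_stats,realigned_stats Matrices with one row per simulation
#'   and 27 columns (true and post-alignment statistics, row-aligned).
#' @return An object of class `correction_model` with the coefficient
#'   matrix, training size, and diagnostics.
#' @export
fit_correction <- function(true_stats, realigned_stats) {
  true_stats <- as.matrix(true_stats)
  realigned_stats <- as.matrix(realigned_stats)
  stopifnot(nrow(true_stats) == nrow(realigned_stats),
            ncol(true_stats) == N_SUMMARY_STATS,
            ncol(realigned_stats) == N_SUMMARY_STATS)
  n <- nrow(true_stats)
  if (n < 2L) stop("need at least 2 training pairs")
  fit_coef <- function(X, Y) {
    co <- stats::lm.fit(cbind(`(intercept)` = 1, X), Y)$coefficients
    co[is.na(co)] <- 0
    co
  }
  r2 <- rep(NA_real_, N_SUMMARY_STATS)
  if (n >= 50L) {
    hold <- seq_len(n) %% 5L == 0L
    co <- fit_coef(true_stats[!hold, , drop = FALSE],
                   realigned_stats[!hold, , drop = FALSE])
    pred <- cbind(1, true_stats[hold, , drop = FALSE]) %*% co
    obs <- realigned_stats[hold, , drop = FALSE]
    for (j in seq_len(N_SUMMARY_STATS)) {
      ss_tot <- sum((obs[, j] - mean(obs[, j]))^2)
      r2[j] <- if (ss_tot > 0) 1 - sum((obs[, j] - pred[, j])^2) / ss_tot else 1
    }
  }
  coef <- fit_coef(true_stats, realigned_stats)
  colnames(coef) <- summary_stat_names()
  structure(list(coef = coef, training_size = n, holdout_r2 = r2),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("Alignment-bias correction: 27 -> 27 linear map, %d training pairs\n",
              x$training_size))
  if (!all(is.na(x$holdout_r2)))
    cat(sprintf("  holdout R^2: median %.3f (min %.3f)\n",
                stats::median(x$holdout_r2, na.rm = TRUE),
                min(x$holdout_r2, na.rm = TRUE)))
  invisible(x)
}

#' Apply a fitted correction to summary statistics
#'
#' @param model A [fit_correction()] result.
#' @param stats A 27-vector or a matrix with 27 columns.
#' @return Predicted post-alignment statistics with the same shape and
#'   naming; predictions are clipped at 0 (all statistics are nonnegative).
#' @export
apply_correction <- function(model, stats) {
  stopifnot(inherits(model, "correction_model"))
  vec <- is.null(dim(stats))
  X <- if (vec) matrix(stats, nrow = 1L) else as.matrix(stats)
  if (ncol(X) != N_SUMMARY_STATS)
    stop("expected ", N_SUMMARY_STATS, " statistics, got ", ncol(X))
  pred <- pmax(cbind(1, X) %*% model$coef, 0)
  if (vec) stats::setNames(drop(pred), summary_stat_names()) else pred
}

#' Build a correction model for one indel model by simulation
#'
#' Simulates `n_pairs` alignments under prior draws for the given candidate
#' model, realigns each (or applies a synthetic distortion function), and
#' fits the statistics correction on the resulting pairs. With neither an
#' aligner nor a distortion the pairs are (x, x) and the fitted map is the
#' identity, so a disabled correction leaves the pipeline unchanged.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param prior A [prior_config()].
#' @param family,variant Candidate model identity.
#' @param ssa,lsa Root-length prior anchors.
#' @param n_pairs Number of training simulations (paper-scale default 500).
#' @param aligner An [aligner_spec()] or `NULL`.
#' @param distort Optional function mapping a true 27-vector to a distorted
#'   one, used in place of a real aligner (synthetic distortion for
#'   testing).
#' @param alphabet Residue alphabet for [emit_residues()] when realigning.
#' @return A `correction_model`.
#' @export
build_correction <- function(tree, prior, family, variant, ssa, lsa,
                             n_pairs = 500L, aligner = NULL, distort = NULL,
                             alphabet = "protein") {
  stopifnot(n_pairs >= 2L)
  true_m <- matrix(NA_real_, n_pairs, N_SUMMARY_STATS)
  out_m <- matrix(NA_real_, n_pairs, N_SUMMARY_STATS)
  for (i in seq_len(n_pairs)) {
    model <- sample_model(prior, family, variant, ssa, lsa)
    msa <- simulate_msa(tree, model)
    s_true <- compute_summary_statistics(msa)
    s_out <- if (!is.null(aligner)) {
      chars <- emit_residues(msa, alphabet)
      compute_summary_statistics(realign(chars, aligner))
    } else if (!is.null(distort)) {
      distort(s_true)
    } else {
      s_true
    }
    true_m[i, ] <- s_true
    out_m[i, ] <- s_out
  }
  fit_correction(true_m, out_m)
}
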