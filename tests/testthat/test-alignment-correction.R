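# The true-to-realigned statistics correction and the external aligner
# wrapper.

random_stats_matrix <- function(n, seed) {
  set.seed(seed)
  tree <- small_test_tree()
  m <- matrix(NA_real_, n, N_SUMMARY_STATS)
  for (i in seq_len(n)) {
    model <- sample_model(prior_config(), "geometric", "RIM", 60, 90)
    m[i, ] <- compute_summary_statistics(simulate_msa(tree, model))
  }
  m
}

test_that("identity training pairs give an identity correction", {
  X <- random_stats_matrix(80, seed = 61)
  fit <- fit_correction(X, X)
  pred <- apply_correction(fit, X)
  expect_equal(unname(pred), unname(X), tolerance = 1e-8)
  v <- X[3, ]
  expect_equal(unname(apply_correction(fit, v)), unname(v), tolerance = 1e-8)
})

test_that("componentwise affine distortion is recovered exactly", {
  X <- random_stats_matrix(80, seed = 62)
  Y <- 2 * X + 1
  fit <- fit_correction(X, Y)
  expect_equal(unname(apply_correction(fit, X)), unname(Y), tolerance = 1e-6)
  # refit on the same data gives identical coefficients
  expect_identical(fit$coef, fit_correction(X, Y)$coef)
})

test_that("degenerate constant targets become constant predictors", {
  X <- random_stats_matrix(60, seed = 63)
  Y <- X; Y[, 5] <- 7
  fit <- fit_correction(X, Y)
  pred <- apply_correction(fit, X)
  expect_equal(unname(pred[, 5]), rep(7, nrow(X)), tolerance = 1e-8)
  # predictions are clipped at zero
  Yneg <- X - 1e6
  fitn <- fit_correction(X, Yneg)
  expect_true(all(apply_correction(fitn, X) >= 0))
  expect_error(apply_correction(fit, X[, 1:5]), "expected")
})

test_that("correction moves the reference cloud toward the distorted cloud", {
  X <- random_stats_matrix(120, seed = 64)
  set.seed(64)
  Y <- t(apply(X, 1, synthetic_distortion)) +
    matrix(rnorm(length(X), 0, 0.5), nrow(X))
  train <- 1:80; test <- 81:120
  fit <- fit_correction(X[train, ], Y[train, ])
  corrected <- apply_correction(fit, X[test, ])
  active <- which(apply(Y[train, ], 2, var) > 0)
  Cinv <- solve(cov(Y[train, active]) + diag(1e-6, length(active)))
  d_raw <- mean(sapply(test - 80, function(i)
    mahalanobis_distance(X[test[i], active], Y[test[i], active], Cinv)))
  d_cor <- mean(sapply(test - 80, function(i)
    mahalanobis_distance(corrected[i, active], Y[test[i], active], Cinv)))
  expect_lt(d_cor, d_raw)
})

test_that("build_correction without aligner matches an explicit identity distortion", {
  tree <- small_test_tree()
  set.seed(65)
  fit_null <- build_correction(tree, prior_config(), "zipf", "SIM", 60, 90,
                               n_pairs = 40)
  set.seed(65)
  fit_id <- build_correction(tree, prior_config(), "zipf", "SIM", 60, 90,
                             n_pairs = 40, distort = identity)
  expect_identical(fit_null$coef, fit_id$coef)
  # on its own training distribution the fitted map is the identity
  set.seed(65)
  X <- matrix(NA_real_, 20, N_SUMMARY_STATS)
  for (i in 1:20) {
    m <- sample_model(prior_config(), "zipf", "SIM", 60, 90)
    X[i, ] <- compute_summary_statistics(simulate_msa(tree, m))
  }
  expect_equal(unname(apply_correction(fit_null, X)), unname(X),
               tolerance = 1e-6)
})

test_that("external aligner wrapper produces expected alignments", {
  # identical sequences align gaplessly
  seqs <- c(a = "ACGTACGTACGTACGTACGT", b = "ACGTACGTACGTACGTACGT")
  out <- realign(seqs)
  expect_equal(dim(out), c(2L, 20L))
  expect_true(all(out != "-"))
  expect_match(attr(out, "command"), "mafft")

  # one clean deletion of length 3 reappears as one gap block of length 3
  seqs <- c(a = "ACGTACTTGGAACGTACCGGTT", b = "ACGTACTTGCGTACCGGTT")
  out <- realign(seqs)
  blocks <- find_gap_blocks(out)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$length, 3)

  expect_error(realign(seqs, aligner_spec("no-such-aligner-xyz")),
               "not found")
})

test_that("classification with correction beats no correction on distorted data", {
  # empirical statistics distorted by the synthetic aligner stand-in;
  # reference tables either corrected with a matching fit or left raw
  tree <- small_test_tree()
  prior <- prior_config()
  ssa <- 60; lsa <- 90
  set.seed(67)
  distort_noisy <- function(s) synthetic_distortion(s) *
    exp(rnorm(length(s), 0, 0.05))
  corrections <- sapply(model_labels(), function(lab) {
    parts <- strsplit(lab, "-")[[1]]
    build_correction(tree, prior, parts[1], parts[2], ssa, lsa,
                     n_pairs = 60, distort = distort_noisy)
  }, simplify = FALSE)
  tables_raw <- build_reference(tree, prior, ssa, lsa, n_per_model = 400,
                                seed = 671)
  tables_cor <- build_reference(tree, prior, ssa, lsa, n_per_model = 400,
                                correction = corrections, seed = 671)
  set.seed(672)
  corpus <- make_labeled_corpus(tree, prior, 12, ssa, lsa,
                                require_valid = TRUE, min_unique_gaps = 10)
  set.seed(673)
  emp <- t(apply(corpus$stats, 1, distort_noisy))
  acc <- function(tables) {
    prep <- indelfit:::prepare_reference(tables)
    pred <- vapply(seq_len(nrow(emp)), function(i)
      classify(emp[i, ], tables, k = 50, prep = prep)$selected_family,
      character(1))
    mean(pred == corpus$labels$family)
  }
  expect_gte(acc(tables_cor), acc(tables_raw))
})
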