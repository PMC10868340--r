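# Rejection-ABC machinery: distances, nearest-neighbor selection, model
# calls, and posterior summaries.

small_tables <- function(n_per_model = 80, seed = 71, ssa = 60, lsa = 90) {
  tree <- small_test_tree()
  build_reference(tree, prior_config(), ssa, lsa, n_per_model = n_per_model,
                  seed = seed)
}

test_that("mahalanobis_distance agrees with hand computations", {
  x <- c(1, 2, 3); y <- c(0, 0, 0)
  expect_equal(mahalanobis_distance(x, x, diag(3)), 0)
  expect_equal(mahalanobis_distance(x, y, diag(3)), sqrt(sum(x^2)))
  # diag(1,4,9) covariance with difference (1,2,3): sqrt(1 + 1 + 1)
  expect_equal(mahalanobis_distance(x, y, solve(diag(c(1, 4, 9)))), sqrt(3))
})

test_that("nearest-neighbor vote reproduces the worked selection example", {
  counts <- c("zipf-RIM" = 40, "zipf-SIM" = 30, "geometric-RIM" = 20,
              "geometric-SIM" = 8, "poisson-RIM" = 2, "poisson-SIM" = 0)
  call <- classify_counts(counts)
  expect_identical(call$selected_model, "zipf-RIM")
  expect_identical(call$selected_family, "zipf")
  expect_equal(unname(call$family_support["zipf"]), 0.70)
  expect_equal(sum(call$counts), 100)
  expect_equal(sum(call$family_support), 1)
})

test_that("reference tables are reproducible and well-formed", {
  t1 <- small_tables(n_per_model = 10, seed = 72)
  t2 <- small_tables(n_per_model = 10, seed = 72)
  expect_identical(t1, t2)
  expect_length(t1, 6)
  for (tb in t1) {
    expect_equal(nrow(tb$params), 10)
    expect_equal(dim(tb$stats), c(10, 27))
  }
})

test_that("kNN selection matches a brute-force full sort, including ties", {
  tables <- small_tables(n_per_model = 150, seed = 73)
  # duplicate one table's rows to force exact distance ties
  tables[["zipf-SIM"]]$stats[2, ] <- tables[["zipf-SIM"]]$stats[1, ]
  prep <- indelfit:::prepare_reference(tables)
  x <- colMeans(prep$S)
  res <- classify(x, tables, k = 100, prep = prep)
  # selection agrees with a full sort of the distances, ties by row index
  oracle <- order(res$distances, seq_along(res$distances))[1:100]
  expect_identical(res$neighbors$index, oracle)
  expect_equal(res$neighbors$distance, res$distances[oracle])
  expect_true(!is.unsorted(res$neighbors$distance))
  # the distance vector itself matches the scalar definition
  for (i in c(1, 57, 423)) {
    expect_equal(res$distances[i],
                 mahalanobis_distance(prep$S[i, prep$active],
                                      x[prep$active], prep$cov_inverse),
                 tolerance = 1e-6)
  }
  # the two duplicated rows tie exactly and keep index order
  dup <- which(res$neighbors$label == "zipf-SIM" & res$neighbors$model_row %in% 1:2)
  if (length(dup) == 2) expect_lt(res$neighbors$index[dup[1]],
                                  res$neighbors$index[dup[2]])
})

test_that("identity covariance reduces classification to Euclidean kNN", {
  tables <- small_tables(n_per_model = 60, seed = 74)
  prep <- indelfit:::prepare_reference(tables, covariance = "identity")
  x <- prep$S[7, ] * 1.01
  res <- classify(x, tables, k = 20, prep = prep)
  d_euc <- sqrt(colSums((t(prep$S[, prep$active]) - x[prep$active])^2))
  expect_identical(res$neighbors$index, order(d_euc, seq_along(d_euc))[1:20])
})

test_that("an exactly matching simulation is the rank-1 neighbor", {
  tables <- small_tables(n_per_model = 50, seed = 75)
  # pick a gapped simulation so its statistics vector is almost surely
  # unique in the pooled table (gapless rows tie across models)
  row <- which(tables[["poisson-RIM"]]$stats[, "n_unique_gaps"] >= 5)[1]
  x <- tables[["poisson-RIM"]]$stats[row, ]
  res <- classify(x, tables, k = 10)
  expect_equal(res$neighbors$distance[1], 0)
  expect_identical(res$neighbors$label[1], "poisson-RIM")
  expect_identical(res$neighbors$model_row[1], as.integer(row))
})

test_that("supports sum to one and are invariant to table row order", {
  tables <- small_tables(n_per_model = 60, seed = 76)
  x <- colMeans(do.call(rbind, lapply(tables, `[[`, "stats")))
  res <- classify(x, tables, k = 50)
  expect_equal(sum(res$family_support), 1)
  expect_equal(sum(res$counts), 50)
  # permute rows within each table: same supports (distances generic)
  set.seed(761)
  tables_perm <- lapply(tables, function(tb) {
    p <- sample(tb$n)
    tb$params <- tb$params[p, ]; tb$stats <- tb$stats[p, ]; tb
  })
  res2 <- classify(x, tables_perm, k = 50)
  expect_equal(res2$family_support, res$family_support)

  # k = all rows: supports equal each family's share of the table
  res_all <- classify(x, tables, k = 360)
  expect_equal(unname(res_all$family_support), rep(1 / 3, 3))
})

test_that("posterior summaries behave on accepted draws", {
  tables <- small_tables(n_per_model = 60, seed = 77)
  x <- tables[["zipf-SIM"]]$stats[1, ]
  res <- classify(x, tables, k = 30)
  post <- estimate_posteriors(res, tables)
  expect_true(all(c("mean", "q05", "q50", "q95") %in% colnames(post$summary)))
  expect_true(all(post$summary$q05 <= post$summary$q50 + 1e-12))
  expect_true(all(post$summary$q50 <= post$summary$q95 + 1e-12))
  # degenerate: all accepted draws identical -> zero spread
  tb <- tables[[res$selected_model]]
  tb$params[seq_len(nrow(tb$params)), ] <- tb$params[rep(1, nrow(tb$params)), ]
  tables2 <- tables; tables2[[res$selected_model]] <- tb
  post2 <- estimate_posteriors(res, tables2)
  expect_true(all(post2$summary$sd == 0))
  expect_equal(post2$summary$mean, unname(unlist(tb$params[1, ])))
})

test_that("feature ablation reuses the corpus and reports sane deltas", {
  tree <- small_test_tree()
  tables <- small_tables(n_per_model = 250, seed = 78)
  set.seed(781)
  corpus <- make_labeled_corpus(tree, prior_config(), 8, 60, 90,
                                require_valid = TRUE, min_unique_gaps = 10)
  ab <- feature_ablation(tables, corpus, features = c(1, 11, 16), k = 50)
  expect_equal(nrow(ab), 3)
  expect_true(all(ab$accuracy >= 0 & ab$accuracy <= 1))
  expect_equal(ab$delta, ab$accuracy - ab$baseline)
})
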