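# The Gillespie indel simulator and its homology bookkeeping.

zero_rate_model <- function(root_length = 40) {
  d <- length_distribution("geometric", 0.5)
  indel_model("geometric", "SIM", 0, 0, d, d, root_length)
}

sim_model <- function(rate, mean = 4, family = "geometric",
                      root_length = 60) {
  d <- length_distribution(family, parameter_for_mean(family, mean))
  indel_model(family, "SIM", rate / 2, rate / 2, d, d, root_length)
}

test_that("zero-rate model yields a gapless MSA of root length", {
  tree <- small_test_tree()
  msa <- simulate_msa(tree, zero_rate_model(40))
  expect_equal(msa$n_columns, 40)
  expect_true(all(!msa$gap))
  expect_equal(nrow(msa$events), 0)
  expect_true(all(msa$tip_lengths == 40))
})

test_that("no-event branches preserve length; huge deletion rates absorb at 0", {
  m0 <- zero_rate_model()
  br <- simulate_branch(25, 3, m0)
  expect_equal(br$child_length, 25)
  expect_equal(nrow(br$events), 0)

  d <- length_distribution("geometric", 0.2)
  del_only <- indel_model("geometric", "RIM", 0, 50, d, d, 30)
  set.seed(31)
  br <- simulate_branch(30, 10, del_only)
  expect_equal(br$child_length, 0)
})

test_that("insertion-only expected length gain matches first-order theory", {
  # E[gain] ~ r_ins * (L+1) * t * E[len] for small event probability
  r <- 0.002; t_br <- 0.5; L <- 100; mean_len <- 5
  d <- length_distribution("geometric", parameter_for_mean("geometric", mean_len))
  ins_only <- indel_model("geometric", "RIM", r, 0, d, d, L)
  set.seed(32)
  gains <- replicate(10000, simulate_branch(L, t_br, ins_only)$child_length - L)
  expected <- r * (L + 1) * t_br * mean_length(d)
  se <- sd(gains) / sqrt(length(gains))
  expect_lt(abs(mean(gains) - expected), 3 * se + 0.02 * expected)
})

test_that("place_deletion start set and realized spans behave as specified", {
  expect_equal(place_deletion(1, 1), 0)
  set.seed(33)
  starts <- place_deletion(20, 3, n = 1e5)
  expect_true(all(starts >= -2 & starts <= 19))
  # per-site deletion probability is uniform: count how often each of the
  # 20 sites is covered by the realized span
  hits <- vapply(0:19, function(site)
    sum(starts <= site & starts >= site - 2), integer(1))
  expect_gt(suppressWarnings(chisq.test(hits)$p.value), 0.001)
  # realized length never exceeds the drawn length
  expect_true(all(pmin(starts + 3, 20) - pmax(starts, 0) <= 3))
})

test_that("event log replay reproduces every leaf's ungapped length", {
  tree <- small_test_tree()
  set.seed(34)
  for (rep in 1:5) {
    model <- sample_model(prior_config(), "zipf", "RIM", 80, 120)
    msa <- simulate_msa(tree, model)
    ev <- msa$events
    # walk root-to-tip paths, accumulating realized insertions - deletions
    tr <- msa$tree
    parent_of <- integer(max(tr$edge)); parent_of[tr$edge[, 2]] <- tr$edge[, 1]
    edge_of <- integer(max(tr$edge)); edge_of[tr$edge[, 2]] <- seq_len(nrow(tr$edge))
    root <- length(tr$tip.label) + 1L
    for (tip in seq_along(tr$tip.label)) {
      node <- tip; net <- 0L
      while (node != root) {
        e <- edge_of[node]
        rows <- ev$branch == e
        net <- net + sum(ev$realized[rows & ev$kind == "insertion"]) -
          sum(ev$realized[rows & ev$kind == "deletion"])
        node <- parent_of[node]
      }
      expect_identical(unname(msa$tip_lengths[tip]),
                       model$root_length + as.integer(net))
    }
  }
})

test_that("emitted alignments have no all-gap columns and consistent widths", {
  tree <- small_test_tree()
  set.seed(35)
  for (rep in 1:10) {
    model <- sim_model(rate = 0.08, mean = 6, root_length = 50)
    msa <- simulate_msa(tree, model)
    expect_true(all(colSums(!msa$gap) >= 1))
    expect_gte(msa$n_columns, max(msa$tip_lengths))
    expect_equal(ncol(msa$gap), msa$n_columns)
  }
})

test_that("simulation is byte-identical under a fixed seed", {
  tree <- small_test_tree()
  model <- sim_model(rate = 0.05)
  set.seed(36); a <- simulate_msa(tree, model)
  set.seed(36); b <- simulate_msa(tree, model)
  expect_identical(a, b)
})

test_that("pooled event lengths recover the sampling distribution", {
  d <- length_distribution("zipf", parameter_for_mean("zipf", 4))
  model <- indel_model("zipf", "SIM", 0.5, 0.5, d, d, 200)
  set.seed(37)
  lens <- integer(0)
  while (length(lens) < 50000) {
    br <- simulate_branch(200, 1, model)
    lens <- c(lens, br$events$length)
  }
  counts <- tabulate(lens, nbins = 150)
  expect_gt(gof_pvalue(counts, d$pmf), 0.001)
})

test_that("sibling visit order does not change leaf-level distributions", {
  tree <- ape::read.tree(text = "((a:0.4,b:0.4):0.3,(c:0.5,d:0.2):0.3):0;")
  swapped <- ape::read.tree(text = "((d:0.2,c:0.5):0.3,(b:0.4,a:0.4):0.3):0;")
  model <- sim_model(rate = 0.1, mean = 3, root_length = 60)
  n <- 400
  set.seed(38)
  g1 <- replicate(n, sum(simulate_msa(tree, model)$gap))
  g2 <- replicate(n, sum(simulate_msa(swapped, model)$gap))
  expect_gt(suppressWarnings(ks.test(g1, g2)$p.value), 0.001)
})

test_that("emit_residues respects descent, alphabet, and saturation", {
  tree <- small_test_tree()
  model <- zero_rate_model(30)
  zero_tree <- tree; zero_tree$edge.length[] <- 0
  set.seed(39)
  chars <- emit_residues(simulate_msa(zero_tree, model), "protein")
  expect_true(all(apply(chars, 2, function(col) length(unique(col)) == 1)))

  msa <- simulate_msa(tree, sim_model(rate = 0.05, root_length = 50))
  chars <- emit_residues(msa, "dna")
  expect_true(all(chars %in% c("A", "C", "G", "T", "-")))
  expect_identical(dim(chars), dim(msa$gap))
  expect_identical(unname(chars == "-"), unname(msa$gap))

  # long branches saturate to 1/|alphabet| pairwise identity
  sat <- ape::read.tree(text = "(a:40,b:40):0;")
  big <- simulate_msa(sat, zero_rate_model(4000))
  cc <- emit_residues(big, "dna")
  ident <- mean(cc[1, ] == cc[2, ])
  expect_lt(abs(ident - 0.25), 0.03)
})

test_that("newick and FASTA round-trips preserve simulated data", {
  tree <- small_test_tree()
  set.seed(40)
  msa <- simulate_msa(tree, sim_model(rate = 0.08, root_length = 40))
  chars <- emit_residues(msa, "dna")
  fa <- tempfile(fileext = ".fasta")
  write_fasta(chars, fa)
  back <- read_msa(fa)
  expect_identical(back, chars)
  ev <- tempfile(fileext = ".tsv")
  write_event_log(msa, ev)
  tab <- read.delim(ev)
  expect_equal(nrow(tab), nrow(msa$events))
})
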