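# Shared fixtures and independent oracles used across the test files.

# Independent brute-force recount of all 27 statistics by direct character
# scanning, written without reference to the package internals.
naive_summary_stats <- function(chars) {
  stopifnot(is.matrix(chars), is.character(chars))
  nseq <- nrow(chars); ncol_ <- ncol(chars)
  is_gap <- chars == "-"

  # blocks by scanning each row character by character
  blocks <- list()
  for (i in seq_len(nseq)) {
    j <- 1L
    while (j <= ncol_) {
      if (is_gap[i, j]) {
        k <- j
        while (k < ncol_ && is_gap[i, k + 1L]) k <- k + 1L
        blocks[[length(blocks) + 1L]] <- c(i, j, k)
        j <- k + 1L
      } else j <- j + 1L
    }
  }
  b_len <- vapply(blocks, function(b) b[3] - b[2] + 1L, integer(1))
  b_key <- vapply(blocks, function(b) paste(b[2], b[3]), character(1))
  uk <- unique(b_key)
  u_len <- b_len[match(uk, b_key)]
  u_mult <- vapply(uk, function(k) sum(b_key == k), integer(1))

  gap_per_col <- if (ncol_) colSums(is_gap) else integer(0)
  seq_len_ <- rowSums(!is_gap)
  avg0 <- function(v) if (length(v)) mean(v) else 0
  cls <- function(lens) c(sum(lens == 1), sum(lens == 2), sum(lens == 3),
                          sum(lens >= 4))
  c(avg0(b_len), ncol_, max(seq_len_, 0), if (length(seq_len_)) min(seq_len_) else 0,
    avg0(seq_len_), avg0(u_len),
    sum(gap_per_col == 0), sum(gap_per_col == 1),
    sum(gap_per_col == 2 & gap_per_col < nseq),
    sum(gap_per_col > 2 & gap_per_col < nseq),
    length(blocks), length(uk),
    cls(b_len),
    cls(u_len[u_mult == 1]),
    cls(u_len[u_mult == 2]),
    sum(u_mult > 2 & u_len == 1), sum(u_mult > 2 & u_len == 2),
    sum(u_mult > 2 & u_len >= 3))
}

# Small character MSA from a vector of strings.
msa_from_strings <- function(strings, names = NULL) {
  if (is.null(names)) names <- sprintf("s%d", seq_along(strings))
  mat <- do.call(rbind, strsplit(strings, "", fixed = TRUE))
  rownames(mat) <- names
  mat
}

# Tiny fixed tree reused in simulation tests.
small_test_tree <- function(n = 6, total = 1.5, seed = 7) {
  make_tree(n, total, "coalescent", seed = seed)
}

# Chi-square goodness of fit with tail pooling so expected counts >= 5.
gof_pvalue <- function(observed_counts, probs) {
  n <- sum(observed_counts)
  keep <- which(probs * n >= 5)
  if (length(keep) < 2) stop("too few well-populated bins")
  o <- c(observed_counts[keep], n - sum(observed_counts[keep]))
  p <- c(probs[keep], 1 - sum(probs[keep]))
  if (p[length(p)] <= 0) { o <- o[-length(o)]; p <- p[-length(p)] }
  suppressWarnings(stats::chisq.test(o, p = p / sum(p))$p.value)
}

# Synthetic, deterministic "aligner distortion" of a statistics vector:
# a fixed componentwise affine map, standing in for the bias an alignment
# program introduces. Purely synthetic; used to exercise the correction
# machinery without subprocess calls.
synthetic_distortion <- function(stats) {
  slopes <- 1 + 0.1 * sin(seq_len(length(stats)))
  offsets <- 0.5 * cos(seq_len(length(stats)))
  pmax(slopes * stats + offsets, 0)
}
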