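# The 27 gap-pattern summary statistics of an alignment.
#
# A "gap block" is a maximal run of gap characters in one row. A "unique
# gap" is an equivalence class of blocks sharing identical start and end
# columns across rows; its multiplicity is the number of rows carrying
# exactly that block. The statistic set is held in a registry (name ->
# function) so individual definitions can be swapped without touching any
# downstream code; the vector length is asserted everywhere.

#' Number of summary statistics
#' @export
N_SUMMARY_STATS <- 27L

#' Find all gap blocks of an alignment
#'
#' @param x An alignment (`true_msa`, character matrix, or logical gap
#'   mask with TRUE = gap).
#' @return A data frame with one row per block: `seq` (row index), `start`
#'   (first column, 1-based), `end` (one past the last column), `length`.
#' @export
find_gap_blocks <- function(x) {
  mask <- as_gap_mask(x)
  seq_v <- starts <- ends <- lens <- vector("list", nrow(mask))
  for (i in seq_len(nrow(mask))) {
    r <- rle(mask[i, ])
    g <- which(r$values)
    if (!length(g)) next
    e <- cumsum(r$lengths)
    seq_v[[i]] <- rep.int(i, length(g))
    ends[[i]] <- e[g] + 1L
    lens[[i]] <- r$lengths[g]
    starts[[i]] <- e[g] - r$lengths[g] + 1L
  }
  list2DF(list(seq = as.integer(unlist(seq_v)),
               start = as.integer(unlist(starts)),
               end = as.integer(unlist(ends)),
               length = as.integer(unlist(lens))))
}

# Unique gaps: one row per (start, end) class, with its length and
# multiplicity (number of rows carrying the identical block).
unique_gaps <- function(blocks) {
  if (!nrow(blocks))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), multiplicity = integer(0)))
  key <- as.numeric(blocks$start) * (max(blocks$end) + 1) + blocks$end
  first <- which(!duplicated(key))
  mult <- tabulate(match(key, key[first]), nbins = length(first))
  list2DF(list(start = blocks$start[first], end = blocks$end[first],
               length = blocks$length[first],
               multiplicity = as.integer(mult)))
}

# Count blocks per length class 1 / 2 / 3 / >= 4.
len_class4 <- function(lengths) {
  c(sum(lengths == 1L), sum(lengths == 2L),
    sum(lengths == 3L), sum(lengths >= 4L))
}

#' Names of the 27 summary statistics, in vector order
#' @export
summary_stat_names <- function() names(summary_stat_registry())

# Registry mapping statistic name -> function of the precomputed context.
# The context holds the gap mask, the block list, the unique-gap table,
# per-column gap counts and per-row ungapped lengths.
summary_stat_registry <- function() {
  avg0 <- function(v) if (length(v)) mean(v) else 0
  list(
    avg_block_length     = function(ctx) avg0(ctx$blocks$length),
    msa_columns          = function(ctx) ncol(ctx$mask),
    longest_seq_length   = function(ctx) max(ctx$seq_lengths, 0L),
    shortest_seq_length  = function(ctx) if (length(ctx$seq_lengths)) min(ctx$seq_lengths) else 0L,
    avg_seq_length       = function(ctx) avg0(ctx$seq_lengths),
    avg_unique_gap_length = function(ctx) avg0(ctx$uniq$length),
    cols_no_gap          = function(ctx) sum(ctx$gap_counts == 0L),
    cols_one_gap         = function(ctx) sum(ctx$gap_counts == 1L),
    cols_two_gaps        = function(ctx) sum(ctx$gap_counts == 2L & ctx$gap_counts < ctx$nseq),
    cols_multi_gaps      = function(ctx) sum(ctx$gap_counts > 2L & ctx$gap_counts < ctx$nseq),
    n_gap_blocks         = function(ctx) nrow(ctx$blocks),
    n_unique_gaps        = function(ctx) nrow(ctx$uniq),
    blocks_len1          = function(ctx) ctx$block_classes[1L],
    blocks_len2          = function(ctx) ctx$block_classes[2L],
    blocks_len3          = function(ctx) ctx$block_classes[3L],
    blocks_len4plus      = function(ctx) ctx$block_classes[4L],
    gaps_mult1_len1      = function(ctx) ctx$m1_classes[1L],
    gaps_mult1_len2      = function(ctx) ctx$m1_classes[2L],
    gaps_mult1_len3      = function(ctx) ctx$m1_classes[3L],
    gaps_mult1_len4plus  = function(ctx) ctx$m1_classes[4L],
    gaps_mult2_len1      = function(ctx) ctx$m2_classes[1L],
    gaps_mult2_len2      = function(ctx) ctx$m2_classes[2L],
    gaps_mult2_len3      = function(ctx) ctx$m2_classes[3L],
    gaps_mult2_len4plus  = function(ctx) ctx$m2_classes[4L],
    gaps_multi_len1      = function(ctx) sum(ctx$uniq$multiplicity > 2L & ctx$uniq$length == 1L),
    gaps_multi_len2      = function(ctx) sum(ctx$uniq$multiplicity > 2L & ctx$uniq$length == 2L),
    gaps_multi_len3plus  = function(ctx) sum(ctx$uniq$multiplicity > 2L & ctx$uniq$length >= 3L)
  )
}

#' Compute the 27-component summary-statistic vector of an alignment
#'
#' Components, in order: (1) average gap-block length; (2) number of MSA
#' columns; (3) longest and (4) shortest ungapped sequence length (LSA,
#' SSA); (5) average ungapped sequence length; (6) average unique-gap
#' length; (7-10) numbers of columns in which zero, one, two, or more than
#' two (but not all) sequences are gapped; (11) total gap blocks; (12)
#' unique gaps; (13-16) gap blocks of length 1 / 2 / 3 / >= 4 over all
#' sequences; (17-20) unique gaps carried by exactly one sequence, same
#' four length classes; (21-24) carried by exactly two sequences; (25-27)
#' carried by more than two sequences, lengths 1 / 2 / >= 3. Averages over
#' empty sets are 0, so gapless alignments give finite vectors.
#'
#' @param x An alignment (`true_msa`, character matrix, or logical gap
#'   mask) with at least 2 rows.
#' @return Named numeric vector of length 27.
#' @export
compute_summary_statistics <- function(x) {
  mask <- as_gap_mask(x)
  if (nrow(mask) < 2L) stop("need at least 2 sequences")
  blocks <- find_gap_blocks(mask)
  uniq <- unique_gaps(blocks)
  ctx <- list(
    mask = mask,
    nseq = nrow(mask),
    blocks = blocks,
    uniq = uniq,
    gap_counts = if (ncol(mask)) colSums(mask) else integer(0),
    seq_lengths = rowSums(!mask),
    block_classes = len_class4(blocks$length),
    m1_classes = len_class4(uniq$length[uniq$multiplicity == 1L]),
    m2_classes = len_class4(uniq$length[uniq$multiplicity == 2L]))
  stats <- vapply(summary_stat_registry(), function(f) as.numeric(f(ctx)),
                  numeric(1))
  stopifnot(length(stats) == N_SUMMARY_STATS, all(is.finite(stats)))
  stats
}

#' Write a summary-statistic vector as a one-row named TSV
#'
#' @param stats Named numeric vector from [compute_summary_statistics()].
#' @param path Output path.
#' @export
write_summary_statistics <- function(stats, path) {
  stopifnot(length(stats) == N_SUMMARY_STATS)
  df <- as.data.frame(as.list(stats))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
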