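# FASTA input/output and gap-mask coercion. The gap character is "-";
# residue case is ignored everywhere because all statistics are functions
# of the gap pattern only.

#' Read a multiple sequence alignment from FASTA
#'
#' @param path Path to a FASTA file with aligned, equal-length sequences
#'   (gap character `"-"`).
#' @return A character matrix, one row per sequence, rows named by record.
#' @export
read_msa <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 1L) stop("no sequences in ", path)
  seqs <- toupper(as.character(set))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("sequences have unequal lengths: not an alignment")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(set)
  mat
}

#' Write sequences or an alignment to FASTA
#'
#' @param x A character matrix (alignment rows) or a named character vector
#'   of sequences.
#' @param path Output path.
#' @param degap Drop `"-"` characters before writing (for realignment
#'   input).
#' @export
write_fasta <- function(x, path, degap = FALSE) {
  if (is.matrix(x)) x <- apply(x, 1L, paste, collapse = "")
  stopifnot(is.character(x), !is.null(names(x)))
  if (degap) x <- gsub("-", "", x, fixed = TRUE)
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Coerce the accepted MSA representations to a logical gap mask
# (TRUE = gap). Accepts a true_msa, a character matrix, or a logical matrix.
as_gap_mask <- function(x) {
  if (inherits(x, "true_msa")) return(x$gap)
  if (is.matrix(x) && is.character(x)) return(x == "-")
  if (is.matrix(x) && is.logical(x)) return(x)
  stop("cannot interpret input as an alignment gap mask")
}

#' Ungapped sequence lengths of an alignment
#'
#' @param x An alignment (`true_msa`, character matrix, or logical gap
#'   mask).
#' @return Integer vector of per-sequence lengths excluding gaps.
#' @export
ungapped_lengths <- function(x) {
  mask <- as_gap_mask(x)
  rowSums(!mask)
}
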