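# Gillespie simulation of indel histories along a rooted phylogeny.
#
# Site homology is tracked with integer site identifiers: every site ever
# created (root sites and insertions) gets a unique id, and a global ordered
# column list records where each id sits in the implied alignment. Each node
# carries the ordered subset of ids present in its sequence; emitting the
# leaves against the global column list yields the true MSA directly, with
# no aligner involved.

#' Read a rooted phylogeny with branch lengths
#'
#' Thin wrapper over [ape::read.tree()] that enforces the requirements of
#' the simulator: a rooted topology and nonnegative branch lengths in
#' expected substitutions per site.
#'
#' @param path Path to a newick file.
#' @return An `ape` `phylo` object.
#' @export
read_phylogeny <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick tree from ", path)
  check_phylogeny(tree)
  tree
}

check_phylogeny <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  invisible(tree)
}

#' Simulate indel events along one branch
#'
#' Runs the Gillespie process on a single branch. With current sequence
#' length L the insertion hazard is `insertion_rate * (L + 1)` (a slot
#' before every site plus one after the last) and the deletion hazard is
#' `deletion_rate * (L + E[deletion length] - 1)`, matching the enlarged
#' uniform start set of [place_deletion()] so that the per-site deletion
#' rate is the same for terminal and internal sites. Waiting times are
#' exponential in the summed hazard; the process stops when the cumulative
#' time exceeds the branch length. The sequence may reach length zero, after
#' which only insertions can occur.
#'
#' @param parent_length Ungapped sequence length entering the branch.
#' @param branch_length Branch length in expected substitutions per site.
#' @param model An [indel_model()].
#' @return A list with `events` (data frame: kind, time, start, length,
#'   realized) and `child_length`. Insertion starts are slots `0..L`;
#'   deletion starts are 0-based and may be negative (left overhang), with
#'   `realized` the number of sites actually removed.
#' @export
simulate_branch <- function(parent_length, branch_length, model) {
  br <- simulate_branch_core(parent_length, branch_length, model)
  list(events = data.frame(kind = c("insertion", "deletion")[br$kind],
                           time = br$time, start = br$start,
                           length = br$length, realized = br$realized),
       child_length = br$child_length)
}

# Hot path shared by simulate_branch and simulate_msa: plain preallocated
# vectors, kind coded as 1 = insertion, 2 = deletion.
simulate_branch_core <- function(parent_length, branch_length, model) {
  stopifnot(parent_length >= 0, branch_length >= 0,
            inherits(model, "indel_model"))
  L <- as.integer(parent_length)
  ins_rate <- model$insertion_rate
  del_rate <- model$deletion_rate
  del_mean <- model$deletion_length$mean
  ins_pmf <- model$insertion_length$pmf
  del_pmf <- model$deletion_length$pmf
  trunc_ins <- model$insertion_length$truncation
  trunc_del <- model$deletion_length$truncation
  cap <- 16L
  kind <- integer(cap); time <- numeric(cap)
  start <- integer(cap); len <- integer(cap); realized <- integer(cap)
  n <- 0L
  t <- 0
  repeat {
    h_ins <- ins_rate * (L + 1)
    h_del <- if (L > 0L) del_rate * (L + del_mean - 1) else 0
    h <- h_ins + h_del
    if (h <= 0) break
    t <- t + stats::rexp(1L, rate = h)
    if (t > branch_length) break
    n <- n + 1L
    if (n > cap) {
      cap <- cap * 2L
      length(kind) <- cap; length(time) <- cap
      length(start) <- cap; length(len) <- cap; length(realized) <- cap
    }
    time[n] <- t
    if (stats::runif(1L) < h_ins / h) {
      d <- sample.int(trunc_ins, 1L, prob = ins_pmf)
      kind[n] <- 1L
      start[n] <- sample.int(L + 1L, 1L) - 1L
      len[n] <- d; realized[n] <- d
      L <- L + d
    } else {
      d <- sample.int(trunc_del, 1L, prob = del_pmf)
      s <- sample.int(L + d - 1L, 1L) - d
      r <- min(s + d, L) - max(s, 0L)
      kind[n] <- 2L
      start[n] <- s; len[n] <- d; realized[n] <- r
      L <- L - r
    }
  }
  idx <- seq_len(n)
  list(kind = kind[idx], time = time[idx], start = start[idx],
       length = len[idx], realized = realized[idx], child_length = L)
}

#' Draw the start of a deletion, corrected for edge effects
#'
#' The start is uniform over `{-(del_length - 1), ..., current_length - 1}`
#' (0-based), so a deletion of length d may overhang the left edge of the
#' sequence. The realized deletion is the intersection with the sequence.
#' This enlargement gives every site, terminal or internal, the same
#' probability of being covered by a deletion of a given length, which is
#' the purpose of the edge correction.
#'
#' @param current_length Current ungapped sequence length (>= 1).
#' @param del_length Sampled deletion length (>= 1).
#' @param n Number of independent draws.
#' @return Integer vector of 0-based start positions.
#' @export
place_deletion <- function(current_length, del_length, n = 1L) {
  stopifnot(current_length >= 1, del_length >= 1)
  sample.int(current_length + del_length - 1L, size = n, replace = TRUE) -
    as.integer(del_length)
}

#' Simulate a true MSA along a phylogeny
#'
#' Applies [simulate_branch()] down the tree in preorder while maintaining
#' global site homology, so the leaf sequences come out already aligned
#' (the "true" MSA). Every event is recorded in an event log. Columns in
#' which no leaf carries a site (e.g. an insertion later deleted in its
#' whole subtree) are unobservable and are dropped from the emitted
#' alignment; the event log retains the events.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param model An [indel_model()] with `root_length >= 1`.
#' @return An object of class `true_msa`: a logical gap mask (rows = leaves,
#'   TRUE = gap), the event log, per-node site-id vectors, the tree, and
#'   bookkeeping needed by [emit_residues()].
#' @export
simulate_msa <- function(tree, model) {
  check_phylogeny(tree)
  stopifnot(inherits(model, "indel_model"), model$root_length >= 1L)
  tr <- stats::reorder(tree, "cladewise")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  root <- ntip + 1L

  L0 <- model$root_length
  seqs <- vector("list", nnode)
  anchors <- integer(nnode)      # column id to insert after when sequence empty
  seqs[[root]] <- seq_len(L0)
  columns <- seq_len(L0)
  next_id <- L0 + 1L
  logs <- vector("list", nrow(tr$edge))

  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    s <- seqs[[parent]]
    anchor <- anchors[parent]
    br <- simulate_branch_core(length(s), tr$edge.length[e], model)
    nev <- length(br$kind)
    if (nev) {
      for (i in seq_len(nev)) {
        L <- length(s)
        if (br$kind[i] == 1L) {
          d <- br$length[i]; slot <- br$start[i]
          new_ids <- seq.int(next_id, length.out = d)
          next_id <- next_id + d
          gpos <- if (L == 0L) {
            if (anchor == 0L) 0L else match(anchor, columns)
          } else if (slot == 0L) {
            match(s[1L], columns) - 1L
          } else {
            match(s[slot], columns)
          }
          columns <- append(columns, new_ids, after = gpos)
          s <- append(s, new_ids, after = slot)
        } else {
          a <- br$start[i]; d <- br$length[i]
          from <- max(a, 0L) + 1L
          to <- min(a + d, L)
          if (to >= from) {
            if (to - from + 1L == L) anchor <- s[L]  # sequence wiped out
            s <- s[-(from:to)]
          }
        }
      }
      logs[[e]] <- list(kind = br$kind, time = br$time, start = br$start,
                        length = br$length, realized = br$realized,
                        branch = rep.int(e, nev), node = rep.int(child, nev))
    }
    seqs[[child]] <- s
    anchors[child] <- anchor
  }

  events <- if (length(lg <- Filter(Negate(is.null), logs))) {
    parts <- lapply(c("kind", "time", "start", "length", "realized",
                      "branch", "node"),
                    function(f) unlist(lapply(lg, `[[`, f), use.names = FALSE))
    names(parts) <- c("kind", "time", "start", "length", "realized",
                      "branch", "node")
    parts$kind <- c("insertion", "deletion")[parts$kind]
    list2DF(parts)
  } else {
    data.frame(kind = character(0), time = numeric(0), start = integer(0),
               length = integer(0), realized = integer(0),
               branch = integer(0), node = integer(0))
  }

  gap <- matrix(TRUE, nrow = ntip, ncol = length(columns),
                dimnames = list(tr$tip.label, NULL))
  for (i in seq_len(ntip))
    if (length(seqs[[i]])) gap[i, match(seqs[[i]], columns)] <- FALSE
  keep <- colSums(!gap) > 0L
  structure(
    list(gap = gap[, keep, drop = FALSE],
         n_columns = sum(keep),
         events = events,
         tree = tr,
         node_sites = seqs,
         column_ids = columns[keep],
         root_length = L0,
         tip_lengths = stats::setNames(
           vapply(seqs[seq_len(ntip)], length, integer(1)), tr$tip.label)),
    class = "true_msa")
}

#' @export
print.true_msa <- function(x, ...) {
  cat(sprintf("True MSA: %d sequences x %d columns, %d indel events\n",
              nrow(x$gap), x$n_columns, nrow(x$events)))
  invisible(x)
}

#' Fill a true MSA with residues
#'
#' Assigns characters to the non-gap cells of a simulated alignment so the
#' ungapped sequences can be fed to an external aligner. Root sites are
#' drawn from uniform base/residue frequencies and evolve along branches
#' under a one-parameter Jukes-Cantor-style process with substitution rate
#' 1 per site per unit branch length; sites created by an insertion are
#' drawn fresh on the branch where they arise. Homologous sites share
#' descent. Summary statistics never depend on this residue content.
#'
#' @param msa A `true_msa` from [simulate_msa()].
#' @param alphabet `"dna"` (4 states) or `"protein"` (20 states).
#' @return A character matrix with `"-"` in gap cells; rows named by leaf.
#' @export
emit_residues <- function(msa, alphabet = c("dna", "protein")) {
  stopifnot(inherits(msa, "true_msa"))
  alphabet <- match.arg(alphabet)
  chars <- if (alphabet == "dna") c("A", "C", "G", "T") else
    c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  A <- length(chars)
  tr <- msa$tree
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  states <- vector("list", ntip + tr$Nnode)
  rs <- msa$node_sites[[root]]
  states[[root]] <- stats::setNames(sample.int(A, length(rs), replace = TRUE),
                                    rs)
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    bl <- tr$edge.length[e]
    cs <- msa$node_sites[[child]]
    st <- integer(length(cs)); names(st) <- cs
    ps <- states[[parent]]
    hit <- match(names(st), names(ps))
    inh <- !is.na(hit)
    v <- unname(ps[hit[inh]])
    if (length(v)) {
      p_change <- (A - 1) / A * (1 - exp(-bl * A / (A - 1)))
      ch <- stats::runif(length(v)) < p_change
      if (any(ch))  # jump uniformly to one of the A-1 other states
        v[ch] <- ((v[ch] - 1L + sample.int(A - 1L, sum(ch), replace = TRUE)) %% A) + 1L
    }
    st[inh] <- v
    if (any(!inh)) st[!inh] <- sample.int(A, sum(!inh), replace = TRUE)
    states[[child]] <- st
  }
  out <- matrix("-", nrow = nrow(msa$gap), ncol = msa$n_columns,
                dimnames = dimnames(msa$gap))
  for (i in seq_len(ntip)) {
    ids <- msa$node_sites[[i]]
    if (length(ids))
      out[i, match(ids, msa$column_ids)] <- chars[unname(states[[i]][as.character(ids)])]
  }
  out
}

#' Write an event log as a tab-separated table
#'
#' @param msa A `true_msa`.
#' @param path Output path.
#' @export
write_event_log <- function(msa, path) {
  stopifnot(inherits(msa, "true_msa"))
  utils::write.table(
    msa$events[, c("branch", "node", "time", "kind", "start", "length", "realized")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
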