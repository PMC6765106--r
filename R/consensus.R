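#' Configuration for cluster consensus calling
#'
#' @param seed_k Anchor kmer length for seeded pairwise alignment
#'   (default 30; anchors must be unique within both sequences, which at
#'   this length essentially rules out spurious repeats).
#' @param window Polishing block width in draft coordinates (default 15).
#'   Blocks are consecutive and non-overlapping, which keeps the modal
#'   vote deterministic.
#' @param max_rounds Maximum polish sweeps; reads are re-aligned to the
#'   updated draft between sweeps so indel corrections can propagate
#'   (default 3).
#' @return A list of class `consensus_config`.
#' @export
consensus_config <- function(seed_k = 30L, window = 15L, max_rounds = 3L) {
  stopifnot(seed_k >= 8, window >= 1, max_rounds >= 1)
  structure(list(seed_k = as.integer(seed_k), window = as.integer(window),
                 max_rounds = as.integer(max_rounds)),
            class = "consensus_config")
}

#' Pick a draft consensus from a cluster of reads
#'
#' The draft is the member read whose kmer vector is nearest (Euclidean)
#' to the coordinate-wise mean of the members' kmer vectors -- the most
#' central actual read, which polishing then corrects block by block.
#' Ties go to the lowest read index.
#'
#' @param sequences Character vector of cluster member sequences.
#' @param k Kmer length for the centrality computation (default 6).
#' @param kmat Optional precomputed kmer count matrix for `sequences`.
#' @return The draft sequence (one element of `sequences`).
#' @export
draft_consensus <- function(sequences, k = 6L, kmat = NULL) {
  if (length(sequences) == 0L) stop("cluster is empty")
  if (length(sequences) == 1L) return(sequences[[1L]])
  if (is.null(kmat)) kmat <- kmer_matrix(sequences, k)
  mu <- colMeans(kmat)
  d2 <- rowSums((kmat - matrix(mu, nrow = nrow(kmat), ncol = ncol(kmat),
                               byrow = TRUE))^2)
  sequences[[which.min(d2)]]
}

# All positions' kmers of a sequence plus a mask of those unique within it.
seed_kmers <- function(sequence, seed_k) {
  L <- nchar(sequence)
  if (L < seed_k) return(list(kmers = character(0), unique = logical(0)))
  km <- substring(sequence, 1:(L - seed_k + 1L), seed_k:L)
  list(kmers = km, unique = !(duplicated(km) | duplicated(km, fromLast = TRUE)))
}

# Longest increasing subsequence (strict) over values; returns indices.
lis_indices <- function(values) {
  .cpp_lis_indices(as.numeric(values))
}

#' Kmer-seeded approximate pairwise alignment
#'
#' Aligns a read against a draft reference by anchoring on `seed_k`-mers
#' that occur exactly once in both sequences, chaining the anchors with a
#' longest-increasing-subsequence pass over their coordinates, and closing
#' the gaps between consecutive anchors with exact unit-cost
#' (match 0, mismatch 1, indel 1) dynamic programming. Unanchored
#' prefixes and suffixes are aligned the same way. Because the quadratic
#' alignment only ever runs on the short inter-anchor gaps, the whole
#' procedure scales linearly with sequence length. When no anchors are
#' shared the full exact alignment is used instead (a message is logged).
#'
#' @param read,draft DNA strings, both at least `seed_k` long.
#' @param config A [consensus_config()].
#' @param draft_index Optional precomputed [seed_kmers()] index of the
#'   draft (used by [polish()] to index the draft once per sweep).
#' @return An object of class `pairwise_alignment`: list with `cuts`
#'   (integer vector of length `nchar(draft) + 1`; `cuts[i + 1]` is the
#'   number of read characters consumed after the first `i` draft
#'   characters -- a monotone draft-to-read boundary map), `score` (total
#'   edit cost along the chained alignment, never below the true edit
#'   distance), and the `read` itself.
#' @export
seeded_align <- function(read, draft, config = consensus_config(),
                         draft_index = NULL) {
  sk <- config$seed_k
  if (nchar(read) < sk || nchar(draft) < sk) {
    stop("both sequences must be at least seed_k (", sk, ") long")
  }
  if (is.null(draft_index)) draft_index <- seed_kmers(draft, sk)
  ridx <- seed_kmers(read, sk)
  dpos_of <- match(ridx$kmers, draft_index$kmers)
  ok <- which(ridx$unique & !is.na(dpos_of) & draft_index$unique[dpos_of])
  anchors_r <- ok
  anchors_d <- dpos_of[ok]
  if (length(ok) > 0L) {
    o <- order(anchors_d)
    anchors_d <- anchors_d[o]; anchors_r <- anchors_r[o]
    keep <- lis_indices(anchors_r)
    anchors_d <- anchors_d[keep]; anchors_r <- anchors_r[keep]
    blocks <- merge_anchor_blocks(anchors_d, anchors_r, sk)
  } else {
    blocks <- NULL
  }
  Ld <- nchar(draft); Lr <- nchar(read)
  cuts <- integer(Ld + 1L)
  score <- 0L
  if (is.null(blocks) || nrow(blocks) == 0L) {
    message("seeded_align: no unique shared anchors; full alignment fallback")
    nw <- .cpp_nw_cuts(draft, read)
    cuts <- nw$cuts
    score <- nw$score
  } else {
    # prefix
    p <- splice_segment(draft, read, 0L, 0L, blocks[1L, "ds"] - 1L,
                        blocks[1L, "rs"] - 1L)
    cuts[seq_len(blocks[1L, "ds"])] <- p$cuts
    score <- score + p$score
    for (b in seq_len(nrow(blocks))) {
      ds <- blocks[b, "ds"]; de <- blocks[b, "de"]
      rs <- blocks[b, "rs"]
      cuts[(ds + 1L):(de + 1L)] <- rs:(rs + (de - ds))
      if (b < nrow(blocks)) {
        g <- splice_segment(draft, read, de, blocks[b, "re"],
                            blocks[b + 1L, "ds"] - 1L,
                            blocks[b + 1L, "rs"] - 1L)
        if (length(g$cuts) > 1L) {
          cuts[(de + 2L):(blocks[b + 1L, "ds"])] <-
            blocks[b, "re"] + g$cuts[-1L]
        }
        score <- score + g$score
      }
    }
    last <- nrow(blocks)
    s <- splice_segment(draft, read, blocks[last, "de"], blocks[last, "re"],
                        Ld, Lr)
    if (length(s$cuts) > 1L) {
      cuts[(blocks[last, "de"] + 2L):(Ld + 1L)] <-
        blocks[last, "re"] + s$cuts[-1L]
    }
    score <- score + s$score
  }
  structure(list(cuts = cuts, score = score, read = read, draft_length = Ld),
            class = "pairwise_alignment")
}

# Merge chained anchors into maximal exact-match blocks; anchors that
# overlap a previous block on a different diagonal are dropped.
merge_anchor_blocks <- function(anchors_d, anchors_r, sk) {
  .cpp_merge_anchor_blocks(as.integer(anchors_d), as.integer(anchors_r),
                           as.integer(sk))
}

# Exact unit-cost alignment of draft[d0+1..d1] against read[r0+1..r1];
# returns local cuts (length d1-d0+1, starting at 0) and cost.
splice_segment <- function(draft, read, d0, r0, d1, r1) {
  la <- unname(d1 - d0); lb <- unname(r1 - r0)
  if (la < 0L || lb < 0L) return(list(cuts = integer(0), score = 0L))
  if (la == 0L) return(list(cuts = 0L, score = lb))
  a <- substr(draft, d0 + 1L, d1)
  b <- if (lb > 0L) substr(read, r0 + 1L, r1) else ""
  nw <- .cpp_nw_cuts(a, b)
  list(cuts = nw$cuts, score = nw$score)
}

# Align every read of a cluster to the draft, indexing the draft once.
align_all <- function(reads, draft, config) {
  didx <- seed_kmers(draft, config$seed_k)
  lapply(reads, seeded_align, draft = draft, config = config,
         draft_index = didx)
}

#' Polish a draft consensus by modal block replacement
#'
#' Partitions the draft into consecutive blocks of `window` characters and
#' replaces any block where the most common aligned read subsequence (a
#' strict plurality; ties keep the draft) differs from the draft. The
#' sweep repeats up to `max_rounds` times, re-aligning all reads to the
#' updated draft between sweeps, and stops early at a fixed point -- so
#' the result is idempotent under further polishing.
#'
#' @param draft The draft sequence.
#' @param alignments A list of [seeded_align()] results for the cluster
#'   members against `draft` (each carries its read).
#' @param config A [consensus_config()].
#' @return The polished sequence.
#' @export
polish <- function(draft, alignments, config = consensus_config()) {
  if (length(alignments) == 0L) stop("need at least one alignment")
  reads <- vapply(alignments, function(a) a$read, character(1))
  for (round in seq_len(config$max_rounds)) {
    new_draft <- polish_sweep(draft, alignments, config$window)
    if (new_draft == draft) break
    draft <- new_draft
    if (round < config$max_rounds) {
      alignments <- align_all(reads, draft, config)
    }
  }
  draft
}

polish_sweep <- function(draft, alignments, window) {
  Ld <- nchar(draft)
  starts <- seq.int(1L, Ld, by = window)
  ends <- pmin(starts + window - 1L, Ld)
  pieces <- character(length(starts))
  for (b in seq_along(starts)) {
    s <- starts[b]; e <- ends[b]
    votes <- vapply(alignments, function(al) {
      substr(al$read, al$cuts[s] + 1L, al$cuts[e + 1L])
    }, character(1))
    tab <- table(votes)
    mx <- max(tab)
    winners <- names(tab)[tab == mx]
    draft_block <- substr(draft, s, e)
    pieces[b] <- if (length(winners) == 1L) winners else draft_block
  }
  paste0(pieces, collapse = "")
}

#' Consensus sequence of a read cluster
#'
#' Full consensus procedure for one cluster: pick the most central member
#' as a draft ([draft_consensus()]), align every member to it
#' ([seeded_align()]), and correct the draft block-by-block with modal
#' polishing ([polish()]). With independent errors, moderate coverage and
#' error rates of a few percent, the modal vote recovers the true template
#' in essentially every block.
#'
#' @param sequences Character vector of cluster member sequences.
#' @param config A [consensus_config()].
#' @param k Kmer length for draft selection.
#' @param kmat Optional precomputed kmer matrix of the members.
#' @return The consensus DNA string.
#' @export
cluster_consensus <- function(sequences, config = consensus_config(),
                              k = 6L, kmat = NULL) {
  if (length(sequences) == 0L) stop("cluster is empty")
  if (length(sequences) == 1L) return(sequences[[1L]])
  draft <- draft_consensus(sequences, k = k, kmat = kmat)
  alignments <- align_all(sequences, draft, config)
  polish(draft, alignments, config)
}
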