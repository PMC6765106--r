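#' Kmer count vector of a DNA sequence
#'
#' Converts a DNA sequence into its vector of kmer counts over the 4^k
#' possible kmers, in lexicographic order (A < C < G < T, equivalently a
#' 2-bit big-endian encoding with A=0, C=1, G=2, T=3). Windows containing
#' any character other than A/C/G/T (for example `N`) match no kmer and are
#' simply not counted, so ambiguity codes never inflate distances.
#'
#' @param sequence A single DNA string over `{A,C,G,T,N}`.
#' @param k Kmer length (default 6, the length used throughout the
#'   denoising pipeline).
#' @return An object of class `kmer_vector`: a list with integer `counts`
#'   (length `4^k`), `k`, and `seq_length` (the length of the originating
#'   sequence, used by [scaled_distance()]).
#' @examples
#' kv <- kmer_vector("ACGTACGT", k = 2)
#' sum(kv$counts) # 7 windows
#' @export
kmer_vector <- function(sequence, k = 6L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (nchar(sequence) < k) {
    stop("sequence shorter than k (", nchar(sequence), " < ", k, ")")
  }
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(sequence), width = k
  )
  structure(
    list(counts = as.integer(counts), k = k, seq_length = nchar(sequence)),
    class = "kmer_vector"
  )
}

#' Kmer count matrix for a set of sequences
#'
#' Counts kmers for many sequences at once. Rows are sequences, columns
#' are the `4^k` kmers in lexicographic order (same indexing as
#' [kmer_vector()]). Attributes `k` and `seq_lengths` are attached so the
#' clustering engines can work on plain numeric matrices.
#'
#' @param sequences Character vector of DNA strings, each at least `k`
#'   long.
#' @inheritParams kmer_vector
#' @return A numeric matrix of kmer counts with attributes `k` and
#'   `seq_lengths`.
#' @export
kmer_matrix <- function(sequences, k = 6L) {
  k <- as.integer(k)
  if (any(nchar(sequences) < k)) stop("all sequences must be at least k long")
  m <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(sequences), width = k
  )
  m <- matrix(as.numeric(m), nrow = length(sequences), ncol = 4L^k)
  attr(m, "k") <- k
  attr(m, "seq_lengths") <- nchar(sequences)
  m
}

check_same_k <- function(u, v) {
  if (!inherits(u, "kmer_vector") || !inherits(v, "kmer_vector")) {
    stop("both arguments must be kmer_vector objects")
  }
  if (u$k != v$k) stop("kmer vectors have different k (", u$k, " vs ", v$k, ")")
}

#' Corrected kmer approximation of edit distance
#'
#' A single substitution in a sequence whose affected kmers are otherwise
#' unique changes 2k entries of the kmer count vector by one each, so the
#' sum of squared count differences divided by 2k scales approximately
#' one-to-one with the number of substitutions separating two sequences.
#' Indel differences change fewer entries and are therefore down-weighted,
#' which is the desired behaviour when the error process is indel-dominated.
#'
#' @param u,v `kmer_vector` objects with equal `k`.
#' @return Non-negative numeric; 0 exactly when the count vectors are equal.
#' @seealso [scaled_distance()] for the per-base form,
#'   [euclidean_kmer_distance()] for the true-metric form.
#' @export
corrected_distance <- function(u, v) {
  check_same_k(u, v)
  sum((u$counts - v$counts)^2) / (2 * u$k)
}

#' Length-scaled kmer distance
#'
#' [corrected_distance()] divided by the mean of the two sequence lengths,
#' yielding a per-base divergence (0.01 is roughly 1% divergence). The mean
#' length keeps the distance symmetric for sequences of unequal length.
#'
#' @inheritParams corrected_distance
#' @export
scaled_distance <- function(u, v) {
  corrected_distance(u, v) / mean(c(u$seq_length, v$seq_length))
}

#' Euclidean distance between kmer count vectors
#'
#' Plain Euclidean distance in kmer count space. Unlike
#' [corrected_distance()] (a squared distance) this satisfies the triangle
#' inequality, which is what makes the pruned DP-means clustering exact:
#' `corrected_distance == euclidean_kmer_distance^2 / (2k)`.
#'
#' @inheritParams corrected_distance
#' @export
euclidean_kmer_distance <- function(u, v) {
  check_same_k(u, v)
  sqrt(sum((u$counts - v$counts)^2))
}

#' Decode a kmer index into its DNA string
#'
#' @param index 1-based kmer index in lexicographic order (A < C < G < T).
#' @param k Kmer length.
#' @return The kmer as a character string.
#' @export
kmer_string <- function(index, k) {
  bases <- c("A", "C", "G", "T")
  idx <- as.integer(index) - 1L
  if (any(idx < 0L) || any(idx >= 4L^k)) stop("kmer index out of range")
  vapply(idx, function(i) {
    out <- character(k)
    for (pos in k:1) {
      out[pos] <- bases[i %% 4L + 1L]
      i <- i %/% 4L
    }
    paste0(out, collapse = "")
  }, character(1))
}

#' Do two kmers differ by a single homopolymer length edit?
#'
#' Tests whether deleting one character of `a` that sits inside a run
#' (i.e. equals an adjacent character) yields a length-(k-1) string that is
#' a prefix or a suffix of `b`, or symmetrically with the roles of `a` and
#' `b` swapped. Such kmer pairs are the signature of homopolymer indel
#' errors -- the dominant long-read error mode -- and are excluded when
#' selecting kmers for fine cluster splitting.
#'
#' @param a,b Kmer strings of equal length.
#' @return `TRUE` or `FALSE`. Identical kmers return `FALSE`.
#' @export
homopolymer_length_edit_pair <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (a == b) return(FALSE)
  one_way <- function(x, y) {
    cx <- strsplit(x, "", fixed = TRUE)[[1]]
    n <- length(cx)
    for (i in seq_len(n)) {
      in_run <- (i > 1L && cx[i] == cx[i - 1L]) ||
        (i < n && cx[i] == cx[i + 1L])
      if (!in_run) next
      shortened <- paste0(cx[-i], collapse = "")
      if (shortened == substr(y, 1L, n - 1L)) return(TRUE)
      if (shortened == substr(y, 2L, n)) return(TRUE)
    }
    FALSE
  }
  one_way(a, b) || one_way(b, a)
}

#' Select high-variance kmers for fine cluster splitting
#'
#' Computes the per-kmer (population) variance of counts across a set of
#' kmer vectors, takes the `M` highest-variance kmers, discards the
#' indel-sensitive kmers from that pool, and returns the `N`
#' highest-variance survivors. Ties in variance are broken toward the
#' lower kmer index so the selection is deterministic.
#'
#' Two filters remove kmers whose count variance can be driven by
#' homopolymer-length errors rather than genuine template differences:
#' every pooled kmer that itself contains a homopolymer run (two or more
#' adjacent equal bases) is discarded -- any kmer whose count changes
#' under a run-length edit of the sequence overlaps the run by at least
#' two characters, so this removes all columns directly perturbed by
#' run-length errors -- and, in addition, every kmer that participates in
#' a single-homopolymer-length-edit pair with another pooled kmer (see
#' [homopolymer_length_edit_pair()]) is discarded, which also catches the
#' run-free shifted partners that such errors create.
#'
#' @param vectors A list of `kmer_vector` objects, or a numeric matrix of
#'   counts (rows = sequences) with a `k` attribute, as produced internally.
#' @param M Size of the high-variance candidate pool (default 20).
#' @param N Number of kmers to return (default 6). Fewer may be returned if
#'   the homopolymer filter leaves fewer than `N` survivors.
#' @return Integer vector of 1-based kmer column indices, ordered by
#'   decreasing variance.
#' @export
top_variance_kmers <- function(vectors, M = 20L, N = 6L) {
  if (is.list(vectors)) {
    k <- vectors[[1L]]$k
    mat <- do.call(rbind, lapply(vectors, function(v) v$counts))
  } else {
    mat <- vectors
    k <- attr(mat, "k")
  }
  if (is.null(k)) stop("cannot determine k for the supplied vectors")
  if (nrow(mat) < 2L) stop("need at least two vectors")
  M <- as.integer(M); N <- as.integer(N)
  if (N < 1L || M < N) stop("require M >= N >= 1")
  n <- nrow(mat)
  mu <- colMeans(mat)
  vars <- colMeans(mat^2) - mu^2       # population variance
  pool <- order(-vars, seq_along(vars))[seq_len(min(M, length(vars)))]
  if (length(pool) > 0L) {
    kmers <- kmer_string(pool, k)
    # kmers containing a run are sensitive to homopolymer-length errors
    drop <- vapply(kmers, function(s) {
      cx <- strsplit(s, "", fixed = TRUE)[[1L]]
      any(cx[-1L] == cx[-length(cx)])
    }, logical(1), USE.NAMES = FALSE)
    for (i in seq_len(length(pool) - 1L)) {
      for (j in seq.int(i + 1L, length(pool))) {
        if (homopolymer_length_edit_pair(kmers[i], kmers[j])) {
          drop[i] <- TRUE
          drop[j] <- TRUE
        }
      }
    }
    pool <- pool[!drop]
  }
  pool[seq_len(min(N, length(pool)))]
}

#' Deterministic DNA sequence with all kmers distinct
#'
#' Builds a prefix of a greedy de Bruijn sequence over `{A,C,G,T}` of order
#' `k`: starting from `k` copies of `A`, each step appends the
#' lexicographically largest base that does not recreate an already-seen
#' kmer. Any prefix of length at most `4^k + k - 1` therefore contains
#' every kmer at most once -- handy for constructing sequences where the
#' kmer distance behaves exactly (a single substitution changes 2k count
#' entries).
#'
#' @param length Desired sequence length (must be <= `4^k + k - 1`).
#' @param k Kmer order (default 6).
#' @return A DNA string of the requested length whose kmers are all unique.
#' @export
unique_kmer_sequence <- function(length, k = 6L) {
  k <- as.integer(k)
  if (length < k) stop("length must be at least k")
  if (length > 4L^k + k - 1L) stop("length exceeds the de Bruijn bound")
  bases <- c("T", "G", "C", "A")
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- rep("A", length)
  assign(paste0(rep("A", k), collapse = ""), TRUE, envir = seen)
  pos <- k
  while (pos < length) {
    tail_km1 <- paste0(out[(pos - k + 2L):pos], collapse = "")
    placed <- FALSE
    for (b in bases) {
      cand <- paste0(tail_km1, b)
      if (!exists(cand, envir = seen, inherits = FALSE)) {
        assign(cand, TRUE, envir = seen)
        pos <- pos + 1L
        out[pos] <- b
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("greedy de Bruijn construction stalled") # unreachable within bound
  }
  paste0(out[seq_len(length)], collapse = "")
}
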