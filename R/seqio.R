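#' Expected number of errors implied by Phred quality scores
#'
#' Each Phred score Q corresponds to an error probability `10^(-Q/10)`;
#' the expected number of errors in a read is the sum of these
#' probabilities over its bases.
#'
#' @param quality Integer vector of Phred scores (all >= 0).
#' @return A single non-negative number; 0 for an empty vector.
#' @export
expected_errors <- function(quality) {
  if (length(quality) == 0L) return(0)
  if (any(quality < 0)) stop("Phred scores must be >= 0")
  sum(10^(-quality / 10))
}

#' Probability that a read contains zero errors
#'
#' Under a Poisson model for the number of errors in a read, the
#' probability of an error-free read is `exp(-E)` where E is the expected
#' error count. The Poisson form is used (rather than the product of
#' per-base no-error probabilities) so that it matches the Poisson
#' assumption of the downstream abundance test; the two agree to second
#' order in the per-base error probabilities.
#'
#' @param expected_errors Non-negative expected error count.
#' @export
prob_error_free <- function(expected_errors) {
  if (any(expected_errors < 0)) stop("expected_errors must be >= 0")
  exp(-expected_errors)
}

#' Read a FASTQ file of CCS amplicon reads
#'
#' Parses a plain 4-line-per-record FASTQ file with Phred+33 quality
#' encoding (the fixed encoding of modern instruments; other encodings are
#' rejected rather than guessed, in the sense that no autodetection is
#' attempted). Each record yields one row with the read id, sequence,
#' quality scores and the derived expected error count.
#'
#' @param path Path to the FASTQ file.
#' @return A `read_set`: a data.frame with columns `id`, `sequence`,
#'   `quality` (list column of integer Phred vectors) and
#'   `expected_errors`, one row per record in file order. An empty file
#'   yields zero rows.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(read_set(character(), character(), list()))
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: number of lines (", length(lines),
         ") is not a multiple of 4")
  }
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  if (any(substr(ids, 1L, 1L) != "@")) {
    bad <- which(substr(ids, 1L, 1L) != "@")[1L]
    stop("malformed FASTQ: record ", bad, " does not start with '@'")
  }
  ids <- sub("^@", "", ids)
  mismatch <- nchar(seqs) != nchar(quals)
  if (any(mismatch)) {
    bad <- which(mismatch)[1L]
    stop("malformed FASTQ record '", ids[bad],
         "': sequence and quality lengths differ (",
         nchar(seqs[bad]), " vs ", nchar(quals[bad]), ")")
  }
  qual_ints <- lapply(quals, function(q) utf8ToInt(q) - 33L)
  if (any(vapply(qual_ints, function(q) any(q < 0L), logical(1)))) {
    stop("quality characters below '!' found; input is not Phred+33")
  }
  read_set(ids, toupper(seqs), qual_ints)
}

# Construct a read_set data.frame from parallel vectors.
read_set <- function(id, sequence, quality) {
  ee <- vapply(quality, expected_errors, numeric(1))
  out <- data.frame(
    id = as.character(id),
    sequence = as.character(sequence),
    expected_errors = ee,
    stringsAsFactors = FALSE
  )
  out$quality <- quality
  class(out) <- c("read_set", "data.frame")
  out
}

#' Filter reads by expected error rate
#'
#' Retains reads whose expected error count per base
#' (`expected_errors / length`) is at most `max_rate`. A 1% threshold
#' (`max_rate = 0.01`) is the conventional retention cutoff for CCS
#' amplicon reads, and matches the default clustering radius of the robust
#' denoiser.
#'
#' @param reads A `read_set` (see [read_fastq()]).
#' @param max_rate Maximum expected errors per base, in (0, 1].
#' @return The retained rows, in their original order.
#' @export
filter_by_error_rate <- function(reads, max_rate = 0.01) {
  stopifnot(max_rate > 0, max_rate <= 1)
  keep <- reads$expected_errors / nchar(reads$sequence) <= max_rate
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dereplicate reads into unique sequences with counts
#'
#' Groups reads by exact full-length sequence identity, and orders the
#' resulting table by decreasing count, ties broken lexicographically by
#' sequence. No trimming or length binning is performed; primer/barcode
#' removal is an upstream concern.
#'
#' @param reads A `read_set`, or a character vector of sequences.
#' @return A data.frame with columns `sequence` and `count`, class
#'   `derep_table`. Counts sum to the number of input reads.
#' @export
dereplicate <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  tab <- table(seqs)
  out <- data.frame(
    sequence = names(tab),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("derep_table", "data.frame")
  out
}

#' Construct a template set
#'
#' A template set holds inferred (or true) variant sequences together with
#' assigned read counts and normalised frequencies.
#'
#' @param sequences Character vector of unique template sequences.
#' @param counts Non-negative read counts, one per sequence.
#' @return An object of class `template_set` with elements `sequences`,
#'   `counts` and `frequencies` (counts normalised to sum to one).
#' @export
template_set <- function(sequences, counts) {
  stopifnot(length(sequences) == length(counts), all(counts >= 0))
  if (anyDuplicated(sequences)) stop("template sequences must be unique")
  total <- sum(counts)
  freq <- if (total > 0) counts / total else rep(0, length(counts))
  structure(
    list(sequences = as.character(sequences),
         counts = as.numeric(counts),
         frequencies = freq),
    class = "template_set"
  )
}

#' @export
print.template_set <- function(x, ...) {
  cat("template_set with", length(x$sequences), "templates,",
      sum(x$counts), "assigned reads\n")
  invisible(x)
}

#' Write templates to an annotated FASTA file
#'
#' Writes one record per template with USEARCH-style abundance annotation
#' in the header: `;size=<count>` and/or `;freq=<frequency>` (frequency
#' printed with six decimal places).
#'
#' @param templates A [template_set()].
#' @param path Output file path.
#' @param dialect Which annotations to write: `"size"`, `"freq"` or
#'   `"both"`.
#' @return Invisibly, `path`.
#' @export
write_templates <- function(templates, path, dialect = c("size", "freq", "both")) {
  dialect <- match.arg(dialect)
  n <- length(templates$sequences)
  if (n == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  ann <- character(n)
  if (dialect %in% c("size", "both")) {
    ann <- paste0(ann, ";size=", format(round(templates$counts), scientific = FALSE, trim = TRUE))
  }
  if (dialect %in% c("freq", "both")) {
    ann <- paste0(ann, ";freq=", sprintf("%.6f", templates$frequencies))
  }
  headers <- paste0(">template_", seq_len(n), ann)
  writeLines(as.vector(rbind(headers, templates$sequences)), path)
  invisible(path)
}

#' Read an annotated template FASTA file
#'
#' Inverse of [write_templates()]: reads a FASTA file whose headers may
#' carry `;size=` and/or `;freq=` annotations. Frequencies are taken from
#' `;freq=` when present, otherwise from normalised `;size=` counts,
#' otherwise uniform.
#'
#' @param path Path to the FASTA file.
#' @return A [template_set()].
#' @export
read_template_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(template_set(character(), numeric()))
  is_header <- substr(lines, 1L, 1L) == ">"
  if (!is_header[1L]) stop("not a FASTA file: ", path)
  rec <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  seqs <- vapply(split(lines[!is_header], rec[!is_header]),
                 paste0, character(1), collapse = "")
  sizes <- suppressWarnings(as.numeric(sub(".*;size=([0-9]+).*", "\\1", headers)))
  sizes[!grepl(";size=", headers)] <- NA
  freqs <- suppressWarnings(as.numeric(sub(".*;freq=([0-9.eE+-]+).*", "\\1", headers)))
  freqs[!grepl(";freq=", headers)] <- NA
  counts <- if (!anyNA(sizes)) sizes else rep(1, length(headers))
  ts <- template_set(toupper(unname(seqs)), counts)
  if (!anyNA(freqs)) ts$frequencies <- freqs / sum(freqs)
  ts
}
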