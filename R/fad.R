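#' Configuration for the fast amplicon denoiser
#'
#' @param alpha Significance level of the Poisson offspring test
#'   (default 0.01).
#' @param min_count Minimum dereplicated abundance for a sequence to be
#'   considered as a candidate template (default 2: singletons are never
#'   trusted as templates).
#' @param neighbor_radius Corrected kmer distance below which a candidate
#'   is considered a potential error offspring of an accepted template, in
#'   base-equivalent units (default 1.0, i.e. one substitution).
#' @param k Kmer length for the distance approximation (default 6).
#' @return A list of class `fad_config`.
#' @export
fad_config <- function(alpha = 0.01, min_count = 2L, neighbor_radius = 1.0, k = 6L) {
  stopifnot(alpha > 0, alpha < 1, min_count >= 1, neighbor_radius > 0)
  structure(list(alpha = alpha, min_count = as.integer(min_count),
                 neighbor_radius = neighbor_radius, k = as.integer(k)),
            class = "fad_config")
}

#' Mean probability of an error-free read
#'
#' The expected proportion of error-free sequences in a dataset: the mean
#' over reads of `exp(-E)` where E is each read's expected error count.
#' Observed abundances of error-free template copies are corrected by this
#' fraction to estimate true template abundances.
#'
#' @param reads A `read_set`.
#' @return A number in (0, 1].
#' @export
error_free_fraction <- function(reads) {
  if (nrow(reads) == 0L) stop("cannot compute error-free fraction of no reads")
  mean(prob_error_free(reads$expected_errors))
}

#' P-value for the size of a putative error offspring
#'
#' Null hypothesis: the offspring sequence (a near-identical neighbour of a
#' more abundant parent template) consists purely of reads of the parent
#' that acquired an error at one specific site. The parent's observed
#' (dereplicated, error-free) abundance is first corrected to a total
#' abundance by dividing by the error-free fraction `f0`; with errors
#' assumed uniform over sites, the expected number of reads carrying an
#' error at one given site is `(parent_count / f0) * mean_errors /
#' mean_length`. The upper-tail Poisson probability of the observed
#' offspring count is Bonferroni-corrected for the `mean_length` sites at
#' which such an offspring could have arisen.
#'
#' @param parent_count Observed abundance of the parent.
#' @param offspring_count Observed abundance of the offspring.
#' @param f0 Error-free fraction of the dataset, in (0, 1].
#' @param mean_errors Mean expected errors per read over the dataset.
#' @param mean_length Mean read length over the dataset.
#' @return A p-value in (0, 1]; small values mean the offspring is too
#'   abundant to be explained by sequencing error and should be kept as a
#'   real template.
#' @export
offspring_pvalue <- function(parent_count, offspring_count, f0,
                             mean_errors, mean_length) {
  stopifnot(parent_count >= 0, offspring_count >= 0,
            f0 > 0, f0 <= 1, mean_length > 0, mean_errors >= 0)
  if (offspring_count == 0) return(1)
  mu <- (parent_count / f0) * mean_errors / mean_length
  raw <- stats::ppois(offspring_count - 1, mu, lower.tail = FALSE)
  min(1, mean_length * raw)
}

#' Assign reads to templates by minimum kmer distance
#'
#' Each read goes to the template with the smallest corrected kmer
#' distance; ties go to the template with the larger pre-assignment count,
#' then to the lower template index.
#'
#' @param reads A `read_set` or character vector of read sequences.
#' @param templates Character vector of template sequences.
#' @param template_counts Optional pre-assignment counts used only for tie
#'   breaking (defaults to all equal).
#' @param k Kmer length.
#' @return A list with `assignments` (template index per read), `counts`
#'   and `frequencies`.
#' @export
assign_to_templates <- function(reads, templates, template_counts = NULL, k = 6L) {
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  if (length(templates) == 0L) stop("need at least one template")
  if (is.null(template_counts)) template_counts <- rep(1, length(templates))
  X <- kmer_matrix(seqs, k)
  C <- kmer_matrix(templates, k)
  D <- corrected_cross_dist(X, C, k)
  pref <- order(-template_counts, seq_along(templates))   # tie-break priority
  assignments <- apply(D, 1L, function(d) {
    cand <- which(d <= min(d) + 1e-9)
    cand[order(match(cand, pref))][1L]
  })
  counts <- tabulate(assignments, nbins = length(templates))
  list(assignments = assignments, counts = counts,
       frequencies = counts / length(seqs))
}

# Corrected kmer distances between all rows of X and all rows of C.
corrected_cross_dist <- function(X, C, k) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * (X %*% t(C))
  d2[d2 < 0] <- 0
  d2 / (2 * k)
}

#' Fast amplicon denoising (read selection)
#'
#' Denoises a set of quality-filtered CCS reads in the short/accurate
#' regime, where an appreciable fraction of reads is error free. Reads are
#' dereplicated and sorted by abundance; sequences below `min_count` are
#' ignored. Walking from the most to the least abundant candidate, a
#' candidate is accepted as a template when it is at corrected kmer
#' distance of at least `neighbor_radius` (one base equivalent) from every
#' template accepted so far, or when the Bonferroni-corrected Poisson test
#' ([offspring_pvalue()]) against the most abundant accepted template
#' within that radius rejects the hypothesis that it is an error offspring.
#' Finally every input read is assigned to its nearest accepted template
#' and frequencies are recomputed. Accepted templates are always verbatim
#' input reads; no consensus averaging is performed.
#'
#' @param reads A `read_set` of quality-filtered reads.
#' @param config A [fad_config()].
#' @return A [template_set()] with attributes `error_free_fraction` and
#'   `duplicate_fraction` (diagnostics of whether the read-selection regime
#'   applies; a warning is emitted when the error-free fraction is very
#'   low, in which case the clustering-based robust denoiser is the right
#'   tool).
#' @seealso [rad_denoise()] for the long/inaccurate regime.
#' @export
fad_denoise <- function(reads, config = fad_config()) {
  if (nrow(reads) == 0L) stop("no reads supplied")
  derep <- dereplicate(reads)
  dup_fraction <- sum(derep$count[derep$count >= 2]) / sum(derep$count)
  cand <- derep[derep$count >= config$min_count, , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop("no sequence occurs at least ", config$min_count, " times; ",
         "there are too few error-free reads for read-selection denoising. ",
         "Use rad_denoise() for this dataset.")
  }
  f0 <- error_free_fraction(reads)
  if (f0 < 0.05) {
    warning("error-free fraction is ", signif(f0, 3),
            "; rad_denoise() is likely more appropriate for this dataset")
  }
  mean_errors <- mean(reads$expected_errors)
  mean_length <- mean(nchar(reads$sequence))

  K <- kmer_matrix(cand$sequence, config$k)
  accepted <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(accepted) == 0L) {
      accepted <- i
      next
    }
    diffs <- K[accepted, , drop = FALSE] -
      matrix(K[i, ], nrow = length(accepted), ncol = ncol(K), byrow = TRUE)
    d <- rowSums(diffs^2) / (2 * config$k)
    near <- which(d < config$neighbor_radius)
    if (length(near) == 0L) {
      accepted <- c(accepted, i)
    } else {
      parent <- accepted[near][which.max(cand$count[accepted[near]])]
      p <- offspring_pvalue(cand$count[parent], cand$count[i], f0,
                            mean_errors, mean_length)
      if (p <= config$alpha) accepted <- c(accepted, i)
    }
  }
  templates <- cand$sequence[accepted]
  asg <- assign_to_templates(reads, templates,
                             template_counts = cand$count[accepted],
                             k = config$k)
  out <- template_set(templates, asg$counts)
  attr(out, "error_free_fraction") <- f0
  attr(out, "duplicate_fraction") <- dup_fraction
  attr(out, "method") <- "fad"
  out
}
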