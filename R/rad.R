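#' Configuration for the robust amplicon denoiser
#'
#' @param coarse_radius DP-means radius for the initial kmer-domain
#'   clustering with the scaled kmer distance (default 0.01, matched to
#'   the 1% expected-error filtering threshold).
#' @param M High-variance kmer pool size for fine splitting (default 20).
#' @param N Dimension of the high-variance projection (default 6; a
#'   single-base difference perturbs at least 6 kmers, so this suffices to
#'   separate variants one base apart).
#' @param split_radius Euclidean DP-means radius in the projected space
#'   (default 1: reads differing at more than one selected kmer separate).
#' @param alpha Significance level for accepting a candidate split
#'   (default 0.01).
#' @param max_depth Recursion cap for [refine()] (default 20; hitting it
#'   logs a warning).
#' @param min_cluster Minimum final cluster size to report (default 5).
#'   In the long/inaccurate regime individual reads can drift beyond the
#'   coarse radius from every centroid and end up as stray singleton or
#'   near-singleton clusters of pure noise; clusters below this size are
#'   dropped before the consensus stage rather than reported as spurious
#'   low-frequency templates. Set to 1 to keep every cluster.
#' @param k Kmer length (default 6).
#' @param consensus A [consensus_config()] for the per-cluster consensus.
#' @return A list of class `rad_config`.
#' @export
rad_config <- function(coarse_radius = 0.01, M = 20L, N = 6L,
                       split_radius = 1.0, alpha = 0.01, max_depth = 20L,
                       min_cluster = 5L, k = 6L,
                       consensus = consensus_config()) {
  stopifnot(M >= N, N >= 1, split_radius > 0, coarse_radius > 0,
            alpha > 0, alpha < 1, max_depth >= 0, min_cluster >= 1)
  structure(list(coarse_radius = coarse_radius, M = as.integer(M),
                 N = as.integer(N), split_radius = split_radius,
                 alpha = alpha, max_depth = as.integer(max_depth),
                 min_cluster = as.integer(min_cluster), k = as.integer(k),
                 consensus = consensus),
            class = "rad_config")
}

#' Coarse kmer-domain clustering of reads
#'
#' Clusters the reads' kmer count vectors with pruned DP-means
#' ([dp_means_pruned()]) under the scaled kmer distance and the coarse
#' radius. Every read lands in exactly one cluster.
#'
#' @param reads A `read_set` of quality-filtered reads.
#' @param config A [rad_config()].
#' @return A list of clusters, each a list with `members` (read indices).
#'   The kmer count matrix of the reads is attached as attribute `kmat`
#'   for reuse by later stages.
#' @export
coarse_cluster <- function(reads, config = rad_config()) {
  kmat <- kmer_matrix(reads$sequence, config$k)
  cl <- dp_means_pruned(
    kmat,
    dp_means_config(radius = config$coarse_radius,
                    distance = "scaled_kmer", k = config$k),
    lengths = attr(kmat, "seq_lengths")
  )
  clusters <- lapply(seq_len(nrow(cl$centroids)), function(i) {
    list(members = which(cl$assignments == i))
  })
  attr(clusters, "kmat") <- kmat
  clusters
}

# Dataset-wide error statistics driving the split significance test.
rad_stats <- function(reads) {
  list(mean_errors = mean(reads$expected_errors),
       mean_length = mean(nchar(reads$sequence)))
}

#' Attempt one fine split of a cluster
#'
#' Projects the cluster members onto their `N` highest-variance kmers
#' (after discarding homopolymer-length-edit kmer pairs, see
#' [top_variance_kmers()]) and runs Euclidean DP-means with the split
#' radius on that low-dimensional representation. The candidate
#' sub-clusters are then screened by abundance: a sub-cluster is
#' significant when the Bonferroni-corrected Poisson test
#' ([offspring_pvalue()]) rejects the hypothesis that its size is
#' explained by reads of the largest sub-cluster carrying an error at one
#' site. If no sub-cluster besides the largest is significant the split
#' is rejected and the cluster returned unchanged; otherwise
#' non-significant fragments are reabsorbed into the nearest significant
#' sub-cluster (projected centroid distance), so error-driven shattering
#' never survives.
#'
#' No error-free-fraction correction is applied to the parent abundance
#' here (`f0 = 1`): cluster sizes already count every noisy read of a
#' template, unlike the dereplicated error-free counts the fast denoiser
#' corrects.
#'
#' @param members Integer vector of read indices in the cluster.
#' @param kmat Kmer count matrix of all reads (with `k` attribute).
#' @param config A [rad_config()].
#' @param stats Dataset statistics from the filtered reads: list with
#'   `mean_errors` and `mean_length`.
#' @return A list of member index vectors: length one if the split was
#'   rejected, otherwise one element per accepted sub-cluster.
#' @export
split_once <- function(members, kmat, config, stats) {
  if (length(members) < 2L) return(list(members))
  X <- kmat[members, , drop = FALSE]
  attr(X, "k") <- attr(kmat, "k")
  idx <- top_variance_kmers(X, M = config$M, N = config$N)
  if (length(idx) == 0L) return(list(members))
  P <- X[, idx, drop = FALSE]
  cl <- dp_means(P, dp_means_config(radius = config$split_radius,
                                    distance = "euclidean"))
  ncl <- nrow(cl$centroids)
  if (ncl < 2L) return(list(members))
  sizes <- cl$sizes
  largest <- which.max(sizes)
  others <- setdiff(seq_len(ncl), largest)
  pvals <- vapply(others, function(j) {
    offspring_pvalue(sizes[largest], sizes[j], f0 = 1,
                     mean_errors = stats$mean_errors,
                     mean_length = stats$mean_length)
  }, numeric(1))
  significant <- others[pvals <= config$alpha]
  if (length(significant) == 0L) return(list(members))
  keep <- c(largest, significant)
  failed <- setdiff(seq_len(ncl), keep)
  dest <- cl$assignments
  if (length(failed) > 0L) {
    for (f in failed) {
      d <- rowSums((cl$centroids[keep, , drop = FALSE] -
                      matrix(cl$centroids[f, ], nrow = length(keep),
                             ncol = ncol(cl$centroids), byrow = TRUE))^2)
      dest[dest == f] <- keep[which.min(d)]
    }
  }
  lapply(keep, function(cid) members[dest == cid])
}

#' Recursively refine clusters by fine splitting
#'
#' Applies [split_once()] to every cluster and recurses into accepted
#' sub-clusters until no split is accepted or the recursion depth cap is
#' reached. A rejected split is terminal for that cluster. The output
#' clusters always partition the input reads, and refinement never merges
#' clusters.
#'
#' @param clusters A list of clusters (lists with `members`), e.g. from
#'   [coarse_cluster()].
#' @inheritParams split_once
#' @return A list of refined clusters in the same format.
#' @export
refine <- function(clusters, kmat, config, stats) {
  out <- list()
  queue <- lapply(clusters, function(cl) list(members = cl$members, depth = 0L))
  depth_hit <- FALSE
  while (length(queue) > 0L) {
    item <- queue[[1L]]
    queue <- queue[-1L]
    if (item$depth >= config$max_depth) {
      if (config$max_depth > 0L) depth_hit <- TRUE
      out[[length(out) + 1L]] <- list(members = item$members)
      next
    }
    parts <- split_once(item$members, kmat, config, stats)
    if (length(parts) == 1L) {
      out[[length(out) + 1L]] <- list(members = parts[[1L]])
    } else {
      queue <- c(lapply(parts, function(p) {
        list(members = p, depth = item$depth + 1L)
      }), queue)
    }
  }
  if (depth_hit) warning("refinement recursion depth cap reached")
  out
}

#' Robust amplicon denoising (cluster and average)
#'
#' Denoises quality-filtered CCS reads in the long/inaccurate regime,
#' where few or no reads are error free: coarse DP-means clustering of
#' kmer vectors ([coarse_cluster()]), recursive fine splitting on
#' high-variance kmers ([refine()]), and a kmer-seeded alignment consensus
#' per final cluster ([cluster_consensus()]). Identical consensus
#' sequences are merged with their counts summed; frequencies come from
#' final cluster sizes (there is no global read re-assignment, which is a
#' read-selection concern of the fast denoiser).
#'
#' @param reads A `read_set` of quality-filtered reads.
#' @param config A [rad_config()].
#' @return A [template_set()] of consensus templates, counts and
#'   frequencies; attribute `method` is `"rad"`.
#' @seealso [fad_denoise()] for the short/accurate regime.
#' @export
rad_denoise <- function(reads, config = rad_config()) {
  if (nrow(reads) == 0L) stop("no reads supplied")
  stats <- rad_stats(reads)
  clusters <- coarse_cluster(reads, config)
  kmat <- attr(clusters, "kmat")
  clusters <- refine(clusters, kmat, config, stats)
  clusters <- clusters[vapply(clusters, function(cl) length(cl$members),
                              integer(1)) >= config$min_cluster]
  if (length(clusters) == 0L) stop("no cluster meets min_cluster")
  consensi <- vapply(clusters, function(cl) {
    sub <- kmat[cl$members, , drop = FALSE]
    attr(sub, "k") <- attr(kmat, "k")
    cluster_consensus(reads$sequence[cl$members], config$consensus,
                      k = config$k, kmat = sub)
  }, character(1))
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  counts <- tapply(sizes, consensi, sum)
  out <- template_set(names(counts), as.numeric(counts))
  attr(out, "method") <- "rad"
  attr(out, "n_clusters") <- length(clusters)
  out
}
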