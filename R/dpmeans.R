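#' Configuration for DP-means clustering
#'
#' DP-means is the small-variance deterministic limit of a Dirichlet
#' process Gaussian mixture: a k-means-like pass algorithm in which an
#' element farther than a radius `lambda` from every current centroid
#' seeds a new cluster, so the number of clusters is controlled by the
#' radius rather than fixed in advance. Setting the radius to the
#' sequencing error rate (0.01 for 1%-filtered CCS reads, with the scaled
#' kmer distance) is what makes it fit amplicon clustering: two reads
#' farther apart than the error rate cannot come from one template.
#'
#' @param radius The cluster radius lambda (default 0.01, appropriate for
#'   the scaled kmer distance on 1%-filtered reads).
#' @param max_iterations Cap on assign/update passes (default 100; the
#'   algorithm almost always converges in a handful).
#' @param distance `"scaled_kmer"` (corrected kmer distance divided by
#'   mean sequence length) or `"euclidean"` (used for the low-dimensional
#'   projections of fine cluster splitting).
#' @param k Kmer length, used only by the scaled kmer distance.
#' @return A list of class `dp_means_config`.
#' @export
dp_means_config <- function(radius = 0.01, max_iterations = 100L,
                            distance = c("scaled_kmer", "euclidean"),
                            k = 6L) {
  distance <- match.arg(distance)
  stopifnot(radius > 0, max_iterations >= 1)
  structure(list(radius = radius,
                 max_iterations = as.integer(max_iterations),
                 distance = distance, k = as.integer(k)),
            class = "dp_means_config")
}

# Distances from one point to all current centroids under the configured
# metric. For "scaled_kmer", `len` is the point's sequence length and
# `clens` the centroids' mean member lengths.
point_centroid_dist <- function(x, C, config, len = NULL, clens = NULL) {
  d2 <- rowSums((C - matrix(x, nrow = nrow(C), ncol = length(x),
                            byrow = TRUE))^2)
  if (config$distance == "euclidean") {
    sqrt(d2)
  } else {
    d2 / (2 * config$k) / ((len + clens) / 2)
  }
}

#' DP-means clustering of points or kmer vectors
#'
#' Deterministic given the input order: the first element seeds the first
#' cluster; each pass assigns every element to the nearest centroid if
#' that distance is below the radius and otherwise seeds a new cluster at
#' the element; after each pass centroids are recomputed as coordinate
#' means of their members (empty clusters are dropped) until an assignment
#' pass changes nothing or `max_iterations` is reached. Permuting the
#' input can change the clustering -- callers fix the read order for
#' reproducibility.
#'
#' @param points Numeric matrix, one row per element. For the scaled kmer
#'   distance this is a kmer count matrix; per-row sequence lengths are
#'   taken from the `seq_lengths` attribute or the `lengths` argument.
#' @param config A [dp_means_config()].
#' @param lengths Sequence lengths per row (scaled kmer distance only).
#' @return A list of class `dp_clustering`: `assignments` (cluster index
#'   per element), `centroids` (matrix), `sizes`, `centroid_lengths`, and
#'   `dist_evals` (number of point-to-centroid distance evaluations, for
#'   instrumentation).
#' @export
dp_means <- function(points, config = dp_means_config(), lengths = NULL) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 1L)
  n <- nrow(points)
  if (n < 1L) stop("need at least one point")
  scaled <- config$distance == "scaled_kmer"
  if (scaled) {
    if (is.null(lengths)) lengths <- attr(points, "seq_lengths")
    if (is.null(lengths)) stop("scaled kmer distance needs sequence lengths")
  }
  C <- points[1L, , drop = FALSE]
  clens <- if (scaled) lengths[1L] else NA_real_
  assignments <- rep(NA_integer_, n)
  evals <- 0L
  for (pass in seq_len(config$max_iterations)) {
    prev <- assignments
    for (i in seq_len(n)) {
      d <- point_centroid_dist(points[i, ], C, config,
                               len = if (scaled) lengths[i] else NULL,
                               clens = clens)
      evals <- evals + length(d)
      if (min(d) < config$radius) {
        assignments[i] <- which.min(d)
      } else {
        C <- rbind(C, points[i, ])
        clens <- c(clens, if (scaled) lengths[i] else NA_real_)
        assignments[i] <- nrow(C)
      }
    }
    upd <- update_centroids(points, assignments, lengths, scaled)
    C <- upd$C; clens <- upd$clens; assignments <- upd$assignments
    if (identical(assignments, prev)) break
  }
  structure(list(assignments = assignments, centroids = C,
                 sizes = tabulate(assignments, nbins = nrow(C)),
                 centroid_lengths = clens, dist_evals = evals),
            class = "dp_clustering")
}

# Recompute centroids as member means, drop empty clusters, relabel
# assignments to consecutive indices in centroid order.
update_centroids <- function(points, assignments, lengths, scaled) {
  present <- sort(unique(assignments))
  C <- do.call(rbind, lapply(present, function(cl) {
    colMeans(points[assignments == cl, , drop = FALSE])
  }))
  clens <- if (scaled) {
    vapply(present, function(cl) mean(lengths[assignments == cl]), numeric(1))
  } else {
    rep(NA_real_, length(present))
  }
  list(C = C, clens = clens,
       assignments = match(assignments, present))
}

#' DP-means with meta-centroid triangle-inequality pruning
#'
#' Returns a clustering identical to [dp_means()] on the same input and
#' order, but skips provably useless distance computations. After the
#' first pass, the centroids themselves are clustered into a coarse set of
#' meta-centroids; the Euclidean distance from every read to every
#' meta-centroid is computed once. On later passes a read-to-centroid
#' distance is only computed when the Euclidean lower bound
#' `|d(read, meta) - d(centroid, meta)|` does not already prove the scaled
#' distance to be at least the radius. The bound lives in the Euclidean
#' kmer domain (a true metric); the scaled radius `lambda` converts to the
#' per-pair Euclidean threshold `sqrt(2 k lambda * mean length)`, so the
#' pruning is conservative and exact, not approximate.
#'
#' @inheritParams dp_means
#' @param meta_radius_factor The meta-centroids are built with radius
#'   `meta_radius_factor * radius` (default 4: coarse super-clusters keep
#'   the bounds tight without many meta-centroids; correctness does not
#'   depend on this choice).
#' @return A `dp_clustering`, as for [dp_means()]; `dist_evals` counts
#'   only the full distance evaluations actually performed.
#' @export
dp_means_pruned <- function(points, config = dp_means_config(), lengths = NULL,
                            meta_radius_factor = 4) {
  if (config$distance != "scaled_kmer") {
    stop("pruned DP-means is defined for the scaled kmer distance")
  }
  if (!is.matrix(points)) points <- matrix(points, ncol = 1L)
  n <- nrow(points)
  if (is.null(lengths)) lengths <- attr(points, "seq_lengths")
  if (is.null(lengths)) stop("scaled kmer distance needs sequence lengths")
  twok <- 2 * config$k

  # first pass: identical to naive DP-means
  C <- points[1L, , drop = FALSE]
  clens <- lengths[1L]
  assignments <- rep(NA_integer_, n)
  evals <- 0L
  for (i in seq_len(n)) {
    d <- point_centroid_dist(points[i, ], C, config,
                             len = lengths[i], clens = clens)
    evals <- evals + length(d)
    if (min(d) < config$radius) {
      assignments[i] <- which.min(d)
    } else {
      C <- rbind(C, points[i, ])
      clens <- c(clens, lengths[i])
      assignments[i] <- nrow(C)
    }
  }
  upd <- update_centroids(points, assignments, lengths, TRUE)
  C <- upd$C; clens <- upd$clens; assignments <- upd$assignments

  # meta-centroids from the first-pass centroids, then read-to-meta
  # Euclidean distances, computed once
  meta_cfg <- dp_means_config(radius = meta_radius_factor * config$radius,
                              max_iterations = 10L,
                              distance = "scaled_kmer", k = config$k)
  meta <- dp_means(C, meta_cfg, lengths = clens)
  Mc <- meta$centroids
  RM <- euclid_cross(points, Mc)

  for (pass in seq_len(config$max_iterations - 1L) + 1L) {
    prev <- assignments
    CM <- euclid_cross(C, Mc)
    for (i in seq_len(n)) {
      lb <- rep(0, nrow(C))
      for (m in seq_len(ncol(RM))) {
        lb <- pmax(lb, abs(RM[i, m] - CM[, m]))
      }
      thresh <- sqrt(twok * config$radius * (lengths[i] + clens) / 2)
      cand <- which(lb < thresh)
      if (length(cand) > 0L) {
        diffs <- C[cand, , drop = FALSE] -
          matrix(points[i, ], nrow = length(cand), ncol = ncol(C), byrow = TRUE)
        d <- rowSums(diffs^2) / twok / ((lengths[i] + clens[cand]) / 2)
        evals <- evals + length(d)
      } else {
        d <- numeric(0)
      }
      if (length(d) > 0L && min(d) < config$radius) {
        assignments[i] <- cand[which.min(d)]
      } else {
        C <- rbind(C, points[i, ])
        clens <- c(clens, lengths[i])
        CM <- rbind(CM, RM[i, ])
        assignments[i] <- nrow(C)
      }
    }
    upd <- update_centroids(points, assignments, lengths, TRUE)
    C <- upd$C; clens <- upd$clens; assignments <- upd$assignments
    if (identical(assignments, prev)) break
  }
  structure(list(assignments = assignments, centroids = C,
                 sizes = tabulate(assignments, nbins = nrow(C)),
                 centroid_lengths = clens, dist_evals = evals),
            class = "dp_clustering")
}

# Euclidean distance matrix between rows of X and rows of Y.
euclid_cross <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(Y))) +
    outer(rep(1, nrow(X)), rowSums(Y^2)) - 2 * (X %*% t(Y))
  d2[d2 < 0] <- 0
  sqrt(d2)
}
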