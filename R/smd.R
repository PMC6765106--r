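#' Levenshtein edit distance
#'
#' Exact unit-cost edit distance (substitutions, insertions and deletions
#' all cost 1), computed with a band-doubling dynamic program so that
#' closely related kilobase-scale sequences compare quickly.
#'
#' @param a,b Character strings.
#' @return Non-negative integer.
#' @export
edit_distance <- function(a, b) {
  .cpp_edit_distance(a, b)
}

#' Pairwise edit distance matrix
#'
#' @param a,b Character vectors of sequences.
#' @return Integer matrix of dimension `length(a) x length(b)`.
#' @export
edit_distance_matrix <- function(a, b) {
  .cpp_edit_distance_matrix(a, b)
}

#' Construct a weighted sequence population
#'
#' A population is a set of sequences with associated frequencies. For the
#' population-comparison metric the frequencies must be supplied already
#' normalised (summing to one within 1e-6); converting counts to
#' frequencies is the caller's job, and no silent renormalisation is
#' performed.
#'
#' @param sequences Character vector of sequences.
#' @param frequencies Non-negative frequencies summing to 1.
#' @return An object of class `weighted_population`.
#' @export
weighted_population <- function(sequences, frequencies) {
  stopifnot(length(sequences) == length(frequencies))
  if (length(sequences) == 0L) stop("population must be non-empty")
  if (any(frequencies < 0)) stop("frequencies must be non-negative")
  if (abs(sum(frequencies) - 1) > 1e-6) {
    stop("frequencies must sum to 1 (got ", format(sum(frequencies)), ")")
  }
  structure(list(sequences = as.character(sequences),
                 frequencies = as.numeric(frequencies)),
            class = "weighted_population")
}

#' Coerce to a weighted population
#'
#' @param x A `weighted_population`, [template_set()], or list with
#'   `sequences` and `frequencies`.
#' @export
as_weighted_population <- function(x) {
  if (inherits(x, "weighted_population")) return(x)
  if (!is.null(x$sequences) && !is.null(x$frequencies)) {
    return(weighted_population(x$sequences, x$frequencies))
  }
  stop("cannot coerce object to weighted_population")
}

#' Sequence Mutation Distance between two weighted populations
#'
#' The Sequence Mutation Distance (SMD) is an earth mover's distance over
#' sequence populations: given the matrix `D` of pairwise edit distances
#' between the truth population A (rows) and the inferred population B
#' (columns), it is the minimum of `sum(F * D)` over flow matrices `F >= 0`
#' whose row sums equal the frequencies of A and whose column sums equal
#' the frequencies of B. The value is the frequency-weighted average number
#' of nucleotide changes per sequence needed to convert A into B, so it
#' reads directly as a per-sequence error rate of a reconstruction.
#'
#' Two one-sided relaxations are reported alongside: dropping the row
#' (truth) constraint gives `smd_fp`, which grows with false-positive
#' sequences in B, and dropping the column constraint gives `smd_fn`,
#' which grows when B is missing true sequences. The optimal flow is
#' possibly non-unique; only the objective value is meaningful.
#'
#' @param truth The ground-truth population (rows of the flow matrix).
#' @param inferred The inferred population (columns).
#' @return An object of class `smd_result`: list with the distance matrix
#'   `D`, an optimal flow `F`, and the scores `smd`, `smd_fp`, `smd_fn`.
#' @examples
#' a <- weighted_population(c("ACGTACGT", "ACGAACGT"), c(0.5, 0.5))
#' b <- weighted_population(c("ACGTACGT", "ACGAACGT"), c(0.25, 0.75))
#' smd(a, b)$smd  # 0.25 of the mass moves across 1 edit
#' @export
smd <- function(truth, inferred) {
  truth <- as_weighted_population(truth)
  inferred <- as_weighted_population(inferred)
  D <- edit_distance_matrix(truth$sequences, inferred$sequences)
  sol <- solve_transport(D, truth$frequencies, inferred$frequencies)
  structure(
    list(
      D = D,
      F = sol$flow,
      smd = sol$cost,
      smd_fp = sum(inferred$frequencies * apply(D, 2L, min)),
      smd_fn = sum(truth$frequencies * apply(D, 1L, min))
    ),
    class = "smd_result"
  )
}

#' @export
print.smd_result <- function(x, ...) {
  cat(sprintf("SMD: %.6g (FP: %.6g, FN: %.6g)\n", x$smd, x$smd_fp, x$smd_fn))
  invisible(x)
}

#' One-sided relaxations of the Sequence Mutation Distance
#'
#' With the constraint on the truth marginal dropped, the optimal flow
#' sends each inferred sequence's full frequency to its nearest true
#' sequence, so `smd_fp` has the closed form
#' `sum_j freq(B_j) * min_i D[i, j]`; `smd_fn` is the symmetric expression
#' over rows. Both are bounded above by the full `smd`.
#'
#' @inheritParams smd
#' @return A list with elements `smd_fp` and `smd_fn`.
#' @export
smd_relaxed <- function(truth, inferred) {
  truth <- as_weighted_population(truth)
  inferred <- as_weighted_population(inferred)
  D <- edit_distance_matrix(truth$sequences, inferred$sequences)
  list(
    smd_fp = sum(inferred$frequencies * apply(D, 2L, min)),
    smd_fn = sum(truth$frequencies * apply(D, 1L, min))
  )
}
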