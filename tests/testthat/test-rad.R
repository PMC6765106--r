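rad_reads <- function(sequences, q = 20L) {
  ampdenoise:::read_set(
    id = sprintf("r%05d", seq_along(sequences)),
    sequence = sequences,
    quality = lapply(nchar(sequences), function(n) rep(q, n))
  )
}

test_that("coarse_cluster separates strongly diverged templates", {
  set.seed(71)
  t1 <- random_dna(600L)
  t2 <- random_dna(600L)
  rs <- rad_reads(c(rep(t1, 6L), rep(t2, 4L)))
  clusters <- coarse_cluster(rs, rad_config())
  expect_equal(length(clusters), 2L)
  expect_setequal(clusters[[1L]]$members, 1:6)
  expect_setequal(clusters[[2L]]$members, 7:10)
  expect_false(is.null(attr(clusters, "kmat")))
})

test_that("split_once separates a balanced single-substitution mixture", {
  pair <- clean_snp_pair(len = 400L, seed = 2L)
  seqs <- c(rep(pair$a, 100L), rep(pair$b, 100L))
  kmat <- kmer_matrix(seqs, 6L)
  attr(kmat, "k") <- 6L
  stats <- list(mean_errors = 4, mean_length = 400)
  parts <- split_once(seq_along(seqs), kmat, rad_config(), stats)
  expect_equal(length(parts), 2L)
  sizes <- sort(vapply(parts, length, integer(1)))
  expect_equal(sizes, c(100L, 100L))
  # the split tracks the true origin exactly
  origins <- rep(1:2, each = 100L)
  for (p in parts) expect_equal(length(unique(origins[p])), 1L)
})

test_that("split_once leaves a homogeneous cluster unchanged", {
  set.seed(73)
  s <- random_dna(400L)
  seqs <- rep(s, 50L)
  kmat <- kmer_matrix(seqs, 6L)
  attr(kmat, "k") <- 6L
  stats <- list(mean_errors = 4, mean_length = 400)
  parts <- split_once(seq_along(seqs), kmat, rad_config(), stats)
  expect_equal(parts, list(seq_along(seqs)))
})

test_that("split_once rejects a split driven by a tiny fragment", {
  # 100 copies of one template plus 2 copies of a 1-sub variant: a size-2
  # fragment is well within Poisson noise from a 100-read parent at these
  # error rates, so the split must be rejected.
  pair <- clean_snp_pair(len = 400L, seed = 3L)
  seqs <- c(rep(pair$a, 100L), rep(pair$b, 2L))
  kmat <- kmer_matrix(seqs, 6L)
  attr(kmat, "k") <- 6L
  stats <- list(mean_errors = 4, mean_length = 400)
  parts <- split_once(seq_along(seqs), kmat, rad_config(), stats)
  expect_equal(length(parts), 1L)
  expect_setequal(parts[[1L]], seq_along(seqs))
})

test_that("split_once ignores pure homopolymer-length variation", {
  set.seed(79)
  left <- random_dna(200L); right <- random_dna(200L)
  a <- paste0(left, "AAA", right)
  b <- paste0(left, "AAAA", right)
  seqs <- c(rep(a, 60L), rep(b, 60L))
  kmat <- kmer_matrix(seqs, 6L)
  attr(kmat, "k") <- 6L
  stats <- list(mean_errors = 4, mean_length = 403)
  parts <- split_once(seq_along(seqs), kmat, rad_config(), stats)
  expect_equal(length(parts), 1L)
})

test_that("refine partitions the reads and is idempotent when converged", {
  pair <- clean_snp_pair(len = 400L, seed = 5L)
  seqs <- c(rep(pair$a, 80L), rep(pair$b, 80L))
  kmat <- kmer_matrix(seqs, 6L)
  attr(kmat, "k") <- 6L
  stats <- list(mean_errors = 4, mean_length = 400)
  cfg <- rad_config()
  refined <- refine(list(list(members = seq_along(seqs))), kmat, cfg, stats)
  expect_equal(length(refined), 2L)
  all_members <- sort(unlist(lapply(refined, `[[`, "members")))
  expect_equal(all_members, seq_along(seqs))
  # running refine again changes nothing (up to cluster order)
  again <- refine(refined, kmat, cfg, stats)
  key <- function(cls) {
    sort(vapply(cls, function(cl) paste(sort(cl$members), collapse = ","),
                character(1)))
  }
  expect_equal(key(again), key(refined))
})

test_that("refine with max_depth 0 returns clusters verbatim", {
  pair <- clean_snp_pair(len = 400L, seed = 7L)
  seqs <- c(rep(pair$a, 50L), rep(pair$b, 50L))
  kmat <- kmer_matrix(seqs, 6L)
  attr(kmat, "k") <- 6L
  stats <- list(mean_errors = 4, mean_length = 400)
  cfg <- rad_config(max_depth = 0L)
  out <- refine(list(list(members = seq_along(seqs))), kmat, cfg, stats)
  expect_equal(length(out), 1L)
  expect_setequal(out[[1L]]$members, seq_along(seqs))
})

test_that("rad_denoise recovers diverged templates from error-free reads", {
  set.seed(83)
  base <- random_dna(600L)
  pop <- generate_templates(base, n_templates = 5L, subs_per_template = 40L,
                            min_pairwise_distance = 30L, rng_seed = 9L)
  seqs <- rep(pop$sequences, each = 20L)
  out <- rad_denoise(rad_reads(seqs))
  expect_setequal(out$sequences, pop$sequences)
  expect_equal(out$frequencies, rep(0.2, 5L), tolerance = 1e-12)
  expect_equal(attr(out, "method"), "rad")
  expect_equal(attr(out, "n_clusters"), 5L)
})

test_that("rad and fad agree on clean well-separated data", {
  set.seed(89)
  t1 <- random_dna(500L)
  t2 <- random_dna(500L)
  rs <- rad_reads(c(rep(t1, 30L), rep(t2, 20L)), q = 93L)
  r <- rad_denoise(rs)
  f <- fad_denoise(rs)
  expect_setequal(r$sequences, f$sequences)
  o <- match(f$sequences, r$sequences)
  expect_equal(r$frequencies[o], f$frequencies, tolerance = 1e-12)
})

test_that("min_cluster drops stray micro-clusters", {
  set.seed(97)
  t1 <- random_dna(600L)
  stray <- random_dna(600L)
  rs <- rad_reads(c(rep(t1, 30L), rep(stray, 2L)))
  out <- rad_denoise(rs)  # default min_cluster = 5
  expect_equal(out$sequences, t1)
  keep <- rad_denoise(rs, rad_config(min_cluster = 1L))
  expect_setequal(keep$sequences, c(t1, stray))
})

test_that("rad_denoise merges clusters with identical consensus", {
  # two coarse clusters cannot form here, but duplicate consensi can come
  # from an accepted split whose halves polish to the same template; use
  # min_cluster = 1 with two identical-read groups listed apart
  set.seed(101)
  t1 <- random_dna(600L)
  rs <- rad_reads(rep(t1, 12L))
  out <- rad_denoise(rs, rad_config(min_cluster = 1L))
  expect_equal(out$sequences, t1)
  expect_equal(out$frequencies, 1)
})
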