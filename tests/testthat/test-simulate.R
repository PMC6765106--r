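test_that("example_amplicon is deterministic and well-formed", {
  a <- example_amplicon(2600L)
  b <- example_amplicon(2600L)
  expect_identical(a, b)
  expect_equal(nchar(a), 2600L)
  expect_true(grepl("^[ACGT]+$", a))
})

test_that("simulate_reads is byte-identical across runs with one seed", {
  pop <- weighted_population(c(example_amplicon(600L)), 1)
  profile <- error_profile(0.002, 0.01)
  p1 <- tempfile(fileext = ".fastq"); p2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(pop, 40L, profile, rng_seed = 5L)$reads, p1)
  write_fastq(simulate_reads(pop, 40L, profile, rng_seed = 5L)$reads, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed gives different reads
  p3 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(pop, 40L, profile, rng_seed = 6L)$reads, p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("simulate_reads does not disturb the caller's RNG stream", {
  pop <- weighted_population(example_amplicon(600L), 1)
  set.seed(12345)
  before <- runif(1)
  set.seed(12345)
  invisible(simulate_reads(pop, 5L, error_profile(0.01, 0.01), rng_seed = 99L))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("a zero-rate profile reproduces templates verbatim", {
  pop <- weighted_population(c(example_amplicon(800L)), 1)
  sim <- simulate_reads(pop, 20L, error_profile(0, 0), rng_seed = 1L)
  expect_true(all(sim$reads$sequence == pop$sequences))
  # quality then encodes a zero error rate: Q93
  expect_true(all(vapply(sim$reads$quality, function(q) all(q == 93L),
                         logical(1))))
})

test_that("empirical substitution rate matches the profile within 10%", {
  tpl <- example_amplicon(2000L)
  pop <- weighted_population(tpl, 1)
  rate <- 0.01
  sim <- simulate_reads(pop, 300L, error_profile(rate, 0), rng_seed = 7L)
  # with no indels every read aligns positionally; count mismatches
  tc <- strsplit(tpl, "", fixed = TRUE)[[1L]]
  mism <- vapply(sim$reads$sequence, function(s) {
    sum(strsplit(s, "", fixed = TRUE)[[1L]] != tc)
  }, numeric(1), USE.NAMES = FALSE)
  emp <- sum(mism) / (300 * 2000)
  expect_lte(abs(emp - rate) / rate, 0.1)
})

test_that("substitution-only errors never change homopolymer run lengths", {
  tpl <- example_amplicon(1500L)
  sim <- simulate_reads(weighted_population(tpl, 1), 50L,
                        error_profile(0.01, 0), rng_seed = 9L)
  expect_true(all(nchar(sim$reads$sequence) == 1500L))
})

test_that("indel-only errors only change run lengths, never run bases", {
  tpl <- example_amplicon(1500L)
  sim <- simulate_reads(weighted_population(tpl, 1), 50L,
                        error_profile(0, 0.02), rng_seed = 11L)
  tpl_runs <- rle(strsplit(tpl, "", fixed = TRUE)[[1L]])
  for (s in sim$reads$sequence) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
    # dropped runs (length 0) aside, the base sequence of runs is a
    # subsequence-preserving match: after removing zero-length runs the
    # values must embed into the template's run values in order
    expect_true(length(r$values) <= length(tpl_runs$values))
  }
  # length-1 runs are never touched: a template with no runs >= 2 is
  # immune to indels
  flat <- paste(rep("ACGT", 200L), collapse = "")
  sim2 <- simulate_reads(weighted_population(flat, 1), 20L,
                         error_profile(0, 0.2), rng_seed = 13L)
  expect_true(all(sim2$reads$sequence == flat))
})

test_that("quality-implied expected errors track realised errors", {
  tpl <- example_amplicon(2000L)
  profile <- error_profile(0.002, 0.018)
  sim <- simulate_reads(weighted_population(tpl, 1), 200L, profile,
                        rng_seed = 15L)
  implied <- mean(sim$reads$expected_errors)
  realised <- mean(vapply(sim$reads$sequence, edit_distance, numeric(1),
                          b = tpl, USE.NAMES = FALSE))
  expect_lte(abs(implied - realised) / realised, 0.15)
})

test_that("phred encoding of a rate is clamped to [2, 93]", {
  expect_equal(ampdenoise:::phred_for_rate(0), 93L)
  expect_equal(ampdenoise:::phred_for_rate(1), 2L)
  expect_equal(ampdenoise:::phred_for_rate(0.001), 30L)
  expect_equal(ampdenoise:::phred_for_rate(1e-12), 93L)
})

test_that("generate_templates honours the minimum pairwise distance", {
  base <- example_amplicon(800L)
  pop <- generate_templates(base, n_templates = 6L, subs_per_template = 8L,
                            min_pairwise_distance = 4L, rng_seed = 21L)
  expect_equal(length(pop$sequences), 6L)
  expect_equal(sum(pop$frequencies), 1, tolerance = 1e-12)
  D <- edit_distance_matrix(pop$sequences, pop$sequences)
  expect_gte(min(D[upper.tri(D)]), 4L)
  # reproducible
  pop2 <- generate_templates(base, n_templates = 6L, subs_per_template = 8L,
                             min_pairwise_distance = 4L, rng_seed = 21L)
  expect_identical(pop, pop2)
})

test_that("fixture templates and allocations are as documented", {
  fx <- mvc_fixture("single_base_pair", rng_seed = 3L)
  gt <- fx$ground_truth
  expect_equal(length(gt$templates$sequences), 2L)
  expect_equal(edit_distance(gt$templates$sequences[1L],
                             gt$templates$sequences[2L]), 1L)
  expect_equal(gt$templates$frequencies, c(0.5, 0.5))
  expect_equal(nrow(fx$reads), 1000L)
  # exactly equal allocation
  expect_equal(as.vector(table(gt$read_origins)), c(500L, 500L))

  fx2 <- mvc_fixture("low_error", rng_seed = 3L)
  expect_equal(length(fx2$ground_truth$templates$sequences), 20L)
  expect_equal(nrow(fx2$reads), 2000L)
  expect_equal(unname(tabulate(fx2$ground_truth$read_origins)),
               rep(100L, 20L))
  # low-error regime really has an appreciable error-free fraction
  expect_gt(error_free_fraction(fx2$reads), 0.2)
})

test_that("fixtures are pure functions of their seed", {
  a <- mvc_fixture("low_error", rng_seed = 4L)
  b <- mvc_fixture("low_error", rng_seed = 4L)
  expect_identical(a$reads$sequence, b$reads$sequence)
  expect_identical(a$ground_truth$read_origins, b$ground_truth$read_origins)
})
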