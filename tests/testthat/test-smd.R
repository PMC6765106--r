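test_that("edit_distance agrees with the adist oracle on random pairs", {
  set.seed(13)
  for (rep in 1:100) {
    a <- random_dna(sample(5:120, 1L))
    b <- random_dna(sample(5:120, 1L))
    expect_equal(edit_distance(a, b),
                 as.integer(adist(a, b)))
  }
})

test_that("edit_distance handles identity, empties and single edits", {
  expect_equal(edit_distance("ACGT", "ACGT"), 0L)
  expect_equal(edit_distance("", ""), 0L)
  expect_equal(edit_distance("ACGT", ""), 4L)
  expect_equal(edit_distance("", "ACGT"), 4L)
  expect_equal(edit_distance("ACGT", "AGGT"), 1L)     # substitution
  expect_equal(edit_distance("ACGT", "ACGGT"), 1L)    # insertion
  expect_equal(edit_distance("ACGT", "AGT"), 1L)      # deletion
})

test_that("edit_distance banding is exact for long diverged pairs", {
  set.seed(29)
  s <- random_dna(1500L)
  # scatter 40 substitutions plus a 4-base deletion
  t <- s
  for (p in round(seq(10, 1490, length.out = 40))) t <- sub_at(t, p)
  t <- paste0(substr(t, 1, 700), substr(t, 705, 1500))
  expect_equal(edit_distance(s, t), as.integer(adist(s, t)))
})

test_that("edit_distance_matrix matches elementwise edit_distance", {
  set.seed(31)
  a <- replicate(4, random_dna(60L))
  b <- replicate(3, random_dna(55L))
  M <- edit_distance_matrix(a, b)
  expect_equal(dim(M), c(4L, 3L))
  for (i in 1:4) for (j in 1:3) {
    expect_equal(M[i, j], edit_distance(a[i], b[j]))
  }
})

test_that("weighted_population validates frequencies strictly", {
  expect_error(weighted_population(character(0), numeric(0)), "non-empty")
  expect_error(weighted_population("A", -1), "non-negative")
  expect_error(weighted_population(c("A", "C"), c(0.5, 0.6)), "sum to 1")
  p <- weighted_population(c("A", "C"), c(0.5, 0.5))
  expect_s3_class(p, "weighted_population")
})

test_that("transport solver matches the dense simplex oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:6, 1L); m <- sample(2:6, 1L)
    D <- matrix(sample(0:20, n * m, replace = TRUE), n, m)
    supply <- as.vector(rmultinom(1, 100, rep(1, n))) / 100
    demand <- as.vector(rmultinom(1, 100, rep(1, m))) / 100
    # keep both marginals strictly positive
    supply <- (supply + 0.01) / sum(supply + 0.01)
    demand <- (demand + 0.01) / sum(demand + 0.01)
    f <- ampdenoise:::solve_transport(D, supply, demand)
    expect_equal(f$cost, oracle_transport_cost(D, supply, demand),
                 tolerance = 1e-9)
  }
})

test_that("transport flow satisfies both marginals and prices the cost", {
  set.seed(57)
  D <- matrix(runif(12, 0, 5), 3, 4)
  supply <- c(0.2, 0.3, 0.5)
  demand <- c(0.1, 0.2, 0.3, 0.4)
  f <- ampdenoise:::solve_transport(D, supply, demand)
  expect_true(all(f$flow >= -1e-12))
  expect_equal(rowSums(f$flow), supply, tolerance = 1e-9)
  expect_equal(colSums(f$flow), demand, tolerance = 1e-9)
  expect_equal(sum(f$flow * D), f$cost, tolerance = 1e-9)
})

test_that("smd is zero iff the populations are identical", {
  p <- weighted_population(c("ACGTACGT", "TTTTCCCC"), c(0.4, 0.6))
  expect_equal(smd(p, p)$smd, 0)
  q <- weighted_population(c("ACGTACGT", "TTTTCCCC"), c(0.6, 0.4))
  expect_gt(smd(p, q)$smd, 0)
})

test_that("smd matches hand-computed values on tiny populations", {
  # [DERIVED] 0.25 of the mass moves across a 1-edit gap
  a <- weighted_population(c("ACGTACGT", "ACGAACGT"), c(0.5, 0.5))
  b <- weighted_population(c("ACGTACGT", "ACGAACGT"), c(0.25, 0.75))
  r <- smd(a, b)
  expect_equal(r$smd, 0.25, tolerance = 1e-9)
  # a dropped true sequence costs its frequency times its distance
  c1 <- weighted_population("ACGTACGT", 1)
  expect_equal(smd(a, c1)$smd, 0.5, tolerance = 1e-9)
})

test_that("smd is symmetric and obeys the triangle inequality", {
  set.seed(77)
  pops <- replicate(3, {
    s <- replicate(3, random_dna(40L))
    f <- runif(3); weighted_population(s, f / sum(f))
  }, simplify = FALSE)
  d12 <- smd(pops[[1]], pops[[2]])$smd
  d21 <- smd(pops[[2]], pops[[1]])$smd
  expect_equal(d12, d21, tolerance = 1e-9)
  d13 <- smd(pops[[1]], pops[[3]])$smd
  d23 <- smd(pops[[2]], pops[[3]])$smd
  expect_lte(d13, d12 + d23 + 1e-9)
})

test_that("relaxed scores lower-bound smd and match the closed form", {
  set.seed(91)
  for (rep in 1:10) {
    a <- weighted_population(replicate(4, random_dna(30L)),
                             rep(0.25, 4))
    f <- runif(3)
    b <- weighted_population(replicate(3, random_dna(30L)), f / sum(f))
    full <- smd(a, b)
    rel <- smd_relaxed(a, b)
    expect_equal(rel$smd_fp, full$smd_fp)
    expect_equal(rel$smd_fn, full$smd_fn)
    expect_lte(rel$smd_fp, full$smd + 1e-9)
    expect_lte(rel$smd_fn, full$smd + 1e-9)
    # closed form recomputed independently from the D matrix
    expect_equal(rel$smd_fp,
                 sum(b$frequencies * apply(full$D, 2L, min)))
    expect_equal(rel$smd_fn,
                 sum(a$frequencies * apply(full$D, 1L, min)))
  }
})

test_that("smd flow result is internally consistent", {
  set.seed(99)
  a <- weighted_population(replicate(3, random_dna(25L)),
                           c(0.2, 0.3, 0.5))
  b <- weighted_population(replicate(4, random_dna(25L)),
                           c(0.1, 0.4, 0.3, 0.2))
  r <- smd(a, b)
  expect_equal(rowSums(r$F), a$frequencies, tolerance = 1e-9)
  expect_equal(colSums(r$F), b$frequencies, tolerance = 1e-9)
  expect_equal(sum(r$F * r$D), r$smd, tolerance = 1e-9)
})
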