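# Independent reference implementations used as oracles. These are kept
# deliberately naive (quadratic DP, dense simplex) so that agreement with
# the package's optimised code is meaningful.

DNA <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste0(sample(DNA, n, replace = TRUE), collapse = "")
}

# Substitute position `pos` of `s` with a base different from the current
# one (deterministic choice: first differing base in DNA order).
sub_at <- function(s, pos) {
  cur <- substr(s, pos, pos)
  repl <- setdiff(DNA, cur)[1L]
  paste0(substr(s, 1L, pos - 1L), repl, substr(s, pos + 1L, nchar(s)))
}

# O(n^2) longest strictly increasing subsequence (indices of one optimum).
ref_lis <- function(values) {
  n <- length(values)
  if (n == 0L) return(integer(0))
  best <- rep(1L, n)
  prev <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (values[j] < values[i] && best[j] + 1L > best[i]) {
        best[i] <- best[j] + 1L
        prev[i] <- j
      }
    }
  }
  end <- which.max(best)
  out <- integer(best[end])
  cur <- end
  for (s in rev(seq_along(out))) {
    out[s] <- cur
    cur <- prev[cur]
  }
  out
}

# Reference (list-growing) implementation of anchor block merging with the
# exact semantics documented for merge_anchor_blocks().
ref_merge_blocks <- function(anchors_d, anchors_r, sk) {
  blocks <- matrix(integer(0), ncol = 4L,
                   dimnames = list(NULL, c("ds", "de", "rs", "re")))
  for (a in seq_along(anchors_d)) {
    dp <- anchors_d[a]; rp <- anchors_r[a]
    if (nrow(blocks) > 0L) {
      prev <- blocks[nrow(blocks), ]
      same_diag <- (rp - dp) == (prev["rs"] - prev["ds"])
      if (dp <= prev["de"] || rp <= prev["re"]) {
        if (same_diag && dp > prev["ds"]) {
          blocks[nrow(blocks), "de"] <- dp + sk - 1L
          blocks[nrow(blocks), "re"] <- rp + sk - 1L
        }
        next
      }
    }
    blocks <- rbind(blocks, c(ds = dp, de = dp + sk - 1L,
                              rs = rp, re = rp + sk - 1L))
  }
  blocks
}

# Dense-simplex oracle for the transportation problem (boot::simplex).
# One redundant equality is dropped so the constraint matrix has full rank.
oracle_transport_cost <- function(D, supply, demand) {
  n <- length(supply); m <- length(demand)
  cons <- rbind(
    t(sapply(seq_len(n), function(i) {
      z <- matrix(0, n, m); z[i, ] <- 1; as.vector(z)
    })),
    t(sapply(seq_len(m), function(j) {
      z <- matrix(0, n, m); z[, j] <- 1; as.vector(z)
    }))
  )
  rhs <- c(supply, demand)
  cons <- cons[-(n + m), , drop = FALSE]
  rhs <- rhs[-(n + m)]
  res <- boot::simplex(a = as.vector(D), A3 = cons, b3 = rhs, maxi = FALSE)
  unname(res$value)
}

# A template pair one substitution apart with a repeat-free context window
# around the variant site, so the substitution-signal kmers survive the
# homopolymer filters of top_variance_kmers().
clean_snp_pair <- function(len = 400L, k = 6L, seed = 1L) {
  set.seed(seed)
  repeat {
    s <- random_dna(len)
    cx <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (pos in seq(2L * k, len - 2L * k)) {
      win <- cx[(pos - k):(pos + k)]
      if (any(win[-1L] == win[-length(win)])) next
      repl <- setdiff(DNA, c(cx[pos - 1L], cx[pos], cx[pos + 1L]))[1L]
      s2 <- paste0(substr(s, 1L, pos - 1L), repl,
                   substr(s, pos + 1L, len))
      return(list(a = s, b = s2, pos = pos))
    }
  }
}
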