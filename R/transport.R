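# Exact solver for the dense transportation problem
#   min sum_ij F_ij D_ij   s.t.  rowSums(F) = supply, colSums(F) = demand, F >= 0
# via successive shortest augmenting paths with node potentials (a special
# case of min-cost flow where every supply->demand arc exists and has
# unlimited capacity). All arc costs are non-negative, so plain Dijkstra
# works from the first augmentation onward.
solve_transport <- function(cost, supply, demand, tol = 1e-12) {
  n <- length(supply); m <- length(demand)
  stopifnot(nrow(cost) == n, ncol(cost) == m,
            all(supply >= 0), all(demand >= 0))
  if (abs(sum(supply) - sum(demand)) > 1e-6) {
    stop("total supply and demand differ beyond tolerance")
  }
  demand <- demand * (sum(supply) / sum(demand))  # make marginals match exactly

  FF <- matrix(0, n, m)
  ra <- supply; rb <- demand
  pa <- numeric(n); pb <- numeric(m)              # node potentials
  max_aug <- 20L * (n + m) + 1000L
  aug <- 0L
  while (sum(ra) > tol && aug < max_aug) {
    aug <- aug + 1L
    # Dijkstra over the bipartite residual graph
    da <- ifelse(ra > tol, 0, Inf); db <- rep(Inf, m)
    doneA <- rep(FALSE, n); doneB <- rep(FALSE, m)
    prevB <- integer(m); prevA <- integer(n)      # 0 = source
    repeat {
      ia <- if (any(!doneA)) which(!doneA)[which.min(da[!doneA])] else NA
      ib <- if (any(!doneB)) which(!doneB)[which.min(db[!doneB])] else NA
      va <- if (is.na(ia)) Inf else da[ia]
      vb <- if (is.na(ib)) Inf else db[ib]
      if (is.infinite(va) && is.infinite(vb)) break
      if (va <= vb) {
        doneA[ia] <- TRUE
        cand <- da[ia] + cost[ia, ] + pa[ia] - pb  # forward arcs ia -> all B
        upd <- !doneB & cand < db - 1e-15
        if (any(upd)) { db[upd] <- cand[upd]; prevB[upd] <- ia }
      } else {
        doneB[ib] <- TRUE
        has_back <- FF[, ib] > tol
        if (any(has_back)) {                      # backward arcs ib -> A
          cand <- db[ib] - cost[, ib] + pb[ib] - pa
          upd <- has_back & !doneA & cand < da - 1e-15
          if (any(upd)) { da[upd] <- cand[upd]; prevA[upd] <- ib }
        }
      }
    }
    t_opts <- which(rb > tol & is.finite(db))
    if (length(t_opts) == 0L) stop("transportation problem is infeasible")
    tgt <- t_opts[which.min(db[t_opts])]

    # recover augmenting path source -> ... -> tgt
    pathA <- integer(0); pathB <- integer(0)
    j <- tgt
    repeat {
      i <- prevB[j]
      pathB <- c(j, pathB); pathA <- c(i, pathA)
      if (prevA[i] == 0L) break                   # node fed from the source
      j <- prevA[i]
    }
    start <- pathA[1L]
    delta <- min(ra[start], rb[tgt])
    if (length(pathB) > 1L) {
      # backward arcs used: B[pathB[s]] -> A[pathA[s+1]] carries flow
      for (s in seq_len(length(pathB) - 1L)) {
        delta <- min(delta, FF[pathA[s + 1L], pathB[s]])
      }
    }
    for (s in seq_along(pathB)) {
      FF[pathA[s], pathB[s]] <- FF[pathA[s], pathB[s]] + delta
      if (s < length(pathB)) {
        FF[pathA[s + 1L], pathB[s]] <- FF[pathA[s + 1L], pathB[s]] - delta
      }
    }
    ra[start] <- ra[start] - delta
    rb[tgt] <- rb[tgt] - delta
    ra[ra < tol] <- 0; rb[rb < tol] <- 0
    FF[FF < tol] <- 0

    # potential update keeps all residual reduced costs non-negative
    dcap <- db[tgt]
    pa <- pa + pmin(da, dcap)
    pb <- pb + pmin(db, dcap)
  }
  if (sum(ra) > 1e-8) stop("transport solver failed to ship all supply")
  list(flow = FF, cost = sum(FF * cost))
}
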