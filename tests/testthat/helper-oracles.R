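# Independent brute-force oracles. Each reimplements a quantity from its
# definition, by enumeration where feasible, and must stay independent of
# the package code paths it checks.

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins (point-probability rule; the 1e-7
# relative fudge guards float classification of exact ties).
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  lo <- max(0, k - m2)
  hi <- min(k, m1)
  probs <- dhyper(lo:hi, m1, m2, k)
  p_obs <- dhyper(a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Naive Ward agglomeration on a precomputed dissimilarity matrix via the
# explicit Lance-Williams recurrence (distances, squared inside the
# update). Returns the merge sequence as (label_a, label_b, height) with
# labels the original point names of any cluster member-minimum.
oracle_ward <- function(D) {
  n <- nrow(D)
  labels <- rownames(D) %||% as.character(seq_len(n))
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  idx <- seq_len(n)
  d <- D
  merges <- list()
  while (length(idx) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(idx)[-length(idx)]) {
      for (j in seq((i + 1), length(idx))) {
        v <- d[idx[i], idx[j]]
        if (v < best[1]) best <- c(v, idx[i], idx[j])
      }
    }
    a <- best[2]; b <- best[3]
    for (m in setdiff(idx, c(a, b))) {
      ni <- sizes[a]; nj <- sizes[b]; nk <- sizes[m]
      dn <- sqrt(((ni + nk) * d[a, m]^2 + (nj + nk) * d[b, m]^2 -
                    nk * d[a, b]^2) / (ni + nj + nk))
      d[a, m] <- dn; d[m, a] <- dn
    }
    merges[[length(merges) + 1]] <- list(
      members_a = sort(members[[a]]), members_b = sort(members[[b]]),
      height = best[1])
    members[[a]] <- c(members[[a]], members[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    idx <- setdiff(idx, b)
  }
  merges
}

# flatten an hclust object into the same member-set merge representation
hclust_merges <- function(h) {
  sets <- list()
  lapply(seq_len(nrow(h$merge)), function(i) {
    get_set <- function(v) if (v < 0) -v else sets[[v]]
    a <- get_set(h$merge[i, 1])
    b <- get_set(h$merge[i, 2])
    sets[[i]] <<- c(a, b)
    # order the pair canonically so comparison ignores left/right
    pa <- list(sort(a), sort(b))
    pa <- pa[order(vapply(pa, min, 0))]
    list(members_a = pa[[1]], members_b = pa[[2]], height = h$height[i])
  })
}

canon_merges <- function(ms) {
  lapply(ms, function(m) {
    pa <- list(m$members_a, m$members_b)
    pa <- pa[order(vapply(pa, min, 0))]
    list(members_a = pa[[1]], members_b = pa[[2]],
         height = round(m$height, 10))
  })
}

# Maximum-weight spanning tree weight by enumerating all |V|-1 edge
# subsets that form a spanning tree.
oracle_mst_weight <- function(edges, n_vertices) {
  stopifnot(nrow(edges) >= n_vertices - 1)
  combos <- utils::combn(nrow(edges), n_vertices - 1)
  best <- -Inf
  for (ci in seq_len(ncol(combos))) {
    sub <- edges[combos[, ci], ]
    g <- igraph::graph_from_data_frame(sub[c("from", "to")],
                                       directed = FALSE)
    if (igraph::vcount(g) == n_vertices && igraph::is_connected(g)) {
      best <- max(best, sum(sub$dice))
    }
  }
  best
}

# Weighted Newman modularity computed from its definition.
oracle_modularity <- function(edges, membership) {
  m2 <- 2 * sum(edges$w)
  deg <- tapply(c(edges$w, edges$w), c(edges$from, edges$to), sum)
  q <- 0
  for (i in seq_len(nrow(edges))) {
    if (membership[[edges$from[i]]] == membership[[edges$to[i]]]) {
      q <- q + 2 * edges$w[i] / m2
    }
  }
  for (comm in unique(membership)) {
    dc <- sum(deg[names(membership)[membership == comm]])
    q <- q - (dc / m2)^2
  }
  q
}

# All set partitions of 1..n (restricted-growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, next_id) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return(invisible())
    }
    for (g in seq_len(next_id)) {
      rec(c(assign, g), max(next_id, g + 1))
    }
  }
  rec(integer(0), 1)
  out
}
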