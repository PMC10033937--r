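# Independent brute-force oracles. These deliberately use naive loops and
# enumeration (never the package's matrix-product code paths) so that
# agreement is meaningful.

dense_adj <- function(g) as.matrix(adjacency_matrix(g, drop_self_loops = TRUE))

oracle_neighbors <- function(A, i) which(A[i, ] > 0)

# classical indices by direct set arithmetic
oracle_local_index <- function(A, i, j, index) {
  ni <- oracle_neighbors(A, i)
  nj <- oracle_neighbors(A, j)
  cn <- intersect(ni, nj)
  k <- rowSums(A)
  switch(index,
    CN = length(cn),
    RA = sum(1 / k[cn]),
    AA = sum(ifelse(k[cn] > 1, 1 / log(k[cn]), 0)),
    JC = if (length(union(ni, nj)) == 0) 0 else
      length(cn) / length(union(ni, nj)),
    PA = k[i] * k[j],
    CRA = if (length(cn) == 0) 0 else
      sum(vapply(cn, function(z) length(intersect(oracle_neighbors(A, z), cn)) / k[z],
                 1))
  )
}

# Katz by truncated power series (independent of the matrix-inverse route)
oracle_katz <- function(A, beta, i, j, L = 300) {
  Ap <- A
  s <- 0
  for (l in seq_len(L)) {
    s <- s + beta^l * Ap[i, j]
    Ap <- Ap %*% A
  }
  s
}

# L3 by explicit triple loop over intermediate nodes
oracle_l3 <- function(A, i, j, normalized = TRUE) {
  k <- rowSums(A)
  s <- 0
  for (u in oracle_neighbors(A, i)) {
    for (v in oracle_neighbors(A, j)) {
      if (A[u, v] > 0) {
        s <- s + if (normalized) 1 / sqrt(k[u] * k[v]) else 1
      }
    }
  }
  s
}

# ----- ranking metrics recomputed naively -----------------------------------

oracle_auroc <- function(scores, rel) {
  pos <- scores[rel == 1]
  neg <- scores[rel == 0]
  if (length(neg) == 0) return(1)
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

oracle_ap <- function(rel) {
  hits <- 0
  s <- 0
  for (i in seq_along(rel)) {
    if (rel[i] == 1) {
      hits <- hits + 1
      s <- s + hits / i
    }
  }
  s / sum(rel)
}

oracle_ndcg <- function(rel) {
  dcg <- sum(rel / log2(seq_along(rel) + 1))
  ideal <- sort(rel, decreasing = TRUE)
  dcg / sum(ideal / log2(seq_along(rel) + 1))
}

oracle_p_at_k <- function(rel, k) sum(rel[seq_len(min(k, length(rel)))]) / k

# ----- exhaustive SBM oracle ------------------------------------------------

# all set partitions of n elements as membership vectors
partitions_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in partitions_of(n - 1)) {
    for (gnew in seq_len(max(p) + 1)) out[[length(out) + 1L]] <- c(p, gnew)
  }
  out
}

sbm_partition_energy <- function(sigma, A) {
  gs <- sort(unique(sigma))
  sizes <- tabulate(sigma)
  H <- 0
  for (ri in seq_along(gs)) {
    for (si in ri:length(gs)) {
      r <- gs[ri]; s <- gs[si]
      if (r == s) {
        poss <- sizes[r] * (sizes[r] - 1) / 2
        l <- sum(A[sigma == r, sigma == r]) / 2
      } else {
        poss <- sizes[r] * sizes[s]
        l <- sum(A[sigma == r, sigma == s])
      }
      H <- H + log(poss + 1) + lchoose(poss, l)
    }
  }
  H
}

sbm_exact_reliability <- function(A, ia, ib) {
  ps <- partitions_of(nrow(A))
  w <- vapply(ps, function(p) exp(-sbm_partition_energy(p, A)), 1)
  w <- w / sum(w)
  vapply(seq_along(ia), function(t) {
    sum(w * vapply(ps, function(p) {
      sizes <- tabulate(p)
      r <- p[ia[t]]; s <- p[ib[t]]
      if (r == s) {
        poss <- sizes[r] * (sizes[r] - 1) / 2
        l <- sum(A[p == r, p == r]) / 2
      } else {
        poss <- sizes[r] * sizes[s]
        l <- sum(A[p == r, p == s])
      }
      (l + 1) / (poss + 2)
    }, 1))
  }, 1)
}

# ----- misc -----------------------------------------------------------------

# all-pairs shortest paths by hand-rolled BFS
oracle_bfs_distances <- function(g) {
  A <- dense_adj(g)
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, oracle_neighbors, A = A)))
      nxt <- nxt[!is.finite(D[s, nxt])]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

score_lookup <- function(st, a, b) {
  key <- paste(pmin(a, b), pmax(a, b), sep = "\t")
  st$score[match(key, paste(st$node_a, st$node_b, sep = "\t"))]
}
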