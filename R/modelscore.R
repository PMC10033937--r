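# Probabilistic, factorization and diffusion scorers: stochastic block model
# link reliability via Metropolis sampling over node partitions, latent-space
# embeddings (NNMF and two Laplacian eigenmap variants) scored by cosine
# similarity, and the diffusion trio ACT / RWR / SimRank.

# --- stochastic block model ------------------------------------------------

# Energy of a partition under the microcanonical SBM with no prior on the
# number of groups: H(P) = sum_{r<=s} [ ln(r_rs + 1) + ln C(r_rs, l_rs) ],
# where l_rs counts observed and r_rs possible links between groups r,s.
sbm_possible_links <- function(sizes, r, s) {
  ifelse(r == s, sizes[r] * (sizes[r] - 1) / 2, sizes[r] * sizes[s])
}

# Sum of the energy terms of all block pairs involving group r.
sbm_row_energy <- function(l, sizes, r) {
  poss <- sizes[r] * sizes
  poss[r] <- sizes[r] * (sizes[r] - 1) / 2
  sum(log(poss + 1) + lchoose(poss, l[r, ]))
}

sbm_pair_energy <- function(l, sizes, r, s) {
  poss <- sbm_possible_links(sizes, r, s)
  log(poss + 1) + lchoose(poss, ifelse(r == s, l[r, r], l[r, s]))
}

#' Stochastic block model link reliability
#'
#' Estimates, for each candidate pair, the posterior probability that the
#' link exists under the stochastic block model: nodes are partitioned into
#' groups and the connection probability between two nodes depends only on
#' their groups. The reliability
#' `R_ij = < (l_{σi σj} + 1) / (r_{σi σj} + 2) >` is averaged over partitions
#' sampled by a Metropolis chain with energy
#' `H(P) = Σ_{r<=s} [ln(r_rs + 1) + ln C(r_rs, l_rs)]`, single-node group
#' moves, and acceptance `min(1, exp(-ΔH))`. The group count is free: moves
#' may create or empty groups.
#'
#' @param g an [interactome] (self-loops are ignored).
#' @param pairs candidate node pairs.
#' @param n_samples number of recorded partition samples (> 0).
#' @param burn_in discarded initial Metropolis steps.
#' @param thin steps between recorded samples.
#' @param seed integer RNG seed.
#' @return A [score_table] with scores in (0,1).
#' @export
sbm_reliability_scores <- function(g, pairs, n_samples = 2000,
                                   burn_in = 2000, thin = 10, seed = 1) {
  if (n_samples < 1) stop("n_samples must be positive")
  rp <- resolve_pairs(g, pairs, allow_self = FALSE)
  A <- adjacency_matrix(g, drop_self_loops = TRUE)
  n <- nrow(A)
  nbr <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  sigma <- seq_len(n)            # start from the all-singletons partition
  sizes <- rep(1L, n)
  l <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (w in nbr[[i]]) if (i < w) {
      l[sigma[i], sigma[w]] <- l[sigma[i], sigma[w]] + 1
      l[sigma[w], sigma[i]] <- l[sigma[w], sigma[i]] + 1
    }
  }
  diag(l) <- diag(l) / 2         # within-group edges counted once
  # (initially zero anyway under singletons, kept for clarity)

  move <- function(i, a, b, cnt) {
    l[a, ] <<- l[a, ] - cnt
    l[, a] <<- l[, a] - cnt
    l[a, a] <<- l[a, a] + cnt[a]
    l[b, ] <<- l[b, ] + cnt
    l[, b] <<- l[, b] + cnt
    l[b, b] <<- l[b, b] - cnt[b]
    sizes[a] <<- sizes[a] - 1L
    sizes[b] <<- sizes[b] + 1L
    sigma[i] <<- b
  }

  acc <- numeric(length(rp$ia))
  with_seed(seed, {
    total <- burn_in + n_samples * thin
    next_record <- burn_in + thin
    recorded <- 0L
    for (step in seq_len(total)) {
      i <- sample.int(n, 1L)
      a <- sigma[i]
      b <- sample.int(n, 1L)
      if (b != a) {
        cnt <- tabulate(sigma[nbr[[i]]], nbins = n)
        # the chain runs over group-label assignments; a partition with k
        # blocks has n!/(n-k)! labelings, so moves that change the block
        # count carry a multiplicity correction to target set partitions
        k_groups <- sum(sizes > 0L)
        dk <- (sizes[b] == 0L) - (sizes[a] == 1L)
        log_mult <- if (dk == 1L) -log(n - k_groups) else
          if (dk == -1L) log(n - k_groups + 1) else 0
        h_old <- sbm_row_energy(l, sizes, a) + sbm_row_energy(l, sizes, b) -
          sbm_pair_energy(l, sizes, a, b)
        move(i, a, b, cnt)
        h_new <- sbm_row_energy(l, sizes, a) + sbm_row_energy(l, sizes, b) -
          sbm_pair_energy(l, sizes, a, b)
        log_acc <- h_old - h_new + log_mult
        if (log_acc < 0 && stats::runif(1L) >= exp(log_acc)) {
          cnt_back <- tabulate(sigma[nbr[[i]]], nbins = n)
          move(i, b, a, cnt_back)
        }
      }
      if (step == next_record) {
        r <- sigma[rp$ia]
        s <- sigma[rp$ib]
        same <- r == s
        poss <- ifelse(same, sizes[r] * (sizes[r] - 1) / 2,
                       sizes[r] * sizes[s])
        lrs <- l[cbind(r, s)]
        acc <- acc + (lrs + 1) / (poss + 2)
        recorded <- recorded + 1L
        next_record <- next_record + thin
      }
    }
  })
  score_table(rp$pairs, acc / n_samples,
              method = sprintf("SBM(samples=%d)", n_samples), graph = g$name)
}

# --- latent-space embeddings ----------------------------------------------

cosine_pair_scores <- function(U, ia, ib) {
  num <- rowSums(U[ia, , drop = FALSE] * U[ib, , drop = FALSE])
  den <- sqrt(rowSums(U[ia, , drop = FALSE]^2) *
              rowSums(U[ib, , drop = FALSE]^2))
  ifelse(den > 0, num / den, 0)
}

nnmf_factorize <- function(A, d, n_iter, seed) {
  n <- nrow(A)
  eps <- 1e-10
  with_seed(seed, {
    W <- matrix(stats::runif(n * d), n, d)
    H <- matrix(stats::runif(d * n), d, n)
    for (it in seq_len(n_iter)) {
      H <- H * (crossprod(W, A)) / (crossprod(W) %*% H + eps)
      W <- W * (A %*% t(H)) / (W %*% tcrossprod(H) + eps)
    }
    (W + t(H)) / 2
  })
}

laplacian_embedding <- function(A, d, normalized) {
  n <- nrow(A)
  k <- rowSums(A)
  if (normalized) {
    w <- ifelse(k > 0, 1 / sqrt(k), 0)
    L <- diag(n) - (w * A) * rep(w, each = n)
  } else {
    L <- diag(k) - A
  }
  eig <- eigen(L, symmetric = TRUE)
  ord <- order(eig$values)              # ascending
  vals <- eig$values[ord]
  tol <- 1e-8 * max(1, abs(vals[n]))
  nonzero <- which(vals > tol)
  if (length(nonzero) < d) {
    stop("graph has fewer than d informative Laplacian modes")
  }
  eig$vectors[, ord[nonzero[seq_len(d)]], drop = FALSE]
}

#' Latent-feature link scores from matrix factorization embeddings
#'
#' Learns a `d`-dimensional representation of every node and scores a pair
#' by the cosine similarity of the endpoint vectors.
#' \describe{
#'   \item{nnmf}{nonnegative factorization `A ≈ WH` by multiplicative
#'     updates; a node's vector averages its row of `W` and column of `H`,
#'     so scores lie in [0,1].}
#'   \item{glee}{coordinates from the `d` eigenvectors of the unnormalized
#'     Laplacian `L = D - A` with smallest nonzero eigenvalues.}
#'   \item{spc}{same, for the symmetric normalized Laplacian
#'     `I - D^{-1/2} A D^{-1/2}`.}
#' }
#' Zero embedding vectors score 0 by convention. The seed affects only the
#' NNMF initialization.
#'
#' @param g an [interactome].
#' @param pairs candidate node pairs.
#' @param method `"nnmf"`, `"glee"` or `"spc"`.
#' @param d embedding dimension (< number of nodes).
#' @param seed integer RNG seed (NNMF only).
#' @param n_iter multiplicative-update iterations (NNMF only).
#' @return A [score_table] with cosine scores in [-1,1].
#' @export
embedding_scores <- function(g, pairs, method = c("nnmf", "glee", "spc"),
                             d = 16, seed = 1, n_iter = 500) {
  method <- match.arg(method)
  rp <- resolve_pairs(g, pairs, allow_self = FALSE)
  A <- as.matrix(adjacency_matrix(g, drop_self_loops = TRUE))
  n <- nrow(A)
  if (d >= n) stop("embedding dimension d must be smaller than the node count")
  U <- switch(method,
    nnmf = nnmf_factorize(A, d, n_iter, seed),
    glee = laplacian_embedding(A, d, normalized = FALSE),
    spc = laplacian_embedding(A, d, normalized = TRUE)
  )
  score_table(rp$pairs, cosine_pair_scores(U, rp$ia, rp$ib),
              method = sprintf("%s(d=%d)", toupper(method), d),
              graph = g$name)
}

# --- diffusion scorers -----------------------------------------------------

#' Average commute time (ACT) scores
#'
#' The commute time between two nodes — the expected number of steps for a
#' random walker to travel there and back — is `CT(i,j) = 2m R_eff(i,j)`,
#' where `R_eff` is the effective resistance obtained from the Moore-Penrose
#' pseudoinverse of the graph Laplacian:
#' `R_eff = L+_ii + L+_jj - 2 L+_ij`. Pairs are scored by `1/CT`; endpoints
#' in different components have infinite commute time and score 0 by
#' convention.
#'
#' @param g an [interactome].
#' @param pairs candidate node pairs.
#' @return A [score_table].
#' @export
act_scores <- function(g, pairs) {
  rp <- resolve_pairs(g, pairs, allow_self = FALSE)
  A <- adjacency_matrix(g, drop_self_loops = TRUE)
  n <- nrow(A)
  m <- sum(A) / 2
  comp <- igraph::components(as_igraph(g))$membership[g$nodes]
  s <- numeric(length(rp$ia))
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) < 2L) next
    sel <- which(comp[rp$ia] == cid & comp[rp$ib] == cid)
    if (length(sel) == 0L) next
    Ac <- as.matrix(A[members, members, drop = FALSE])
    L <- diag(rowSums(Ac)) - Ac
    Lp <- MASS::ginv(L)
    li <- match(rp$ia[sel], members)
    lj <- match(rp$ib[sel], members)
    reff <- diag(Lp)[li] + diag(Lp)[lj] - 2 * Lp[cbind(li, lj)]
    s[sel] <- 1 / (2 * m * reff)
  }
  score_table(rp$pairs, s, method = "ACT", graph = g$name)
}

#' Random walk with restart (RWR) scores
#'
#' For each source `i`, iterates the walker distribution
#' `q <- (1 - restart) * P q + restart * e_i` (with `P` the column-stochastic
#' transition matrix `A D^{-1}`; walkers stranded on degree-0 nodes teleport
#' back to the source) until the maximum change falls below `tol`. The pair
#' score is the symmetrized visiting probability `q_i(j) + q_j(i)`.
#'
#' @param g an [interactome].
#' @param pairs candidate node pairs.
#' @param restart restart probability in (0, 1].
#' @param tol convergence tolerance on the stationary distribution.
#' @param max_iter iteration cap.
#' @return A [score_table].
#' @export
rwr_scores <- function(g, pairs, restart = 0.15, tol = 1e-8,
                       max_iter = 10000) {
  if (restart <= 0 || restart > 1) stop("restart must lie in (0, 1]")
  rp <- resolve_pairs(g, pairs, allow_self = FALSE)
  A <- adjacency_matrix(g, drop_self_loops = TRUE)
  n <- nrow(A)
  k <- Matrix::colSums(A)
  inv_k <- ifelse(k > 0, 1 / k, 0)
  P <- A %*% Matrix::Diagonal(x = inv_k)
  dangling <- which(k == 0)
  src <- sort(unique(c(rp$ia, rp$ib)))
  E <- matrix(0, n, length(src))
  E[cbind(src, seq_along(src))] <- 1
  Q <- E
  for (it in seq_len(max_iter)) {
    leak <- if (length(dangling) > 0L) {
      colSums(Q[dangling, , drop = FALSE])
    } else 0
    Qn <- as.matrix((1 - restart) * (P %*% Q)) +
      (1 - restart) * E * rep(leak, each = n) + restart * E
    if (max(abs(Qn - Q)) < tol) { Q <- Qn; break }
    Q <- Qn
  }
  col_of <- match(seq_len(n), src)
  s <- Q[cbind(rp$ib, col_of[rp$ia])] + Q[cbind(rp$ia, col_of[rp$ib])]
  score_table(rp$pairs, s, method = sprintf("RWR(restart=%.2f)", restart),
              graph = g$name)
}

#' SimRank structural-context similarity
#'
#' Fixed-point iteration of `s(i,j) = c/(k_i k_j) Σ_{u∈Γ(i)} Σ_{v∈Γ(j)}
#' s(u,v)` with `s(i,i) = 1`, starting from the identity. Nodes of degree 0
#' score 0 against every other node.
#'
#' @param g an [interactome].
#' @param pairs candidate node pairs (self-pairs allowed; they score 1).
#' @param c_decay decay constant in (0, 1).
#' @param max_iter iteration cap.
#' @param tol convergence tolerance (max elementwise change).
#' @return A [score_table] with scores in [0,1].
#' @export
simrank_scores <- function(g, pairs, c_decay = 0.8, max_iter = 1000,
                           tol = 1e-6) {
  if (c_decay <= 0 || c_decay >= 1) stop("c_decay must lie in (0, 1)")
  rp <- resolve_pairs(g, pairs, allow_self = TRUE)
  A <- as.matrix(adjacency_matrix(g, drop_self_loops = TRUE))
  n <- nrow(A)
  k <- rowSums(A)
  P <- A * ifelse(k > 0, 1 / k, 0)   # row-stochastic where defined
  S <- diag(n)
  for (it in seq_len(max_iter)) {
    Sn <- c_decay * (P %*% S %*% t(P))
    diag(Sn) <- 1
    if (max(abs(Sn - S)) < tol) { S <- Sn; break }
    S <- Sn
  }
  score_table(rp$pairs, S[cbind(rp$ia, rp$ib)],
              method = sprintf("SimRank(c=%.2f)", c_decay), graph = g$name)
}
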