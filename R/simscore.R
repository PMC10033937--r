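# Similarity-based link scorers: the classical local indices, the Katz
# index, and the L3 family (degree-normalized length-3 path counts). All
# scorers operate on the simple graph (self-loops dropped) and never score
# self-pairs; the candidate-universe policy lives in the evaluation harness.

#' Construct a score table
#'
#' A `score_table` maps canonical candidate node pairs to real-valued link
#' scores. It is a plain data frame with columns `node_a`, `node_b`, `score`
#' plus metadata attributes (`method_name`, `graph_name`, `surrogate`).
#'
#' @param pairs two-column matrix of node labels (canonicalized).
#' @param score numeric vector of finite scores.
#' @param method method name.
#' @param graph source graph name.
#' @param surrogate flag marking scores produced by a documented surrogate
#'   of a method whose exact published composition is unavailable.
#' @return A `score_table`.
#' @export
score_table <- function(pairs, score, method = "score", graph = "graph",
                        surrogate = FALSE) {
  pairs <- canonicalize_pairs(pairs)
  stopifnot(length(score) == nrow(pairs))
  if (any(!is.finite(score))) stop("scores must be finite")
  out <- data.frame(node_a = pairs[, 1L], node_b = pairs[, 2L],
                    score = as.numeric(score), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "method_name") <- method
  attr(out, "graph_name") <- graph
  attr(out, "surrogate") <- surrogate
  class(out) <- c("score_table", "data.frame")
  out
}

score_keys <- function(scores) pair_key(scores$node_a, scores$node_b)

#' Classical local similarity indices
#'
#' Scores candidate pairs with one of the common-neighborhood indices:
#' \describe{
#'   \item{CN}{number of common neighbors, `|Γ(i) ∩ Γ(j)|`.}
#'   \item{RA}{resource allocation, `Σ_z 1/k_z` over common neighbors `z`.}
#'   \item{AA}{Adamic-Adar, `Σ_z 1/ln k_z` over common neighbors (a common
#'     neighbor of a non-self pair necessarily has degree >= 2, so the
#'     logarithm never vanishes).}
#'   \item{JC}{Jaccard index `|Γ(i) ∩ Γ(j)| / |Γ(i) ∪ Γ(j)|` (0 when both
#'     neighborhoods are empty).}
#'   \item{PA}{preferential attachment, the degree product `k_i k_j`.}
#'   \item{CRA}{CAR-based resource allocation, `Σ_z |γ(z)|/k_z` where
#'     `γ(z)` is the set of common neighbors adjacent to `z` (links internal
#'     to the common neighborhood).}
#' }
#'
#' @param g an [interactome].
#' @param pairs two-column matrix of candidate node pairs (no self-pairs).
#' @param index one of `"CN"`, `"RA"`, `"AA"`, `"JC"`, `"PA"`, `"CRA"`.
#' @return A [score_table].
#' @export
local_similarity_scores <- function(g, pairs,
                                    index = c("CN", "RA", "AA", "JC",
                                              "PA", "CRA")) {
  index <- match.arg(toupper(index[1L]), c("CN", "RA", "AA", "JC", "PA",
                                           "CRA"))
  rp <- resolve_pairs(g, pairs, allow_self = FALSE)
  A <- adjacency_matrix(g, drop_self_loops = TRUE)
  k <- Matrix::rowSums(A)
  ia <- rp$ia; ib <- rp$ib
  idx <- cbind(ia, ib)
  s <- switch(index,
    CN = as.numeric((A %*% A)[idx]),
    RA = {
      w <- ifelse(k > 0, 1 / k, 0)
      as.numeric((A %*% (w * A))[idx])
    },
    AA = {
      w <- ifelse(k > 1, 1 / log(k), 0)
      as.numeric((A %*% (w * A))[idx])
    },
    JC = {
      cn <- as.numeric((A %*% A)[idx])
      un <- k[ia] + k[ib] - cn
      ifelse(un > 0, cn / un, 0)
    },
    PA = k[ia] * k[ib],
    CRA = cra_scores_impl(A, k, ia, ib)
  )
  score_table(rp$pairs, s, method = index, graph = g$name)
}

cra_scores_impl <- function(A, k, ia, ib) {
  n <- nrow(A)
  nbr <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  vapply(seq_along(ia), function(t) {
    cn <- intersect(nbr[[ia[t]]], nbr[[ib[t]]])
    if (length(cn) == 0L) return(0)
    sub <- A[cn, cn, drop = FALSE]
    gamma <- Matrix::rowSums(sub)
    sum(gamma / k[cn])
  }, numeric(1))
}

#' Katz index
#'
#' Scores a pair by the damped count of walks of every length between its
#' endpoints: `((I - βA)^{-1} - I)_{ij} = Σ_{l>=1} β^l (#walks of length l)`.
#' The series converges iff `β < 1/λ_max(A)`; the default
#' `β = 0.5/λ_max(A)` guarantees convergence on any graph.
#'
#' @param g an [interactome].
#' @param pairs candidate node pairs.
#' @param beta damping factor; `NULL` selects `0.5/λ_max`.
#' @return A [score_table].
#' @export
katz_scores <- function(g, pairs, beta = NULL) {
  rp <- resolve_pairs(g, pairs, allow_self = FALSE)
  A <- as.matrix(adjacency_matrix(g, drop_self_loops = TRUE))
  n <- nrow(A)
  lam <- if (n > 0) max(abs(eigen(A, symmetric = TRUE,
                                  only.values = TRUE)$values)) else 0
  if (is.null(beta)) beta <- if (lam > 0) 0.5 / lam else 0.1
  if (lam > 0 && beta >= 1 / lam) stop("Katz series divergent: beta >= 1/lambda_max")
  if (beta <= 0) stop("beta must be positive")
  K <- solve(diag(n) - beta * A) - diag(n)
  score_table(rp$pairs, K[cbind(rp$ia, rp$ib)],
              method = sprintf("Katz(beta=%.4g)", beta), graph = g$name)
}

#' L3: degree-normalized paths of length three
#'
#' The L3 principle holds that two proteins are likely to interact when they
#' are joined by many paths of length three — complementary rather than
#' similar interfaces. The normalized score is
#' `L3(i,j) = Σ_{k,l} A_ik A_kl A_lj / sqrt(k_k k_l)`; the unnormalized
#' variant is the raw walk count `(A³)_{ij}`. For non-adjacent candidate
#' pairs the length-3 walk count equals the path count (degenerate walks
#' would require the `i-j` edge itself).
#'
#' @param g an [interactome].
#' @param pairs candidate node pairs.
#' @param normalized use the degree-normalized form (default `TRUE`).
#' @return A [score_table].
#' @export
l3_scores <- function(g, pairs, normalized = TRUE) {
  rp <- resolve_pairs(g, pairs, allow_self = FALSE)
  A <- adjacency_matrix(g, drop_self_loops = TRUE)
  if (normalized) {
    k <- Matrix::rowSums(A)
    w <- ifelse(k > 0, 1 / sqrt(k), 0)
    B <- (w * A) %*% Matrix::Diagonal(x = w)
    M <- A %*% B %*% A
  } else {
    M <- A %*% A %*% A
  }
  score_table(rp$pairs, as.numeric(M[cbind(rp$ia, rp$ib)]),
              method = if (normalized) "L3" else "L3_raw", graph = g$name)
}

#' SIM: L3 combined with the Jaccard index
#'
#' A composite similarity integrating the degree-normalized L3 score with
#' the Jaccard index of the two neighborhoods. The composition used here is
#' the multiplicative bonus `SIM(i,j) = L3(i,j) * (1 + JC(i,j))`, so
#' `SIM >= L3` with equality iff the pair shares no neighbors. The exact
#' published composition is not specified, hence the score table is flagged
#' as a surrogate.
#'
#' @param g an [interactome].
#' @param pairs candidate node pairs.
#' @return A [score_table] (`surrogate = TRUE`).
#' @export
sim_scores <- function(g, pairs) {
  l3 <- l3_scores(g, pairs, normalized = TRUE)
  jc <- local_similarity_scores(g, pairs, "JC")
  score_table(cbind(l3$node_a, l3$node_b), l3$score * (1 + jc$score),
              method = "SIM", graph = g$name, surrogate = TRUE)
}
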