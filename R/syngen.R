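# Seeded generators of synthetic PPI-like interactomes. All generators draw
# from a private RNG stream (with_seed), so repeated calls with the same seed
# return identical edge sets and never perturb the caller's RNG.

dmc_node_labels <- function(n) {
  sprintf("v%0*d", nchar(as.character(n)), seq_len(n))
}

#' Duplication-mutation-complementation (DMC) graph growth
#'
#' Grows a protein-network-like graph from a single edge by repeated gene
#' duplication: each step copies a uniformly chosen node `u` into a new node
#' `v` (inheriting all of `u`'s interactions); then, for every neighbor `w`
#' of `u`, with probability `q_mod` exactly one of the redundant pair
#' `(u,w)`, `(v,w)` — chosen with equal probability — is deleted
#' (complementation); finally the duplicate pair `(u,v)` is connected with
#' probability `q_con` (self-interaction heritage). Growth stops at
#' `n_final` nodes.
#'
#' With `q_mod = 0, q_con = 1` the result is the complete graph; with
#' `q_mod = 1, q_con = 0` the edge count stays at 1 (each duplication copies
#' exactly as many edges as it deletes). The default parameters are
#' calibrated so that a few-hundred-node graph has mean degree near 12,
#' matching curated human interactome maps.
#'
#' @param n_final target node count (>= 2).
#' @param q_mod deletion probability per redundant neighbor pair, in [0,1].
#' @param q_con probability of connecting the duplicate pair, in [0,1].
#' @param seed integer RNG seed.
#' @param name graph name.
#' @return An [interactome] with `n_final` nodes.
#' @export
dmc_generate <- function(n_final, q_mod = 0.3, q_con = 0.2, seed = 1,
                         name = sprintf("dmc_n%d_seed%d", n_final, seed)) {
  stopifnot(n_final >= 2, q_mod >= 0, q_mod <= 1, q_con >= 0, q_con <= 1)
  nbr <- vector("list", n_final)
  nbr[[1L]] <- 2L
  nbr[[2L]] <- 1L
  with_seed(seed, {
    v <- 3L
    while (v <= n_final) {
      u <- sample.int(v - 1L, 1L)
      ws <- nbr[[u]]
      nbr[[v]] <- ws
      for (w in ws) nbr[[w]] <- c(nbr[[w]], v)
      if (length(ws) > 0L) {
        del <- stats::runif(length(ws)) < q_mod
        from_u <- stats::runif(length(ws)) < 0.5
        for (k in which(del)) {
          w <- ws[k]
          if (from_u[k]) {
            nbr[[u]] <- setdiff(nbr[[u]], w)
            nbr[[w]] <- setdiff(nbr[[w]], u)
          } else {
            nbr[[v]] <- setdiff(nbr[[v]], w)
            nbr[[w]] <- setdiff(nbr[[w]], v)
          }
        }
      }
      if (stats::runif(1L) < q_con) {
        nbr[[u]] <- c(nbr[[u]], v)
        nbr[[v]] <- c(nbr[[v]], u)
      }
      v <- v + 1L
    }
  })
  lab <- dmc_node_labels(n_final)
  deg <- lengths(nbr)
  src <- rep.int(seq_len(n_final), deg)
  dst <- unlist(nbr, use.names = FALSE)
  keep <- src < dst
  interactome(cbind(lab[src[keep]], lab[dst[keep]]), nodes = lab, name = name)
}

#' Erdos-Renyi G(n, m) control graph
#'
#' Samples `m` distinct edges uniformly without replacement among the
#' `n(n-1)/2` unordered node pairs; no self-loops.
#'
#' @param n node count.
#' @param m edge count (<= n(n-1)/2).
#' @param seed integer RNG seed.
#' @param name graph name.
#' @return An [interactome] with exactly `m` edges.
#' @export
er_generate <- function(n, m, seed = 1,
                        name = sprintf("er_n%d_m%d_seed%d", n, m, seed)) {
  stopifnot(n >= 1)
  npairs <- n * (n - 1) / 2
  if (m > npairs) stop("m exceeds the number of available node pairs")
  lab <- dmc_node_labels(n)
  if (m == 0L) return(interactome(matrix(character(0), 0, 2),
                                  nodes = lab, name = name))
  idx <- with_seed(seed, sample(npairs, m))
  cum <- cumsum((n - 1):1)
  i <- findInterval(idx, cum, left.open = TRUE) + 1L
  j <- idx - c(0, cum)[i] + i
  interactome(cbind(lab[i], lab[j]), nodes = lab, name = name)
}

#' Degree-preserving randomization by double-edge swaps
#'
#' Repeatedly proposes swaps of two edges `a-b`, `c-d` into `a-d`, `c-b`
#' (with the pairing orientation itself randomized), rejecting any proposal
#' that would create a self-loop or a multi-edge. Every node's degree is
#' identical before and after; self-loops present in the input are left
#' untouched.
#'
#' @param g an [interactome] with at least 2 non-self-loop edges.
#' @param n_swaps number of swap attempts (default `10 x` edge count).
#' @param seed integer RNG seed.
#' @return A rewired [interactome] over the same node set.
#' @export
degree_preserving_randomize <- function(g, n_swaps = NULL, seed = 1) {
  ed <- g$edges
  self <- ed[, 1L] == ed[, 2L]
  loops <- ed[self, , drop = FALSE]
  ed <- ed[!self, , drop = FALSE]
  m <- nrow(ed)
  if (m < 2L) stop("need at least 2 non-self-loop edges to rewire")
  if (is.null(n_swaps)) n_swaps <- 10L * m
  a <- match(ed[, 1L], g$nodes)
  b <- match(ed[, 2L], g$nodes)
  have <- new.env(hash = TRUE, parent = emptyenv())
  for (t in seq_len(m)) assign(pair_key(min(a[t], b[t]), max(a[t], b[t])),
                               TRUE, envir = have)
  has_edge <- function(x, y) {
    exists(pair_key(min(x, y), max(x, y)), envir = have, inherits = FALSE)
  }
  if (n_swaps > 0L) with_seed(seed, {
    for (s in seq_len(n_swaps)) {
      e1 <- sample.int(m, 1L)
      e2 <- sample.int(m, 1L)
      if (e1 == e2) next
      x1 <- a[e1]; y1 <- b[e1]
      x2 <- a[e2]; y2 <- b[e2]
      if (stats::runif(1L) < 0.5) { tmp <- x2; x2 <- y2; y2 <- tmp }
      # proposed: x1-y2 and x2-y1
      if (x1 == y2 || x2 == y1) next
      if (has_edge(x1, y2) || has_edge(x2, y1)) next
      rm(list = c(pair_key(min(x1, y1), max(x1, y1)),
                  pair_key(min(x2, y2), max(x2, y2))), envir = have)
      assign(pair_key(min(x1, y2), max(x1, y2)), TRUE, envir = have)
      assign(pair_key(min(x2, y1), max(x2, y1)), TRUE, envir = have)
      b[e1] <- y2
      b[e2] <- y1
      a[e2] <- x2
    }
  })
  interactome(rbind(cbind(g$nodes[a], g$nodes[b]), loops),
              nodes = g$nodes, name = paste0(g$name, "_rewired"),
              allow_self_loops = g$allow_self_loops)
}

#' Planted-partition (stochastic block) graph
#'
#' Nodes are split into `n_blocks` blocks of `block_size` nodes; each
#' unordered pair is connected independently with probability `p_in` inside
#' a block and `p_out` across blocks. The ground-truth block labels are
#' returned for evaluation of community-aware scorers.
#'
#' @param n_blocks number of blocks.
#' @param block_size nodes per block.
#' @param p_in within-block edge probability.
#' @param p_out between-block edge probability.
#' @param seed integer RNG seed.
#' @param name graph name.
#' @return A list with `graph` (an [interactome]) and `blocks` (named
#'   integer vector of block labels).
#' @export
planted_partition_generate <- function(n_blocks, block_size, p_in, p_out,
                                       seed = 1,
                                       name = sprintf("pp_b%dx%d_seed%d",
                                                      n_blocks, block_size,
                                                      seed)) {
  stopifnot(p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            n_blocks >= 1, block_size >= 1)
  n <- n_blocks * block_size
  lab <- dmc_node_labels(n)
  block <- rep(seq_len(n_blocks), each = block_size)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  prob <- ifelse(block[ut[, 1L]] == block[ut[, 2L]], p_in, p_out)
  keep <- with_seed(seed, stats::runif(nrow(ut)) < prob)
  g <- interactome(cbind(lab[ut[keep, 1L]], lab[ut[keep, 2L]]),
                   nodes = lab, name = name)
  names(block) <- lab
  list(graph = g, blocks = block)
}
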