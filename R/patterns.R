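# Analytics over prediction sets: degree-difference distributions and degree
# profiles of top predictions, network-based separation between protein
# sets, and inter-method overlap of top-k prediction lists.

#' Degree-difference distribution of predicted pairs
#'
#' For each pair, the absolute difference of endpoint degrees in the full
#' graph; summarized as mean, standard deviation and a unit-width histogram.
#' Methods that exploit hubs (the L3 family, block models) characteristically
#' predict pairs with large degree differences relative to random links.
#'
#' @param g an [interactome] (degrees taken from the full graph).
#' @param pairs two-column matrix of predicted pairs.
#' @param self_loop_degree degree contributed by a self-loop (default 2).
#' @return List with `mean`, `sd`, `differences`, `histogram` (named counts).
#' @export
degree_difference_stats <- function(g, pairs, self_loop_degree = 2) {
  if (length(pairs) == 0L || nrow(as.matrix(pairs)) == 0L) {
    stop("empty pair list")
  }
  rp <- resolve_pairs(g, pairs, allow_self = TRUE)
  k <- full_degrees(g, self_loop_degree)
  d <- abs(k[rp$ia] - k[rp$ib])
  list(mean = mean(d), sd = if (length(d) > 1) stats::sd(d) else 0,
       differences = d, histogram = table(factor(d, levels = 0:max(d))))
}

full_degrees <- function(g, self_loop_degree = 2) {
  A <- adjacency_matrix(g, drop_self_loops = TRUE)
  k <- Matrix::rowSums(A)
  self <- g$edges[g$edges[, 1L] == g$edges[, 2L], 1L]
  if (length(self) > 0L) {
    k[match(self, g$nodes)] <- k[match(self, g$nodes)] + self_loop_degree
  }
  k
}

#' Mean degree of proteins in the top-k predictions
#'
#' Averages the full-graph degrees of the endpoints of the `k` highest
#' ranked pairs. Two conventions are reported: the multiset mean (a protein
#' counted once per pair it appears in) and the unique-protein mean.
#'
#' @param g an [interactome].
#' @param ranked output of [rank_candidates].
#' @param k number of top pairs (>= 1, <= list length).
#' @param self_loop_degree degree contributed by a self-loop.
#' @return List with `mean_degree` (multiset convention),
#'   `mean_degree_unique`, `k`, `n_proteins`.
#' @export
top_prediction_degree_profile <- function(g, ranked, k,
                                          self_loop_degree = 2) {
  if (k < 1) stop("k must be at least 1")
  if (k > nrow(ranked)) stop("k exceeds the ranked list length")
  top <- ranked[seq_len(k), , drop = FALSE]
  kdeg <- full_degrees(g, self_loop_degree)
  ends <- c(top$node_a, top$node_b)
  multi <- kdeg[node_index(g, ends)]
  uniq <- kdeg[node_index(g, unique(ends))]
  list(mean_degree = mean(multi), mean_degree_unique = mean(uniq),
       k = k, n_proteins = length(unique(ends)))
}

#' Network-based separation of two protein sets
#'
#' `s_ab = <d_ab> - (<d_aa> + <d_bb>)/2`, where the within- and cross-set
#' distance averages use the nearest-neighbor convention of the separation
#' measure for network modules: for each protein the shortest distance to
#' the nearest (other) member of the target set, averaged over proteins.
#' Negative `s_ab` indicates overlapping network neighborhoods; positive
#' values indicate topologically separated sets. The prose-literal
#' alternative — the mean over all cross/within pairs — is available via
#' `convention = "all_pairs"`. Unreachable pairs are excluded from the means
#' and reported through `coverage` (fraction of contributing distances that
#' were finite); a singleton set has within-distance 0.
#'
#' @param g an [interactome].
#' @param set_a,set_b nonempty character vectors of node labels.
#' @param convention `"nearest"` (default) or `"all_pairs"`.
#' @return List of class `separation_result` with `s_ab`, `d_ab`, `d_aa`,
#'   `d_bb`, `coverage`.
#' @export
network_separation <- function(g, set_a, set_b,
                               convention = c("nearest", "all_pairs")) {
  convention <- match.arg(convention)
  if (length(set_a) == 0L || length(set_b) == 0L) stop("sets must be nonempty")
  node_index(g, set_a)
  node_index(g, set_b)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  ig <- as_igraph(g)
  D <- igraph::distances(ig, v = unique(c(set_a, set_b)),
                         to = unique(c(set_a, set_b)))
  finite_stats <- function(x) {
    fin <- is.finite(x)
    list(mean = if (any(fin)) mean(x[fin]) else NA_real_,
         n = length(x), n_finite = sum(fin))
  }
  cross_d <- function(sa, sb) {
    M <- D[sa, sb, drop = FALSE]
    # a protein present in both sets is not its own nearest cross-partner
    shared <- intersect(sa, sb)
    if (length(shared) > 0L) {
      M[cbind(match(shared, sa), match(shared, sb))] <- Inf
    }
    if (convention == "nearest") {
      c(apply(M, 1, min), apply(M, 2, min))
    } else {
      as.vector(M)
    }
  }
  within_d <- function(sa) {
    if (length(sa) == 1L) return(0)
    M <- D[sa, sa, drop = FALSE]
    diag(M) <- Inf
    if (convention == "nearest") {
      apply(M, 1, min)
    } else {
      M[upper.tri(M)]
    }
  }
  ab <- finite_stats(cross_d(set_a, set_b))
  aa <- finite_stats(within_d(set_a))
  bb <- finite_stats(within_d(set_b))
  cov <- (ab$n_finite + aa$n_finite + bb$n_finite) / (ab$n + aa$n + bb$n)
  if (is.na(ab$mean)) {
    stop("sets are entirely unreachable from each other (coverage 0)")
  }
  d_aa <- if (is.na(aa$mean)) 0 else aa$mean
  d_bb <- if (is.na(bb$mean)) 0 else bb$mean
  structure(list(s_ab = ab$mean - (d_aa + d_bb) / 2, d_ab = ab$mean,
                 d_aa = d_aa, d_bb = d_bb, coverage = cov,
                 convention = convention),
            class = "separation_result")
}

#' Overlap between two prediction sets
#'
#' Agreement of two methods' top-k prediction lists over a shared candidate
#' universe: the Jaccard index of the two sets and Cohen's kappa of the
#' binary in-list indicators across the universe.
#'
#' @param set_a,set_b character vectors of pair keys, or two-column matrices
#'   of pairs.
#' @param universe size of the shared candidate universe (>= `|A ∪ B|`).
#' @return List of class `overlap_result` with `kappa`, `jaccard`,
#'   `universe`, `size_a`, `size_b`.
#' @export
prediction_overlap <- function(set_a, set_b, universe) {
  as_keys <- function(s) {
    if (is.character(s) && is.null(dim(s))) return(unique(s))
    p <- canonicalize_pairs(s)
    unique(pair_key(p[, 1L], p[, 2L]))
  }
  ka <- as_keys(set_a)
  kb <- as_keys(set_b)
  inter <- length(intersect(ka, kb))
  uni <- length(union(ka, kb))
  if (universe < uni) stop("universe smaller than |A union B|")
  a <- inter
  b <- length(ka) - inter
  c_ <- length(kb) - inter
  d <- universe - uni
  po <- (a + d) / universe
  pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / universe^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  structure(list(kappa = kappa, jaccard = if (uni > 0) inter / uni else 1,
                 universe = universe, size_a = length(ka),
                 size_b = length(kb)),
            class = "overlap_result")
}
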