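# Stacking and consensus models: a supervised meta-classifier over
# topological predictors, and unsupervised rank aggregation (mean/max
# percentile, Dowdall) of component score tables.

stack_pairwise_features <- c("cn", "jc", "aa", "ra", "pa", "sp_len", "l3",
                             "katz3")
stack_node_features <- c("degree", "clustering", "core", "pagerank",
                         "eigcent")
stack_global_features <- c("density", "mean_clustering", "assortativity")

#' Topological feature table for candidate pairs
#'
#' Builds the predictor matrix used by the supervised stacking model. All
#' features are computed on the training graph only. Three kinds of
#' predictors are stacked:
#' \itemize{
#'   \item pairwise: CN, JC, AA, RA, PA, shortest-path length (unreachable
#'     encoded as the node count), degree-normalized L3, and the Katz sum
#'     truncated at walk length 3 (`katz3`, damping 0.1);
#'   \item node-based, endpoint-order invariant (reported as min/max over
#'     the two endpoints): degree, local clustering coefficient, core
#'     number, PageRank centrality, eigenvector centrality;
#'   \item global (constant per graph): density, mean local clustering,
#'     degree assortativity (0 for degenerate degree sequences).
#' }
#'
#' @param g_train training [interactome].
#' @param pairs candidate node pairs.
#' @param labels optional 0/1 vector marking known positives.
#' @param katz_beta damping for the truncated Katz feature.
#' @return A data frame of class `feature_table` with columns `node_a`,
#'   `node_b`, the 21 predictors, and `label` when supplied.
#' @export
topological_feature_table <- function(g_train, pairs, labels = NULL,
                                      katz_beta = 0.1) {
  rp <- resolve_pairs(g_train, pairs, allow_self = FALSE)
  ig <- as_igraph(g_train)
  A <- adjacency_matrix(g_train, drop_self_loops = TRUE)
  k <- Matrix::rowSums(A)
  n <- length(g_train$nodes)
  ia <- rp$ia; ib <- rp$ib
  idx <- cbind(ia, ib)

  A2 <- A %*% A
  cn <- as.numeric(A2[idx])
  un <- k[ia] + k[ib] - cn
  w_aa <- ifelse(k > 1, 1 / log(k), 0)
  w_ra <- ifelse(k > 0, 1 / k, 0)
  aa <- as.numeric((A %*% (w_aa * A))[idx])
  ra <- as.numeric((A %*% (w_ra * A))[idx])
  wl3 <- ifelse(k > 0, 1 / sqrt(k), 0)
  l3 <- as.numeric((A %*% ((wl3 * A) %*% Matrix::Diagonal(x = wl3)) %*% A)[idx])
  A3 <- A2 %*% A
  katz3 <- katz_beta * as.numeric(A[idx]) + katz_beta^2 * cn +
    katz_beta^3 * as.numeric(A3[idx])

  D <- igraph::distances(ig)
  sp <- D[cbind(match(g_train$nodes[ia], rownames(D)),
                match(g_train$nodes[ib], rownames(D)))]
  sp[!is.finite(sp)] <- n

  clus <- igraph::transitivity(ig, type = "local", isolates = "zero")
  core <- igraph::coreness(ig)
  pr <- igraph::page_rank(ig)$vector
  ec <- igraph::eigen_centrality(ig)$vector
  node_feats <- cbind(degree = k, clustering = clus, core = core,
                      pagerank = pr, eigcent = ec)

  assort <- suppressWarnings(igraph::assortativity_degree(ig))
  if (!is.finite(assort)) assort <- 0
  gs <- graph_summary(g_train)

  out <- data.frame(node_a = rp$pairs[, 1L], node_b = rp$pairs[, 2L],
                    cn = cn, jc = ifelse(un > 0, cn / un, 0), aa = aa,
                    ra = ra, pa = k[ia] * k[ib], sp_len = sp, l3 = l3,
                    katz3 = katz3, stringsAsFactors = FALSE)
  for (f in stack_node_features) {
    fa <- node_feats[ia, f]
    fb <- node_feats[ib, f]
    out[[paste0(f, "_min")]] <- pmin(fa, fb)
    out[[paste0(f, "_max")]] <- pmax(fa, fb)
  }
  out$density <- gs$density
  out$mean_clustering <- mean(clus)
  out$assortativity <- assort
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(out))
    out$label <- as.numeric(labels)
  }
  attr(out, "graph_name") <- g_train$name
  attr(out, "feature_names") <- setdiff(names(out),
                                        c("node_a", "node_b", "label"))
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Train the supervised stacking classifier
#'
#' Stacking-model-1: a probabilistic binary classifier over the topological
#' feature table. Positives are the labeled rows; negatives are sampled from
#' the unlabeled (non-link) rows at `negative_ratio` negatives per positive
#' (balanced random sampling at the default ratio 1). The default learner is
#' a ridge-regularized logistic regression; any learner emitting scores in
#' [0,1] satisfies the module contract.
#'
#' @param table a [topological_feature_table] with a `label` column
#'   containing both classes.
#' @param negative_ratio negatives sampled per positive (default 1).
#' @param seed integer RNG seed (sampling only; the fit is deterministic).
#' @param lambda ridge penalty of the logistic model.
#' @return A scoring function: `function(new_table) -> numeric in [0,1]`,
#'   with the fitted model in attribute `"model"`.
#' @export
train_stacked_classifier <- function(table, negative_ratio = 1, seed = 1,
                                     lambda = 0.01) {
  if (is.null(table$label)) stop("feature table has no label column")
  feats <- attr(table, "feature_names")
  pos <- which(table$label == 1)
  neg_pool <- which(table$label == 0)
  if (length(pos) == 0L || length(neg_pool) == 0L) {
    stop("training requires both classes")
  }
  n_neg <- min(length(neg_pool), max(1L, round(negative_ratio * length(pos))))
  neg <- with_seed(seed, sample(neg_pool, n_neg))
  train <- table[c(pos, neg), , drop = FALSE]
  x <- as.matrix(train[, feats, drop = FALSE])
  keep <- apply(x, 2, function(col) stats::sd(col) > 0)
  if (!any(keep)) stop("all features are constant on the training sample")
  x <- x[, keep, drop = FALSE]
  y <- train$label
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  used <- feats[keep]
  scorer <- function(new_table) {
    xn <- as.matrix(new_table[, used, drop = FALSE])
    as.numeric(stats::predict(fit, newx = xn, type = "response"))
  }
  attr(scorer, "model") <- fit
  attr(scorer, "features") <- used
  scorer
}

#' Aggregate component rankings into a consensus
#'
#' Unsupervised stacking over two or more score tables covering the same
#' candidate universe:
#' \describe{
#'   \item{mean_percentile}{average of the percentile ranks
#'     (`1 - (rank-1)/(N-1)`, midpoint ties) — Stacking-model-2.}
#'   \item{max_percentile}{maximum of the percentile ranks —
#'     Stacking-model-3.}
#'   \item{dowdall}{reciprocal-rank points `1/rank` summed over components
#'     (a Kemeny-consensus approximation) — Stacking-model-4.}
#' }
#' All rules depend only on within-component ranks, so they are invariant to
#' monotone rescaling of component scores.
#'
#' @param tables list of >= 2 [score_table]s over a common universe.
#' @param rule aggregation rule.
#' @return A [score_table] of aggregate scores (attribute `rule` and
#'   `components` record the recipe).
#' @export
aggregate_rankings <- function(tables, rule = c("mean_percentile",
                                                "max_percentile", "dowdall")) {
  rule <- match.arg(rule)
  if (length(tables) < 2L) stop("need at least two component tables")
  base_keys <- sort(score_keys(tables[[1L]]))
  for (t in tables[-1L]) {
    if (!identical(sort(score_keys(t)), base_keys)) {
      stop("component tables must cover a common candidate universe")
    }
  }
  ref <- tables[[1L]][order(score_keys(tables[[1L]]), method = "radix"), ]
  per_comp <- vapply(tables, function(t) {
    t <- t[order(score_keys(t), method = "radix"), ]
    if (rule == "dowdall") {
      1 / rank(-t$score, ties.method = "average")
    } else {
      percentile_ranks(t$score)
    }
  }, numeric(nrow(ref)))
  agg <- switch(rule,
    mean_percentile = rowMeans(per_comp),
    max_percentile = apply(per_comp, 1, max),
    dowdall = rowSums(per_comp)
  )
  out <- score_table(cbind(ref$node_a, ref$node_b), agg,
                     method = paste0("stack_", rule),
                     graph = attr(tables[[1L]], "graph_name"))
  attr(out, "rule") <- rule
  attr(out, "components") <- vapply(tables, attr, "", "method_name")
  out
}
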