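two_clique_table <- function() {
  cl <- function(lab) t(utils::combn(lab, 2))
  ed <- rbind(cl(paste0("a", 1:5)), cl(paste0("b", 1:5)))
  drop <- c(1, 2, nrow(ed) - 1, nrow(ed))
  g <- interactome(ed[-drop, ], nodes = sort(unique(as.vector(ed))))
  pairs <- build_candidate_universe(g)
  within <- substr(pairs[, 1], 1, 1) == substr(pairs[, 2], 1, 1)
  topological_feature_table(g, pairs, labels = as.numeric(within))
}

test_that("feature tables are deterministic, symmetric and hand-checkable", {
  p3 <- path_graph(3)
  ft <- topological_feature_table(p3, rbind(c("1", "3")))
  expect_equal(ft$cn, 1)
  expect_equal(ft$sp_len, 2)
  expect_equal(ft$pa, 1)
  expect_equal(ft$degree_min, 1)
  expect_equal(ft$degree_max, 1)
  expect_gte(length(attr(ft, "feature_names")), 20)

  g <- dmc_generate(25, 0.3, 0.2, seed = 6)
  pairs <- build_candidate_universe(g)
  ft2 <- topological_feature_table(g, pairs)
  # global features constant across rows
  for (f in c("density", "mean_clustering", "assortativity")) {
    expect_equal(length(unique(ft2[[f]])), 1, info = f)
  }
  # endpoint order does not matter
  ft_rev <- topological_feature_table(g, pairs[, 2:1])
  expect_equal(ft_rev[attr(ft2, "feature_names")],
               ft2[attr(ft2, "feature_names")])
  # unreachable pairs encode shortest path as the node count
  iso <- interactome(rbind(c("a", "b")), nodes = c("a", "b", "z"))
  expect_equal(topological_feature_table(iso, rbind(c("a", "z")))$sp_len, 3)
  expect_error(topological_feature_table(p3, rbind(c("1", "9"))),
               "not present")
})

test_that("the stacked classifier separates separable classes and is seeded", {
  ft <- two_clique_table()
  scorer <- train_stacked_classifier(ft, seed = 1)
  pred <- scorer(ft)
  expect_true(all(pred >= 0 & pred <= 1))
  expect_equal(as.numeric(pred > 0.5), ft$label)  # training accuracy 1
  scorer2 <- train_stacked_classifier(ft, seed = 1)
  expect_identical(scorer2(ft), pred)
  bad <- ft
  bad$label <- 1
  expect_error(train_stacked_classifier(bad), "both classes")
})

test_that("shuffled labels yield chance-level held-out discrimination", {
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    g <- er_generate(30, 100, seed = s)
    pairs <- build_candidate_universe(g)
    lab <- numeric(nrow(pairs))
    lab[sample(length(lab), 40)] <- 1      # labels carry no signal
    ft <- topological_feature_table(g, pairs, labels = lab)
    half <- sample(nrow(ft), nrow(ft) %/% 2)
    tr <- ft[half, ]; te <- ft[-half, ]
    attr(tr, "feature_names") <- attr(ft, "feature_names")
    if (sum(tr$label) < 2 || sum(te$label) < 2) return(0.5)
    scorer <- train_stacked_classifier(tr, seed = s)
    oracle_auroc(scorer(te), te$label)
  }, 1)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

ranking_table <- function(scores) {
  score_table(cbind("a", c("x", "y", "z")), scores, graph = "toy")
}

test_that("rank aggregation reproduces the Dowdall worked example", {
  t1 <- ranking_table(c(3, 2, 1))   # x > y > z
  t2 <- ranking_table(c(2, 3, 1))   # y > x > z
  agg <- aggregate_rankings(list(t1, t2), rule = "dowdall")
  expect_equal(score_lookup(agg, "a", c("x", "y", "z")),
               c(1.5, 1.5, 2 / 3))
  ranked <- rank_candidates(agg)
  expect_equal(ranked$node_b[1], "x")  # canonical tie-break before y

  rev2 <- ranking_table(c(1, 2, 3))   # z > y > x
  mp <- aggregate_rankings(list(t1, rev2), rule = "mean_percentile")
  expect_equal(mp$score, rep(0.5, 3))
  expect_equal(rank_candidates(mp)$node_b, c("x", "y", "z"))
})

test_that("aggregation rules are idempotent, unanimous and rank-invariant", {
  t1 <- ranking_table(c(9, 5, 2))
  for (rule in c("mean_percentile", "max_percentile", "dowdall")) {
    same <- aggregate_rankings(list(t1, t1), rule = rule)
    expect_equal(order(-same$score), order(-t1$score), info = rule)
  }
  # unanimity: first under every component => first under every rule
  t2 <- ranking_table(c(8, 1, 4))
  for (rule in c("mean_percentile", "max_percentile", "dowdall")) {
    agg <- aggregate_rankings(list(t1, t2), rule = rule)
    expect_equal(which.max(agg$score), 1, info = rule)
  }
  # invariance to monotone rescaling of component scores
  t2m <- ranking_table(exp(c(8, 1, 4)) + 3)
  for (rule in c("mean_percentile", "max_percentile", "dowdall")) {
    expect_equal(aggregate_rankings(list(t1, t2), rule = rule)$score,
                 aggregate_rankings(list(t1, t2m), rule = rule)$score,
                 info = rule)
  }
  expect_error(aggregate_rankings(list(t1), "dowdall"), "at least two")
  t3 <- score_table(cbind("a", c("x", "y", "q")), 1:3)
  expect_error(aggregate_rankings(list(t1, t3)), "common candidate universe")
})

test_that("consensus does not beat the best component on a synthetic benchmark", {
  # the empirical observation behind the stacking analysis, reported (not a
  # universal law): aggregate AUPRC <= twice the best component AUPRC
  g <- dmc_generate(80, 0.3, 0.2, seed = 21)
  split <- kfold_edge_split(g, k = 5, seed = 21)
  tr <- training_graph(split, 1)
  probe <- probe_edges(split, 1)
  u <- build_candidate_universe(tr)
  comp <- list(rnm = rnm_scores(tr, u), mps = mps_t_scores(tr, u))
  auprcs <- vapply(comp, function(st) {
    compute_metrics(rank_candidates(st), probe, k = 50)$auprc
  }, 1)
  agg <- aggregate_rankings(comp, "mean_percentile")
  a_agg <- compute_metrics(rank_candidates(agg), probe, k = 50)$auprc
  expect_lt(a_agg, 2 * max(auprcs) + 1e-9)
})
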