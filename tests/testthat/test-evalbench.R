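test_that("k-fold edge splits partition E into near-equal probe sets", {
  g <- er_generate(30, 20, seed = 1)
  split <- kfold_edge_split(g, k = 10, seed = 3)
  sizes <- tabulate(split$fold, 10)
  expect_true(all(sizes == 2))
  probes <- lapply(1:10, function(f) probe_edges(split, f))
  all_probe <- do.call(rbind, probes)
  expect_equal(nrow(all_probe), 20)
  expect_equal(nrow(unique(all_probe)), 20)      # pairwise disjoint
  expect_setequal(paste(all_probe[, 1], all_probe[, 2]),
                  paste(g$edges[, 1], g$edges[, 2]))  # union = E
  for (f in 1:3) {
    tr <- training_graph(split, f)
    expect_equal(nrow(tr$edges) + nrow(probe_edges(split, f)), 20)
    expect_identical(tr$nodes, g$nodes)
  }
  expect_identical(kfold_edge_split(g, 10, seed = 3)$fold, split$fold)
  # uneven division: sizes differ by at most 1
  g2 <- er_generate(30, 23, seed = 1)
  s2 <- tabulate(kfold_edge_split(g2, 10, seed = 1)$fold, 10)
  expect_lte(diff(range(s2)), 1)
  expect_error(kfold_edge_split(g, k = 25), "exceeds")
})

test_that("the candidate universe is every pair absent from training", {
  k4 <- complete_graph(4)
  expect_equal(nrow(build_candidate_universe(k4)), 0)
  g <- interactome(rbind(c("a", "b"), c("c", "d")))
  expect_equal(nrow(build_candidate_universe(g)), 4)
  iso <- interactome(matrix(character(0), 0, 2), nodes = c("x", "y", "z"))
  u <- build_candidate_universe(iso, include_self_pairs = TRUE)
  expect_equal(nrow(u), 6)
  expect_equal(sum(u[, 1] == u[, 2]), 3)
})

test_that("candidate ranking is deterministic with lexicographic ties", {
  st <- score_table(rbind(c("a", "b"), c("c", "d"), c("a", "c")),
                    c(0.5, 0.5, 0.9))
  r <- rank_candidates(st)
  expect_equal(paste(r$node_a, r$node_b), c("a c", "a b", "c d"))
  allt <- score_table(rbind(c("b", "c"), c("a", "b"), c("a", "c")), rep(1, 3))
  expect_equal(rank_candidates(allt)$node_a, c("a", "a", "b"))
  single <- score_table(rbind(c("a", "b")), 0.3)
  expect_equal(nrow(rank_candidates(single)), 1)
})

test_that("fold metrics reproduce their defining formulas", {
  mk <- function(scores) {
    n <- length(scores)
    labs <- sprintf("x%02d", 1:(n + 1))
    rank_candidates(score_table(cbind(labs[1:n], labs[n + 1]), scores))
  }
  # perfect ranking [1,1,0,0]
  r <- mk(c(0.9, 0.8, 0.2, 0.1))
  pos <- rbind(c("x01", "x05"), c("x02", "x05"))
  m <- compute_metrics(r, pos, k = 2)
  expect_equal(m$auroc, 1)
  expect_equal(m$auprc, 1)
  expect_equal(m$p_at_k, 1)
  expect_equal(m$ndcg, 1)
  # the worked example [1,0,1]
  r2 <- mk(c(0.9, 0.5, 0.2))
  pos2 <- rbind(c("x01", "x04"), c("x03", "x04"))
  m2 <- compute_metrics(r2, pos2, k = 2)
  expect_equal(m2$auprc, (1 + 2 / 3) / 2)
  expect_equal(m2$p_at_k, 0.5)
  expect_equal(m2$ndcg, 1.5 / (1 + 1 / log2(3)), tolerance = 1e-12)
  # tie correction: one positive, one negative, equal scores
  r3 <- mk(c(0.5, 0.5))
  m3 <- compute_metrics(r3, rbind(c("x02", "x03")), k = 1)
  expect_equal(m3$auroc, 0.5)
  expect_error(compute_metrics(r3, matrix(character(0), 0, 2)), "undefined")
  expect_error(compute_metrics(r3, rbind(c("zz", "zz"))), "subset")
})

test_that("metrics match naive recomputation on random relevance vectors", {
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(10:60, 1)
    scores <- round(runif(n), 2)   # rounded to force ties
    rel_raw <- rbinom(n, 1, 0.3)
    if (sum(rel_raw) == 0) rel_raw[sample(n, 1)] <- 1
    labs <- sprintf("y%03d", 1:(n + 1))
    st <- score_table(cbind(labs[1:n], labs[n + 1]), scores)
    ranked <- rank_candidates(st)
    pos <- cbind(labs[which(rel_raw == 1)], labs[n + 1])
    m <- compute_metrics(ranked, pos, k = 10)
    rel_ranked <- as.numeric(paste(ranked$node_a, ranked$node_b) %in%
                               paste(pmin(pos[, 1], pos[, 2]),
                                     pmax(pos[, 1], pos[, 2])))
    expect_equal(m$auroc, oracle_auroc(ranked$score, rel_ranked))
    expect_equal(m$auprc, oracle_ap(rel_ranked))
    expect_equal(m$ndcg, oracle_ndcg(rel_ranked))
    expect_equal(m$p_at_k, oracle_p_at_k(rel_ranked, 10))
  }
})

test_that("P@k never increases once all positives are found", {
  st <- score_table(cbind(sprintf("a%02d", 1:20), "zz"), 20:1)
  ranked <- rank_candidates(st)
  pos <- cbind(sprintf("a%02d", 1:3), "zz")
  pk <- vapply(3:20, function(k) compute_metrics(ranked, pos, k = k)$p_at_k, 1)
  expect_true(all(diff(pk) <= 0))
})

test_that("combined z-scores follow the sum-of-three definition", {
  tab <- data.frame(method = c("m1", "m2", "m3"),
                    auprc = c(0.1, 0.2, 0.3),
                    p_at_k = c(0.2, 0.2, 0.2),
                    ndcg = c(0.5, 0.5, 0.5))
  sc <- suppressWarnings(combine_zscores(tab))
  expect_equal(sc$combined[match(c("m1", "m2", "m3"), sc$method)],
               c(-1, 0, 1))
  expect_equal(sum(sc$z_auprc), 0)
  expect_equal(sum(sc$combined), 0)
  expect_warning(combine_zscores(tab), "zero spread")
  same <- data.frame(method = c("a", "b"), auprc = 0.1, p_at_k = 0.1,
                     ndcg = 0.1)
  expect_true(all(suppressWarnings(combine_zscores(same))$combined == 0))
  expect_error(combine_zscores(tab[1, ]), "at least 2")
})

test_that("benchmark runs orchestrate folds and tolerate scorer failure", {
  g <- dmc_generate(60, 0.3, 0.2, seed = 5)
  b <- benchmark_run(g, c("cn", "l3"), k_folds = 5, seed = 2)
  expect_equal(nrow(b$per_fold), 10)
  expect_equal(sort(unique(b$per_fold$fold)), 1:5)
  expect_equal(nrow(b$scorecard), 2)
  b2 <- benchmark_run(g, c("cn", "l3"), k_folds = 5, seed = 2)
  expect_identical(b$per_fold, b2$per_fold)

  boom <- list(cn = method_registry()$cn,
               l3 = method_registry()$l3,
               bad = function(g, p) stop("deliberate failure"))
  expect_warning(b3 <- benchmark_run(g, boom, k_folds = 3, seed = 2),
                 "deliberate failure")
  expect_true(all(is.na(b3$per_fold$auprc[b3$per_fold$method == "bad"])))
  expect_false("bad" %in% b3$scorecard$method)  # N/A: excluded, run completes
  expect_equal(nrow(b3$scorecard), 2)

  d <- withr::local_tempdir()
  write_benchmark_report(b, d)
  expect_true(file.exists(file.path(d, "metrics.tsv")))
  expect_true(file.exists(file.path(d, "report.json")))
})
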