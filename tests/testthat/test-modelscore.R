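test_that("SBM reliabilities agree with exhaustive partition enumeration", {
  for (g in list(path_graph(4), star_graph())) {
    pairs <- all_missing_pairs(g)
    A <- dense_adj(g)
    exact <- sbm_exact_reliability(A, match(pairs[, 1], g$nodes),
                                   match(pairs[, 2], g$nodes))
    got <- sbm_reliability_scores(g, pairs, n_samples = 3000,
                                  burn_in = 1500, seed = 4)$score
    expect_true(all(abs(got - exact) < 0.03), info = g$name)
    expect_true(all(got > 0 & got < 1))
  }
  expect_error(sbm_reliability_scores(path_graph(4), rbind(c("1", "3")),
                                      n_samples = 0), "positive")
})

test_that("SBM respects graph automorphisms and planted blocks", {
  p5 <- path_graph(5)
  st <- sbm_reliability_scores(p5, rbind(c("1", "3"), c("3", "5")),
                               n_samples = 4000, burn_in = 2000, seed = 2)
  # reversal automorphism maps (1,3) onto (5,3)
  expect_lt(abs(st$score[1] - st$score[2]), 0.02)

  pp <- planted_partition_generate(3, 8, p_in = 0.9, p_out = 0.05, seed = 6)
  g <- pp$graph
  pairs <- all_missing_pairs(g)
  st2 <- sbm_reliability_scores(g, pairs, n_samples = 1500, burn_in = 1500,
                                seed = 3)
  within <- pp$blocks[pairs[, 1]] == pp$blocks[pairs[, 2]]
  expect_gt(mean(st2$score[within]), mean(st2$score[!within]))
  # determinism
  st3 <- sbm_reliability_scores(p5, rbind(c("1", "3")), n_samples = 200,
                                burn_in = 100, seed = 9)
  st4 <- sbm_reliability_scores(p5, rbind(c("1", "3")), n_samples = 200,
                                burn_in = 100, seed = 9)
  expect_identical(st3$score, st4$score)
})

test_that("embedding scorers separate blocks and respect conventions", {
  pp <- planted_partition_generate(2, 8, p_in = 0.9, p_out = 0.1, seed = 1)
  g <- pp$graph
  pairs <- all_missing_pairs(g)
  within <- pp$blocks[pairs[, 1]] == pp$blocks[pairs[, 2]]
  for (m in c("nnmf", "glee", "spc")) {
    st <- embedding_scores(g, pairs, m, d = 2, seed = 1)
    expect_gt(mean(st$score[within]), mean(st$score[!within]))
    expect_true(all(st$score >= -1 - 1e-12 & st$score <= 1 + 1e-12))
  }
  expect_true(all(embedding_scores(g, pairs, "nnmf", d = 2)$score >= 0))
  expect_error(embedding_scores(g, pairs, "glee", d = 16), "dimension")
  # NNMF is seeded; Laplacian variants ignore the seed
  expect_identical(embedding_scores(g, pairs, "nnmf", d = 3, seed = 5)$score,
                   embedding_scores(g, pairs, "nnmf", d = 3, seed = 5)$score)
  # isolated node has a zero row: cosine defined as 0
  iso <- interactome(rbind(c("a", "b"), c("b", "c"), c("c", "d")),
                     nodes = c("a", "b", "c", "d", "z"))
  stz <- embedding_scores(iso, rbind(c("a", "z")), "nnmf", d = 2, n_iter = 2000)
  expect_lt(stz$score, 0.2)
})

test_that("ACT equals inverse commute time from the Laplacian pseudoinverse", {
  p3 <- path_graph(3)
  st <- act_scores(p3, rbind(c("1", "2"), c("1", "3")))
  expect_equal(st$score, c(1 / 4, 1 / 8), tolerance = 1e-10)
  two <- interactome(rbind(c("a", "b"), c("c", "d")))
  expect_equal(act_scores(two, rbind(c("a", "c")))$score, 0)
  k3 <- complete_graph(3)
  s3 <- act_scores(k3, rbind(c("1", "2"), c("1", "3"), c("2", "3")))$score
  expect_lt(diff(range(s3)), 1e-12)
})

test_that("ACT matches an absorbing random-walk simulation", {
  # hitting times H(i->j) + H(j->i) estimated by direct walk simulation
  p3 <- path_graph(3)
  A <- dense_adj(p3)
  set.seed(42)
  walk_time <- function(from, to, n_walks = 3000) {
    mean(vapply(seq_len(n_walks), function(w) {
      pos <- from; steps <- 0
      while (pos != to) {
        pos <- sample(which(A[pos, ] > 0), 1)
        steps <- steps + 1
      }
      steps
    }, 1))
  }
  ct_sim <- walk_time(1, 3) + walk_time(3, 1)
  ct_pkg <- 1 / act_scores(p3, rbind(c("1", "3")))$score
  expect_lt(abs(ct_sim - ct_pkg) / ct_pkg, 0.1)
})

test_that("RWR solves the restart fixed point and stays stochastic", {
  e <- interactome(rbind(c("a", "b")))
  for (c0 in c(0.15, 0.5)) {
    got <- rwr_scores(e, rbind(c("a", "b")), restart = c0, tol = 1e-12)$score
    expect_equal(got, 2 * (1 - c0) / (2 - c0), tolerance = 1e-8)
  }
  st <- star_graph(leaves = c("a", "b", "d", "e"), hub = "c")
  leaf_pairs <- t(utils::combn(c("a", "b", "d", "e"), 2))
  s <- rwr_scores(st, leaf_pairs)$score
  expect_lt(diff(range(s)), 1e-10)
  expect_equal(rwr_scores(st, leaf_pairs, restart = 1)$score, rep(0, 6))
  expect_error(rwr_scores(st, leaf_pairs, restart = 0), "restart")
  # visiting distributions are probability vectors: symmetrized pair scores
  # over all of a source's partners are bounded by 2
  g <- dmc_generate(30, 0.3, 0.2, seed = 2)
  all_s <- rwr_scores(g, all_missing_pairs(g))$score
  expect_true(all(all_s >= 0 & all_s <= 2))
})

test_that("SimRank matches its one-step closed form on stars", {
  st <- star_graph()  # leaves a, b, d around hub c
  expect_equal(simrank_scores(st, rbind(c("a", "b")), c_decay = 0.8)$score,
               0.8, tolerance = 1e-9)
  expect_equal(simrank_scores(st, rbind(c("a", "a")))$score, 1)
  iso <- interactome(rbind(c("a", "b")), nodes = c("a", "b", "y", "z"))
  expect_equal(simrank_scores(iso, rbind(c("y", "z")))$score, 0)
  expect_error(simrank_scores(st, rbind(c("a", "b")), c_decay = 1.2),
               "c_decay")
  g <- dmc_generate(20, 0.3, 0.2, seed = 3)
  s <- simrank_scores(g, all_missing_pairs(g))$score
  expect_true(all(s >= 0 & s <= 1 + 1e-12))
})
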