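test_that("stratified folds partition each class nearly evenly", {
  ids <- sprintf("g%03d", 1:284)
  labels <- stats::setNames(rep(c(1, 0), each = 142), ids)
  asg <- stratified_kfold(labels, k = 10, repeats = 10, seed = 1)
  expect_length(asg, 10L)
  for (a in asg) {
    expect_setequal(names(a$fold), ids)
    sizes <- table(a$fold)
    expect_true(all(sizes %in% c(28, 29)))
    for (cls in 0:1) {
      per_class <- table(a$fold[labels[names(a$fold)] == cls])
      expect_true(all(per_class %in% c(14, 15)))
    }
  }
  # distinct partitions across repeats, identical under the same seed
  expect_false(identical(asg[[1]]$fold, asg[[2]]$fold))
  asg2 <- stratified_kfold(labels, k = 10, repeats = 10, seed = 1)
  expect_identical(asg, asg2)
  expect_error(stratified_kfold(stats::setNames(c(1, 1, 0), c("a", "b", "c")),
                                k = 2), "fewer than k")
})

test_that("auroc matches examples and the pairwise oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auroc(c(1, 2), c(1, 1)), "both classes")

  for (s in 1:200) {
    withr::with_seed(s, {
      n <- sample(4:30, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
      expect_equal(auroc(scores, labels), auroc_oracle(scores, labels),
                   tolerance = 1e-12)
    })
  }
})

test_that("auroc agrees with an external ROC implementation", {
  withr::with_seed(9, {
    labels <- rbinom(50, 1, 0.4)
    labels[1:2] <- c(0, 1)
    scores <- rnorm(50)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
  })
})

test_that("aupr matches examples and the threshold-sweep oracle", {
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # single positive ranked last among n: area = 1/n
  n <- 7
  expect_equal(aupr(seq(n, 1), c(rep(0, n - 1), 1)), 1 / n)
  expect_error(aupr(c(1, 2), c(0, 0)), "positive")

  for (s in 1:100) {
    withr::with_seed(300 + s, {
      n <- sample(4:20, 1)
      labels <- c(1, rbinom(n - 1, 1, 0.4))
      scores <- sample(seq(0, 1, by = 0.2), n, replace = TRUE)
      expect_equal(aupr(scores, labels), aupr_oracle(scores, labels),
                   tolerance = 1e-10)
    })
  }
})

test_that("random walk with restart solves its fixed point", {
  net <- build_network(edge_df("A", "B", 1))
  # restart 1 puts all mass on the seeds
  expect_equal(rwr_scores(net, "A", restart_prob = 1),
               c(A = 1, B = 0))
  # symmetric 2-node graph, restart 0.5: (2/3, 1/3)
  sc <- rwr_scores(net, "A", restart_prob = 0.5)
  expect_equal(unname(sc), c(2 / 3, 1 / 3), tolerance = 1e-9)

  net2 <- random_network(20, seed = 6)
  seeds <- net2$node_ids[1:4]
  sc2 <- rwr_scores(net2, seeds, 0.5)
  expect_equal(sum(sc2), 1, tolerance = 1e-9)
  expect_true(all(sc2 >= 0))
  # fixed-point residual at convergence
  P <- net2$adjacency / rowSums(net2$adjacency)
  e <- stats::setNames(numeric(20), net2$node_ids)
  e[seeds] <- 1 / 4
  resid <- sum(abs(0.5 * drop(t(P) %*% sc2) + 0.5 * e - sc2))
  expect_lt(resid, 1e-9)
  expect_error(rwr_scores(net2, character()), "no seed")
  expect_error(rwr_scores(net2, "nope"), "unknown seed")
})

test_that("rwr agrees with personalized PageRank", {
  net <- random_network(25, seed = 8)
  seeds <- net$node_ids[c(2, 5, 9)]
  sc <- rwr_scores(net, seeds, restart_prob = 0.3)
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                           weighted = TRUE)
  pers <- stats::setNames(numeric(25), net$node_ids)
  pers[seeds] <- 1
  ref <- igraph::page_rank(g, damping = 0.7, personalized = pers,
                           weights = igraph::E(g)$weight)$vector
  expect_equal(sc, ref[names(sc)], tolerance = 1e-6)
})

test_that("relative difference is exact on worked values", {
  expect_equal(round(relative_difference(0.763, 0.636), 2), 16.64)
  expect_equal(round(relative_difference(0.795, 0.659), 2), 17.11)
  expect_equal(relative_difference(0.5, 0.5), 0)
  expect_error(relative_difference(0, 1), "positive")
  expect_error(relative_difference(-1, 1), "positive")
})

test_that("cross-validation wiring produces one row per repeat and fold", {
  bundle <- small_bundle(seed = 50)
  cfg <- fast_config(k = 4L, repeats = 2L, max_epochs = 15L, patience = 5L)
  rep <- run_cv("dnnOnly", bundle, cfg)
  expect_s3_class(rep, "eval_report")
  expect_equal(nrow(rep$folds), 8L)
  expect_true(all(rep$folds$auroc >= 0 & rep$folds$auroc <= 1))
  expect_true(all(rep$folds$aupr >= 0 & rep$folds$aupr <= 1))
  expect_equal(rep$mean_auroc, mean(rep$folds$auroc))
  expect_equal(rep$mean_aupr, mean(rep$folds$aupr))
})

test_that("the feed-forward-only ablation ignores the network structure", {
  b1 <- small_bundle(seed = 51)
  b2 <- small_bundle(seed = 52)
  # same genes, labels and features; different wiring
  expect_identical(names(b1$labels), names(b2$labels))
  b2$features <- b1$features
  cfg <- fast_config(k = 4L, repeats = 1L, max_epochs = 10L)
  r1 <- run_cv("dnnOnly", b1, cfg)
  r2 <- run_cv("dnnOnly", b2, cfg)
  expect_equal(r1$folds, r2$folds)
  # while the network-aware baseline does depend on the wiring
  w1 <- run_cv("rwr", b1, cfg)
  w2 <- run_cv("rwr", b2, cfg)
  expect_false(isTRUE(all.equal(w1$folds, w2$folds)))
})

test_that("depth ablation returns one bounded report per depth", {
  bundle <- small_bundle(seed = 53)
  cfg <- fast_config(k = 3L, repeats = 1L, max_epochs = 10L,
                     walks_per_node = 3L, walk_length = 10L,
                     skipgram_iterations = 2L, embedding_dim = 8L,
                     gcn_hidden = 8L)
  reports <- layer_ablation(bundle, depths = c(2L, 3L), config = cfg)
  expect_named(reports, c("layers_2", "layers_3"))
  for (r in reports) {
    expect_true(all(r$folds$auroc >= 0 & r$folds$auroc <= 1))
    expect_true(all(r$folds$aupr >= 0 & r$folds$aupr <= 1))
  }
})
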