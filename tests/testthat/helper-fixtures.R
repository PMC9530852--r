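# Shared builders and independent oracles for the test suite. All fixtures
# are generated in code; the oracles are deliberately brute-force so they
# stay independent of the implementation paths they check.

edge_df <- function(a, b, w) {
  data.frame(gene_a = a, gene_b = b, weight = w, stringsAsFactors = FALSE)
}

# Tiny path network A-B (w=1), B-C (w=2).
toy_path_network <- function() {
  build_network(edge_df(c("A", "B"), c("B", "C"), c(1, 2)))
}

# Random connected small network: ring plus random chords, uniform weights.
random_network <- function(n, n_chords = n, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("N%02d", seq_len(n))
    a <- ids[seq_len(n)]
    b <- ids[c(seq_len(n)[-1L], 1L)]
    w <- runif(n, 0.1, 1)
    for (k in seq_len(n_chords)) {
      ij <- sample(n, 2L)
      key_new <- paste(sort(ids[ij]), collapse = "-")
      key_old <- paste(pmin(a, b), pmax(a, b), sep = "-")
      if (key_new %in% key_old) next
      a <- c(a, ids[ij[1L]]); b <- c(b, ids[ij[2L]])
      w <- c(w, runif(1, 0.1, 1))
    }
    build_network(edge_df(a, b, w))
  })
}

# Two 10-cliques joined by one weak bridge: a planted two-community graph.
two_clique_network <- function(bridge_weight = 0.1) {
  edges <- NULL
  for (block in 1:2) {
    ids <- sprintf("C%d%02d", block, 1:10)
    pairs <- t(combn(ids, 2))
    edges <- rbind(edges, edge_df(pairs[, 1], pairs[, 2], 1))
  }
  edges <- rbind(edges, edge_df("C101", "C201", bridge_weight))
  build_network(edges)
}

# Small planted-partition bundle for end-to-end runs.
small_bundle <- function(n_pos = 25, n_neg = 25, p_in = 0.25, p_out = 0.05,
                         delta = 2, seed = 7) {
  cfg <- simulation_config(n_pos = n_pos, n_neg = n_neg, p_in = p_in,
                           p_out = p_out, feature_effect = delta,
                           n_features = 10, seed = seed)
  sim <- simulate_network(cfg)
  X <- simulate_features(sim$labels, cfg)
  list(network = sim$network, features = X, labels = sim$labels)
}

# Light-weight training configuration for small fixtures.
fast_config <- function(...) {
  cfg <- run_config(max_epochs = 50L, patience = 10L, batch_size = 0L,
                    learning_rate = 5e-3, gcn_hidden = 32L,
                    embedding_dim = 32L, dnn_widths = c(32L, 16L),
                    walks_per_node = 5L, walk_length = 20L, window = 5L,
                    skipgram_iterations = 5L, k = 5L, repeats = 1L,
                    seed = 1L)
  update_config(cfg, ...)
}

# Brute-force AUROC: count positive-negative pairs, ties worth 1/2.
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Brute-force AUPR: explicit threshold sweep over distinct scores, step-wise
# area with no interpolation of precision.
aupr_oracle <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  area <- 0
  prev_rec <- 0
  for (t in thr) {
    called <- scores >= t
    tp <- sum(labels == 1 & called)
    prec <- tp / sum(called)
    rec <- tp / n_pos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# Mean pairwise Euclidean distance between rows.
mean_pairwise_dist <- function(M) {
  mean(dist(M))
}

# Run the installed command-line script in a child R process.
run_cli <- function(args) {
  script <- system.file("cli", "deeprw.R", package = "deeprw")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(shQuote(script), args), stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=",
                 shQuote(paste(.libPaths(),
                               collapse = .Platform$path.sep)))))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
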