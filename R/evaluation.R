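# Evaluation harness: repeated stratified k-fold cross-validation, ranking
# metrics (AUROC by the rank/Mann-Whitney formulation, AUPR as the area
# under the precision-recall step curve), the random-walk-with-restart
# baseline, and the ablation runners.

#' Repeated stratified k-fold assignments
#'
#' One independent stratified partition per repeat. Within each class the
#' shuffled members are split into folds whose sizes differ by at most one;
#' the folds receiving a class's remainder rotate across classes so overall
#' fold sizes also stay within one of each other.
#'
#' @param labels Named 0/1 vector.
#' @param k Number of folds (default 10).
#' @param repeats Number of independent partitions (default 10).
#' @param seed Integer seed; the same seed reproduces the assignments.
#' @return List of `repeats` fold assignments, each a list with `fold`
#'   (named integer vector in 1..k), `k`, `repeat_index`, `seed`.
#' @export
stratified_kfold <- function(labels, k = 10L, repeats = 10L, seed = 1L) {
  y <- labels[!is.na(labels)]
  stopifnot(all(y %in% c(0, 1)), k >= 2L, repeats >= 1L)
  for (cls in unique(y)) {
    if (sum(y == cls) < k)
      stop("class ", cls, " has fewer than k = ", k, " members")
  }
  withr::with_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      fold <- integer(length(y))
      names(fold) <- names(y)
      extra_off <- 0L
      for (cls in sort(unique(y))) {
        members <- sample(names(y)[y == cls])
        m <- length(members)
        base <- m %/% k
        rem <- m %% k
        sizes <- rep(base, k)
        if (rem > 0L) {
          who <- ((extra_off + seq_len(rem) - 1L) %% k) + 1L
          sizes[who] <- sizes[who] + 1L
          extra_off <- extra_off + rem
        }
        fold[members] <- rep(seq_len(k), times = sizes)
      }
      list(fold = fold, k = as.integer(k), repeat_index = r,
           seed = as.integer(seed))
    })
  })
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a uniformly chosen
#' positive outranks a uniformly chosen negative, ties counted half.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels 0/1 labels, both classes present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) stop("both classes required")
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-curve area: thresholds sweep the distinct score values from high to
#' low; the precision at each achieved recall level is accumulated against
#' the recall increment, with no linear interpolation of precision.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels 0/1 labels with at least one positive.
#' @return AUPR in `(0, 1]`.
#' @export
aupr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) stop("at least one positive required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Random walk with restart
#'
#' Network-propagation baseline: iterates
#' `p <- (1 - r) * t(P) %*% p + r * e` with `P` the row-normalized weighted
#' transition matrix and `e` uniform over the seed nodes, until the L1
#' change drops below `1e-10`. The stationary scores form a probability
#' distribution measuring proximity to the seed set.
#'
#' @param net A `gene_network`.
#' @param seed_nodes Non-empty character vector of seed node ids.
#' @param restart_prob Restart probability in `(0, 1]` (default 0.5).
#' @return Named numeric vector of scores over all nodes (sums to 1).
#' @export
rwr_scores <- function(net, seed_nodes, restart_prob = 0.5) {
  validate_gene_network(net)
  if (length(seed_nodes) == 0L) stop("no seed nodes")
  if (!all(seed_nodes %in% net$node_ids))
    stop("unknown seed node: ",
         setdiff(seed_nodes, net$node_ids)[1L])
  stopifnot(restart_prob > 0, restart_prob <= 1)
  A <- net$adjacency
  P <- A / rowSums(A)
  n <- length(net$node_ids)
  e <- numeric(n)
  e[match(unique(seed_nodes), net$node_ids)] <- 1 / length(unique(seed_nodes))
  p <- e
  tP <- t(P)
  for (it in seq_len(100000L)) {
    p_new <- (1 - restart_prob) * drop(tP %*% p) + restart_prob * e
    if (sum(abs(p_new - p)) < 1e-10) {
      p <- p_new
      break
    }
    p <- p_new
  }
  names(p) <- net$node_ids
  p
}

#' Percentage difference relative to a reference
#'
#' `100 * (reference - other) / reference`; positive when `other` is below
#' the reference.
#'
#' @param reference Positive reference value.
#' @param other Comparison value.
#' @return Percentage.
#' @export
relative_difference <- function(reference, other) {
  if (!is.finite(reference) || reference <= 0)
    stop("reference must be positive")
  100 * (reference - other) / reference
}

cv_methods <- c("deepRW", "withoutGCN", "withoutDeepWalk", "dnnOnly", "rwr")

method_branches <- function(method) {
  switch(method,
         deepRW = c("deepwalk", "gcn"),
         withoutGCN = "deepwalk",
         withoutDeepWalk = "gcn",
         dnnOnly = "raw",
         rwr = NULL)
}

#' Repeated cross-validated evaluation of one method
#'
#' For each repeat and fold, trains on the remaining folds (the RWR baseline
#' instead uses the training-fold positives as seeds and needs no training),
#' scores the held-out fold and computes AUROC and AUPR. The deep-walk
#' embedding is unsupervised (graph-only), so it is computed once per call
#' and shared across folds. Reported means are arithmetic means over all
#' folds of all repeats.
#'
#' @param method One of `"deepRW"` (full model), `"withoutGCN"` (deep walk
#'   only), `"withoutDeepWalk"` (GCN only), `"dnnOnly"` (features straight
#'   into the classifier) or `"rwr"`.
#' @param bundle List with `network` (a `gene_network`), `features`
#'   (node-feature matrix) and `labels` (named 0/1 vector).
#' @param config A [run_config()].
#' @return Object of class `eval_report`: `method`, `folds` (data frame with
#'   `rep`, `fold`, `auroc`, `aupr`), `mean_auroc`, `mean_aupr`.
#' @export
run_cv <- function(method = cv_methods, bundle, config = run_config()) {
  method <- match.arg(method, cv_methods)
  stopifnot(inherits(config, "run_config"))
  net <- bundle$network
  validate_gene_network(net)
  labels <- bundle$labels[!is.na(bundle$labels)]
  stopifnot(all(names(labels) %in% net$node_ids))

  dw <- NULL
  if (method %in% c("deepRW", "withoutGCN")) {
    corpus <- generate_walks(net, config$walks_per_node, config$walk_length,
                             seed = config$seed)
    dw <- train_skipgram(corpus, dim = config$embedding_dim,
                         window = config$window,
                         iterations = config$skipgram_iterations,
                         seed = config$seed, negative = config$negative)
  }

  assignments <- stratified_kfold(labels, k = config$k,
                                  repeats = config$repeats,
                                  seed = config$seed)
  rows <- list()
  for (asg in assignments) {
    for (f in seq_len(asg$k)) {
      test_nodes <- names(asg$fold)[asg$fold == f]
      train_labels <- labels[setdiff(names(labels), test_nodes)]
      if (method == "rwr") {
        seeds <- names(train_labels)[train_labels == 1]
        sc <- rwr_scores(net, seeds, config$restart_prob)
        scores <- sc[test_nodes]
      } else {
        fold_cfg <- update_config(config,
                                  seed = derive_seed(config$seed,
                                                     asg$repeat_index, f))
        model <- train_model(net, features = bundle$features, dw = dw,
                             labels = train_labels, cfg = fold_cfg,
                             branches = method_branches(method))
        pr <- predict(model, test_nodes)
        scores <- pr$probability_positive
      }
      y_test <- labels[test_nodes]
      rows[[length(rows) + 1L]] <-
        data.frame(rep = asg$repeat_index, fold = f,
                   auroc = auroc(scores, y_test),
                   aupr = aupr(scores, y_test))
    }
  }
  folds <- do.call(rbind, rows)
  structure(list(method = method, folds = folds,
                 mean_auroc = mean(folds$auroc),
                 mean_aupr = mean(folds$aupr)),
            class = "eval_report")
}

#' @exportS3Method base::print
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report [%s]: %d folds, mean AUROC %.4f, mean AUPR %.4f\n",
              x$method, nrow(x$folds), x$mean_auroc, x$mean_aupr))
  invisible(x)
}

#' GCN depth ablation
#'
#' Runs [run_cv()] for the full model at each GCN depth. Three layers is the
#' package default; deeper stacks over-smooth.
#'
#' @param bundle Data bundle as in [run_cv()].
#' @param depths Integer vector of GCN depths (default `c(2, 3, 4)`).
#' @param config A [run_config()].
#' @return Named list of `eval_report`, one per depth.
#' @export
layer_ablation <- function(bundle, depths = c(2L, 3L, 4L),
                           config = run_config()) {
  out <- lapply(depths, function(d) {
    run_cv("deepRW", bundle, update_config(config, gcn_layers = d))
  })
  names(out) <- paste0("layers_", depths)
  out
}
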