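# Run configuration: every tunable hyperparameter of the pipeline with its
# default, validated on construction. Unknown names are rejected so typos in
# configuration fail loudly.

#' Pipeline configuration
#'
#' Collects the hyperparameters of all stages. Defaults follow the method's
#' stated protocol where one exists (skip-gram window 10 trained for 10
#' iterations; a 3-layer GCN; 10-fold cross-validation repeated 10 times;
#' Adam with default moments) and common practice elsewhere (10 walks of
#' length 40 per node, 64-dimensional embeddings, feed-forward widths 64 and
#' 32, restart probability 0.5 for the random-walk-with-restart baseline).
#'
#' The training protocol as printed ("50 epochs" alongside "stop after 50
#' epochs without improvement") would make the early stop inert; the default
#' here is `max_epochs = 200` with `patience = 50` on validation loss, and
#' setting `max_epochs = 50` restores the strict printed protocol.
#'
#' @param window Skip-gram window half-width.
#' @param skipgram_iterations Passes of skip-gram training over the corpus.
#' @param walks_per_node,walk_length Random-walk corpus shape.
#' @param embedding_dim Deep-walk embedding dimension.
#' @param negative Negative samples per skip-gram pair.
#' @param gcn_layers Number of GCN layers (2-4 in the ablation; 3 default).
#' @param gcn_hidden Width of every GCN layer.
#' @param dnn_widths Hidden widths of the feed-forward head (the output
#'   layer is always 2-way softmax).
#' @param max_epochs,patience Training length and early-stopping patience,
#'   in epochs of validation-loss non-improvement.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size; `0` means full batch.
#' @param validation_fraction Fraction of the training labels held out
#'   (stratified) for early stopping.
#' @param bn_momentum Update rate of the batch-norm running statistics.
#' @param k,repeats Cross-validation folds and repetitions.
#' @param restart_prob Restart probability of the RWR baseline.
#' @param seed Integer master seed; all stage seeds derive from it.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(window = 10L, skipgram_iterations = 10L,
                       walks_per_node = 10L, walk_length = 40L,
                       embedding_dim = 64L, negative = 5L,
                       gcn_layers = 3L, gcn_hidden = 64L,
                       dnn_widths = c(64L, 32L),
                       max_epochs = 200L, patience = 50L,
                       learning_rate = 1e-3, batch_size = 32L,
                       validation_fraction = 0.1, bn_momentum = 0.1,
                       k = 10L, repeats = 10L, restart_prob = 0.5,
                       seed = 1L) {
  cfg <- list(window = as.integer(window),
              skipgram_iterations = as.integer(skipgram_iterations),
              walks_per_node = as.integer(walks_per_node),
              walk_length = as.integer(walk_length),
              embedding_dim = as.integer(embedding_dim),
              negative = as.integer(negative),
              gcn_layers = as.integer(gcn_layers),
              gcn_hidden = as.integer(gcn_hidden),
              dnn_widths = as.integer(dnn_widths),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              learning_rate = as.numeric(learning_rate),
              batch_size = as.integer(batch_size),
              validation_fraction = as.numeric(validation_fraction),
              bn_momentum = as.numeric(bn_momentum),
              k = as.integer(k), repeats = as.integer(repeats),
              restart_prob = as.numeric(restart_prob),
              seed = as.integer(seed))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  known <- c("window", "skipgram_iterations", "walks_per_node",
             "walk_length", "embedding_dim", "negative", "gcn_layers",
             "gcn_hidden", "dnn_widths", "max_epochs", "patience",
             "learning_rate", "batch_size", "validation_fraction",
             "bn_momentum", "k", "repeats", "restart_prob", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0L) stop("unknown configuration keys: ",
                               paste(extra, collapse = ", "))
  miss <- setdiff(known, names(cfg))
  if (length(miss) > 0L) stop("missing configuration keys: ",
                              paste(miss, collapse = ", "))
  stopifnot(cfg$window >= 1L, cfg$skipgram_iterations >= 0L,
            cfg$walks_per_node >= 1L, cfg$walk_length >= 2L,
            cfg$embedding_dim >= 1L, cfg$negative >= 0L,
            cfg$gcn_layers >= 1L, cfg$gcn_hidden >= 1L,
            all(cfg$dnn_widths >= 1L), cfg$max_epochs >= 1L,
            cfg$patience >= 0L, cfg$learning_rate > 0,
            cfg$batch_size >= 0L,
            cfg$validation_fraction > 0, cfg$validation_fraction <= 0.5,
            cfg$bn_momentum > 0, cfg$bn_momentum <= 1,
            cfg$k >= 2L, cfg$repeats >= 1L,
            cfg$restart_prob > 0, cfg$restart_prob <= 1)
  structure(cfg, class = "run_config")
}

#' Modify a configuration
#'
#' @param cfg A `run_config`.
#' @param ... Named fields to replace; unknown names are an error.
#' @return The modified, re-validated `run_config`.
#' @export
update_config <- function(cfg, ...) {
  stopifnot(inherits(cfg, "run_config"))
  repl <- list(...)
  for (nm in names(repl)) {
    if (!nm %in% names(cfg)) stop("unknown configuration keys: ", nm)
    cfg[[nm]] <- if (nm %in% c("learning_rate", "validation_fraction",
                               "bn_momentum", "restart_prob"))
      as.numeric(repl[[nm]]) else as.integer(repl[[nm]])
  }
  validate_run_config(unclass(cfg))
}

# Deterministic per-fold seed derivation, kept well below 2^31.
derive_seed <- function(seed, rep_i, fold_i) {
  as.integer((abs(seed) %% 100000L) * 10007L + rep_i * 103L + fold_i)
}
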