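# Prediction head: fusion of the two node representations and a small
# feed-forward classifier (affine -> batch norm -> leaky ReLU twice, then a
# 2-way softmax), trained jointly with the GCN encoder under binary
# cross-entropy with Adam and validation-loss early stopping. The deep-walk
# embedding is trained separately and enters frozen.

#' Fuse two node representations
#'
#' Per-node concatenation of the deep-walk and GCN representations (or any
#' two embeddings over the same node order).
#'
#' @param dw,gc Numeric matrices with identical node-id rownames in the same
#'   order; `gc` may have zero columns, in which case `dw` is returned.
#' @return Matrix with `ncol(dw) + ncol(gc)` columns.
#' @export
fuse <- function(dw, gc) {
  stopifnot(is.matrix(dw), is.matrix(gc))
  if (ncol(gc) == 0L) return(dw)
  if (ncol(dw) == 0L) return(gc)
  if (nrow(dw) != nrow(gc) ||
      !identical(rownames(dw), rownames(gc)))
    stop("node-order mismatch between representations")
  cbind(dw, gc)
}

#' Initialize feed-forward classifier parameters
#'
#' Glorot-uniform weights, zero biases, unit batch-norm scale.
#'
#' @param n_in Input (fused) dimension.
#' @param widths Hidden widths (default `c(64, 32)`).
#' @param n_classes Output classes (2).
#' @param seed Integer seed.
#' @return Object of class `dnn_params`.
#' @export
init_dnn_params <- function(n_in, widths = c(64L, 32L), n_classes = 2L,
                            seed = 1L) {
  dims <- c(n_in, widths, n_classes)
  withr::with_seed(seed, {
    Ws <- lapply(seq_len(length(dims) - 1L),
                 function(l) glorot(dims[l], dims[l + 1L]))
    bs <- lapply(dims[-1L], function(d) numeric(d))
    structure(list(layer_weights = Ws, layer_biases = bs,
                   widths = as.integer(widths),
                   n_classes = as.integer(n_classes),
                   bn = list(gamma = lapply(widths, function(w) rep(1, w)),
                             beta = lapply(widths, function(w) rep(0, w)),
                             running_mean = lapply(widths,
                                                   function(w) rep(0, w)),
                             running_var = lapply(widths,
                                                  function(w) rep(1, w))),
                   negative_slope = 0.2),
              class = "dnn_params")
  })
}

dnn_params_to_flat <- function(params) {
  out <- list()
  nh <- length(params$widths)
  for (l in seq_len(nh + 1L)) {
    out[[paste0("W", l)]] <- params$layer_weights[[l]]
    out[[paste0("b", l)]] <- params$layer_biases[[l]]
  }
  for (l in seq_len(nh)) {
    out[[paste0("g", l)]] <- params$bn$gamma[[l]]
    out[[paste0("be", l)]] <- params$bn$beta[[l]]
  }
  out
}

#' Feed-forward classifier forward pass
#'
#' Per hidden layer: affine transform, batch normalization, leaky ReLU;
#' output layer: affine then softmax, so every row of the result sums to 1.
#' In inference mode (`training = FALSE`) batch normalization uses the
#' stored running statistics and repeated calls are identical; in training
#' mode the statistics of the given batch are used.
#'
#' @param fused Fused representation matrix (rows = nodes/samples).
#' @param params A `dnn_params`.
#' @param training Logical flag selecting batch vs running statistics.
#' @return Class-probability matrix (n x 2); column 2 is the positive class.
#' @export
dnn_forward <- function(fused, params, training = FALSE) {
  stopifnot(inherits(params, "dnn_params"))
  fused <- as.matrix(fused)
  if (ncol(fused) != nrow(params$layer_weights[[1L]]))
    stop("shape mismatch: classifier expects ",
         nrow(params$layer_weights[[1L]]), " inputs, got ", ncol(fused))
  arch <- list(dnn_widths = params$widths, n_classes = params$n_classes,
               negative_slope = params$negative_slope, bn_eps = 1e-5,
               bn_momentum = 0.1)
  state <- list(rm = params$bn$running_mean, rv = params$bn$running_var)
  fwd <- dnn_head_forward(dnn_params_to_flat(params), arch, fused,
                          training = training, state = state)
  probs <- softmax_rows(fwd$logits)
  rownames(probs) <- rownames(fused)
  probs
}

#' Binary cross-entropy
#'
#' `-y log(p) - (1 - y) log(1 - p)`, averaged over the batch, with `p`
#' clipped to `[eps, 1 - eps]` so the logarithm never sees 0.
#'
#' @param y 0/1 labels.
#' @param p Predicted positive-class probabilities.
#' @param eps Clipping constant (default `1e-7`).
#' @return Non-negative scalar (mean over the batch).
#' @export
bce_loss <- function(y, p, eps = 1e-7) {
  stopifnot(length(y) == length(p), all(y %in% c(0, 1)),
            all(p >= 0 & p <= 1))
  p <- pmin(pmax(p, eps), 1 - eps)
  mean(-y * log(p) - (1 - y) * log(1 - p))
}

#' Train the fused model
#'
#' Jointly optimizes the GCN encoder and the feed-forward head under mean
#' binary cross-entropy with Adam, early-stopping on the loss of a
#' held-out stratified validation split and returning the parameters of the
#' best validation epoch. The deep-walk embedding is frozen input. Which
#' representations feed the classifier is controlled by `branches`,
#' supporting the ablations: `c("deepwalk", "gcn")` is the full model,
#' `"deepwalk"` drops the GCN, `"gcn"` drops the deep walk, and `"raw"`
#' feeds the node features straight into the classifier.
#'
#' @param net A `gene_network`.
#' @param features Node-feature matrix with node-id rownames covering the
#'   network (required for the `gcn` and `raw` branches).
#' @param dw Deep-walk embedding matrix with node-id rownames (required for
#'   the `deepwalk` branch).
#' @param labels Named 0/1 vector over a subset of the network's nodes.
#' @param cfg A [run_config()].
#' @param branches Character subset of `c("deepwalk", "gcn", "raw")`.
#' @return Object of class `deeprw_model` holding the trained parameters,
#'   batch-norm state, training log (`epoch`, `train_loss`, `val_loss`) and
#'   everything needed to score any node of the network.
#' @export
train_model <- function(net, features = NULL, dw = NULL, labels,
                        cfg = run_config(),
                        branches = c("deepwalk", "gcn")) {
  validate_gene_network(net)
  stopifnot(inherits(cfg, "run_config"))
  branches <- match.arg(branches, c("deepwalk", "gcn", "raw"),
                        several.ok = TRUE)
  ids <- net$node_ids
  y <- labels[!is.na(labels)]
  if (!all(names(y) %in% ids)) stop("labelled node not in network: ",
                                    setdiff(names(y), ids)[1L])
  if (length(unique(y)) < 2L) stop("degenerate training set")
  stopifnot(all(y %in% c(0, 1)))

  X <- NULL
  if (any(c("gcn", "raw") %in% branches)) {
    if (is.null(features)) stop("branches ", paste(branches, collapse = "+"),
                                " require node features")
    if (!all(ids %in% rownames(features)))
      stop("features missing for some network nodes")
    X <- as.matrix(features)[ids, , drop = FALSE]
    stopifnot(all(is.finite(X)))
  }
  DW <- NULL
  if ("deepwalk" %in% branches) {
    if (is.null(dw)) stop("deepwalk branch requires an embedding matrix")
    if (!all(ids %in% rownames(dw)))
      stop("deep-walk embedding missing for some network nodes")
    DW <- as.matrix(dw)[ids, , drop = FALSE]
    stopifnot(all(is.finite(DW)))
  }

  S <- Matrix::Matrix(normalize_adjacency(net)$matrix, sparse = TRUE)
  arch <- list(branches = branches,
               n_features = if (is.null(X)) 0L else ncol(X),
               dw_dim = if (is.null(DW)) 0L else ncol(DW),
               gcn_hidden = rep(cfg$gcn_hidden, cfg$gcn_layers),
               dnn_widths = cfg$dnn_widths, n_classes = 2L,
               negative_slope = 0.2, bn_eps = 1e-5,
               bn_momentum = cfg$bn_momentum)
  inputs <- list(S = S, X = X, dw = DW)
  idx_lab <- match(names(y), ids)
  fit <- train_joint(inputs, arch, idx_lab, as.integer(y), cfg)
  structure(list(params = fit$params, state = fit$state, arch = arch,
                 inputs = inputs, node_ids = ids, labels = y,
                 log = fit$log, best_epoch = fit$best_epoch, cfg = cfg),
            class = "deeprw_model")
}

#' @exportS3Method base::print
print.deeprw_model <- function(x, ...) {
  cat("deeprw_model [", paste(x$arch$branches, collapse = " + "), "] over",
      length(x$node_ids), "nodes; best epoch", x$best_epoch, "\n")
  invisible(x)
}

#' Score nodes with a trained model
#'
#' @param object A `deeprw_model`.
#' @param nodes Node ids to score (default: all network nodes).
#' @param ... Unused.
#' @return A data frame with `node_id`, `probability_positive` (softmax
#'   positive-class probability) and `label` (1 when the probability is at
#'   least 0.5, so an exact tie goes to the positive class).
#' @export
predict.deeprw_model <- function(object, nodes = NULL, ...) {
  if (is.null(nodes)) nodes <- object$node_ids
  idx <- match(nodes, object$node_ids)
  if (anyNA(idx)) stop("unknown node: ", nodes[which(is.na(idx))[1L]])
  probs <- joint_eval(object$params, object$arch, object$inputs,
                      object$state, idx)
  p <- probs[, 2L]
  data.frame(node_id = nodes, probability_positive = p,
             label = as.integer(p >= 0.5), row.names = NULL,
             stringsAsFactors = FALSE)
}
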