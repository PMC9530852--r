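# DeepWalk branch: weighted truncated random walks over the network and
# skip-gram training of per-node embedding vectors on the walk corpus.

#' Transition distribution of the weighted random walk
#'
#' At each step the walker moves to a neighbor with probability proportional
#' to the incident edge weight.
#'
#' @param net A `gene_network`.
#' @param v A node id.
#' @return A named probability vector over the neighbors of `v` (sums to 1).
#' @export
transition_distribution <- function(net, v) {
  stopifnot(inherits(net, "gene_network"))
  if (!v %in% net$node_ids) stop("unknown node: ", v)
  w <- net$adjacency[v, ]
  nb <- w > 0
  w[nb] / sum(w[nb])
}

#' Generate a corpus of weighted random walks
#'
#' Starts `walks_per_node` truncated first-order walks at every node (no
#' restarts, no second-order bias); each step follows
#' [transition_distribution()]. The same seed always yields the identical
#' corpus.
#'
#' @param net A `gene_network`.
#' @param walks_per_node Walks started at each node (default 10).
#' @param walk_length Number of nodes per walk, at least 2 (default 40).
#' @param seed Integer seed.
#' @return An object of class `walk_corpus`: list with `walks` (list of
#'   character vectors of node ids), `walk_length`, `walks_per_node`, `seed`
#'   and `node_ids` (the network node order).
#' @export
generate_walks <- function(net, walks_per_node = 10L, walk_length = 40L,
                           seed = 1L) {
  validate_gene_network(net)
  stopifnot(walk_length >= 2L, walks_per_node >= 1L)
  ids <- net$node_ids
  n <- length(ids)
  nbrs <- vector("list", n)
  cw <- vector("list", n)
  for (i in seq_len(n)) {
    w <- net$adjacency[i, ]
    j <- which(w > 0)
    nbrs[[i]] <- j
    cw[[i]] <- cumsum(w[j]) / sum(w[j])
  }
  walks <- withr::with_seed(seed, {
    out <- vector("list", n * walks_per_node)
    k <- 0L
    for (pass in seq_len(walks_per_node)) {
      for (start in seq_len(n)) {
        wk <- integer(walk_length)
        wk[1L] <- start
        cur <- start
        for (t in 2:walk_length) {
          r <- runif(1L)
          cur <- nbrs[[cur]][findInterval(r, cw[[cur]]) + 1L]
          wk[t] <- cur
        }
        k <- k + 1L
        out[[k]] <- ids[wk]
      }
    }
    out
  })
  structure(list(walks = walks, walk_length = as.integer(walk_length),
                 walks_per_node = as.integer(walks_per_node),
                 seed = as.integer(seed), node_ids = ids),
            class = "walk_corpus")
}

#' @exportS3Method base::print
print.walk_corpus <- function(x, ...) {
  cat("walk_corpus:", length(x$walks), "walks of length", x$walk_length,
      "over", length(x$node_ids), "nodes\n")
  invisible(x)
}

#' Check that every step of every walk follows an edge
#'
#' @param corpus A `walk_corpus`.
#' @param net The source `gene_network`.
#' @return `TRUE` invisibly; error if any consecutive pair is not an edge.
#' @export
validate_walk_corpus <- function(corpus, net) {
  stopifnot(inherits(corpus, "walk_corpus"))
  A <- net$adjacency
  for (wk in corpus$walks) {
    i <- match(wk, net$node_ids)
    if (anyNA(i)) stop("walk visits node outside the network")
    if (length(i) > 1L && any(A[cbind(i[-length(i)], i[-1L])] <= 0))
      stop("walk step is not an edge")
  }
  invisible(TRUE)
}

#' Full-softmax skip-gram loss at one walk position
#'
#' Reference objective of the embedding: the negative log-probability of the
#' context nodes inside the window around a center node, with
#' `P(context | center)` the softmax over inner products of node vectors.
#' Used as a probe to verify that training reduces the objective; the trainer
#' itself uses the standard negative-sampling estimator.
#'
#' @param model A list with `vectors` (numeric matrix, rownames = node ids)
#'   and `window` (positive integer), as returned by [train_skipgram()] via
#'   its attributes or assembled by hand.
#' @param walk Character vector of node ids.
#' @param center_index Position of the center node within `walk`.
#' @return Non-negative scalar loss.
#' @export
skipgram_loss <- function(model, walk, center_index) {
  V <- model$vectors
  W <- model$window
  stopifnot(is.matrix(V), !is.null(rownames(V)), W >= 1L,
            center_index >= 1L, center_index <= length(walk))
  ctx <- seq(max(1L, center_index - W), min(length(walk), center_index + W))
  ctx <- ctx[ctx != center_index]
  vi <- V[walk[center_index], ]
  logits <- drop(V %*% vi)
  logz <- max(logits) + log(sum(exp(logits - max(logits))))
  logp <- logits - logz
  -sum(logp[match(walk[ctx], rownames(V))])
}

#' Train skip-gram node embeddings on a walk corpus
#'
#' Standard skip-gram with negative sampling over the walk corpus: each
#' (center, context) pair inside a sliding window contributes one positive
#' and `negative` sampled updates; the unigram noise distribution uses the
#' 3/4 power of corpus frequencies. Training is single-threaded with its own
#' seeded generator, so a fixed seed gives bit-identical embeddings.
#'
#' @param corpus A `walk_corpus` covering every network node.
#' @param dim Embedding dimension (default 64).
#' @param window Sliding-window half-width (default 10).
#' @param iterations Passes over the corpus (default 10); 0 returns the
#'   seeded initialization untouched.
#' @param seed Integer seed for initialization and sampling.
#' @param negative Negative samples per positive pair (default 5).
#' @param alpha,min_alpha Initial and floor learning rate of the linearly
#'   decayed SGD schedule.
#' @return A numeric matrix (nodes x dim) with rownames in the network node
#'   order; attributes `window` and `dim` record the configuration, and
#'   `as_skipgram_model()` wraps it for [skipgram_loss()].
#' @export
train_skipgram <- function(corpus, dim = 64L, window = 10L, iterations = 10L,
                           seed = 1L, negative = 5L, alpha = 0.025,
                           min_alpha = 1e-4) {
  stopifnot(inherits(corpus, "walk_corpus"), length(corpus$walks) > 0L,
            dim >= 1L, window >= 1L, iterations >= 0L, negative >= 0L)
  ids <- corpus$node_ids
  seen <- unique(unlist(corpus$walks, use.names = FALSE))
  miss <- setdiff(ids, seen)
  if (length(miss) > 0L)
    stop("node missing from corpus: ", miss[1L])
  walks0 <- lapply(corpus$walks, function(wk) match(wk, ids) - 1L)
  V <- sgns_train(walks0, length(ids), as.integer(dim), as.integer(window),
                  as.integer(iterations), as.integer(negative),
                  as.numeric(alpha), as.numeric(min_alpha), as.integer(seed))
  rownames(V) <- ids
  attr(V, "window") <- as.integer(window)
  V
}

#' Wrap an embedding matrix for the probe loss
#'
#' @param vectors Numeric matrix with node-id rownames.
#' @param window Window half-width; defaults to the `window` attribute.
#' @return A list usable as the `model` argument of [skipgram_loss()].
#' @export
as_skipgram_model <- function(vectors, window = attr(vectors, "window")) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)),
            !is.null(window))
  list(vectors = vectors, window = as.integer(window))
}
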