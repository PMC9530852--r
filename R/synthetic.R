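# Synthetic data generator. Emulates the statistical structure the method
# assumes: disease genes are more densely interconnected than chance
# (planted-partition network, the guilt-by-association premise) and node
# features carry a label-correlated signal (a stand-in for tissue-expression
# profiles). Defaults mirror the 142-positive / 142-negative study design.

#' Simulation configuration
#'
#' @param n_pos,n_neg Number of positive (disease) and negative genes
#'   (default 142 each, matching the study design size).
#' @param p_in,p_out Within-class and between-class edge probabilities
#'   (defaults 0.10 and 0.02: a clear but not extreme homophily signal).
#' @param weight_dist Function `n -> n` positive edge weights; default
#'   uniform on (0, 1], the scale of probabilistic functional-association
#'   scores.
#' @param n_features Number of node features (default 30).
#' @param feature_effect Class separation per feature, in units of
#'   `noise_sd` (default 1.5).
#' @param noise_sd Feature noise standard deviation (default 1).
#' @param seed Integer seed.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_pos = 142L, n_neg = 142L, p_in = 0.10,
                              p_out = 0.02, weight_dist = function(n)
                                stats::runif(n, .Machine$double.eps, 1),
                              n_features = 30L, feature_effect = 1.5,
                              noise_sd = 1, seed = 1L) {
  cfg <- list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
              p_in = as.numeric(p_in), p_out = as.numeric(p_out),
              weight_dist = weight_dist, n_features = as.integer(n_features),
              feature_effect = as.numeric(feature_effect),
              noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  stopifnot(cfg$n_pos >= 10L, cfg$n_neg >= 10L,
            cfg$p_in >= 0, cfg$p_in <= 1, cfg$p_out >= 0, cfg$p_out <= 1,
            is.function(cfg$weight_dist), cfg$n_features >= 1L,
            cfg$noise_sd > 0)
  structure(cfg, class = "simulation_config")
}

#' Simulate a planted-partition gene network with labels
#'
#' Each same-class gene pair is connected with probability `p_in`, each
#' cross-class pair with probability `p_out`; edge weights are drawn from
#' `weight_dist`. Genes left isolated are re-wired to one random same-class
#' partner so the network invariant (no isolated node) holds; with
#' `rewire_isolated = FALSE` isolated genes are simply dropped by network
#' construction.
#'
#' @param cfg A [simulation_config()].
#' @param rewire_isolated Re-wire isolated genes instead of losing them
#'   (default `TRUE`).
#' @return List with `network` (a `gene_network`) and `labels` (named 0/1
#'   vector over the network's nodes; 1 = disease gene).
#' @export
simulate_network <- function(cfg, rewire_isolated = TRUE) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_pos + cfg$n_neg
  ids <- sprintf("G%04d", seq_len(n))
  z <- c(rep(1L, cfg$n_pos), rep(0L, cfg$n_neg))
  names(z) <- ids
  withr::with_seed(cfg$seed, {
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same <- z[ut[, 1L]] == z[ut[, 2L]]
    p <- ifelse(same, cfg$p_in, cfg$p_out)
    drawn <- runif(nrow(ut)) < p
    i <- ut[drawn, 1L]
    j <- ut[drawn, 2L]
    w <- cfg$weight_dist(length(i))
    if (rewire_isolated) {
      deg <- tabulate(c(i, j), nbins = n)
      for (v in which(deg == 0L)) {
        mates <- setdiff(which(z == z[v]), v)
        u <- mates[sample.int(length(mates), 1L)]
        i <- c(i, min(v, u)); j <- c(j, max(v, u))
        w <- c(w, cfg$weight_dist(1L))
        deg[v] <- deg[v] + 1L; deg[u] <- deg[u] + 1L
      }
    }
    edges <- data.frame(gene_a = ids[i], gene_b = ids[j], weight = w,
                        stringsAsFactors = FALSE)
    net <- build_network(edges)
    list(network = net, labels = z[net$node_ids])
  })
}

#' Simulate label-correlated node features
#'
#' Feature `j` of gene `i` is drawn from
#' `Normal(effect * z_i * s_j, noise_sd^2)` with `z_i` the 0/1 label and
#' `s_j` a fixed random sign per feature; `feature_effect = 0` gives pure
#' label-independent noise.
#'
#' @param labels Named 0/1 vector (as returned by [simulate_network()]).
#' @param cfg A [simulation_config()].
#' @return Numeric matrix (genes x features) with node-id rownames in the
#'   label order and feature names `F001...`.
#' @export
simulate_features <- function(labels, cfg) {
  stopifnot(inherits(cfg, "simulation_config"), all(labels %in% c(0, 1)))
  n <- length(labels)
  withr::with_seed(cfg$seed + 1L, {
    s <- sample(c(-1, 1), cfg$n_features, replace = TRUE)
    X <- cfg$feature_effect * outer(as.numeric(labels), s) +
      matrix(rnorm(n * cfg$n_features, sd = cfg$noise_sd), n,
             cfg$n_features)
    dimnames(X) <- list(names(labels),
                        sprintf("F%03d", seq_len(cfg$n_features)))
    X
  })
}

#' Write a simulated dataset as plain-text fixtures
#'
#' Writes `edges.tsv` (via [write_edge_list()]), `positives.txt` and
#' `negatives.txt` (one gene id per line) and `features.tsv` (tab-separated,
#' header row of feature names, first column `node_id`). The files
#' round-trip losslessly through the package readers and are
#' byte-deterministic given fixed inputs.
#'
#' @param dir Output directory (created if absent).
#' @param net A `gene_network`.
#' @param labels Named 0/1 vector.
#' @param features Feature matrix with node-id rownames.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dir, net, labels, features) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  write_edge_list(net, file.path(dir, "edges.tsv"))
  write_lines_lf(sort(names(labels)[labels == 1]),
                 file.path(dir, "positives.txt"))
  write_lines_lf(sort(names(labels)[labels == 0]),
                 file.path(dir, "negatives.txt"))
  X <- as.matrix(features)
  ord <- order(rownames(X))
  X <- X[ord, , drop = FALSE]
  lines <- c(paste(c("node_id", colnames(X)), collapse = "\t"),
             vapply(seq_len(nrow(X)), function(i)
               paste(c(rownames(X)[i], sprintf("%.17g", X[i, ])),
                     collapse = "\t"), character(1)))
  write_lines_lf(lines, file.path(dir, "features.tsv"))
  invisible(dir)
}

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
}

#' Read a gene list (one id per line)
#'
#' @param path File path; blank lines and `#` comments ignored.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a tab-separated feature table
#'
#' First column `node_id`, remaining columns numeric features, header row
#' required.
#'
#' @param path File path.
#' @return Numeric matrix with node-id rownames.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "")
  X <- as.matrix(df[, -1L, drop = FALSE])
  rownames(X) <- df[[1L]]
  storage.mode(X) <- "double"
  X
}
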