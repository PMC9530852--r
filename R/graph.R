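# Weighted undirected gene network: construction, Laplacian and the
# symmetrically normalized augmented adjacency used by the GCN encoder.

#' Build a weighted undirected gene network from an edge list
#'
#' Collapses duplicate/reciprocal records, drops zero-weight records, removes
#' genes left without any incident edge, and fixes a deterministic
#' (lexicographic) node ordering that every downstream matrix, embedding and
#' prediction uses.
#'
#' @param edges A data frame (or coercible) with three columns: `gene_a`,
#'   `gene_b`, `weight`. Weights must be finite and non-negative; weights are
#'   functional-association scores and are used as-is, never rescaled.
#' @return An object of class `gene_network` with elements `node_ids`
#'   (sorted character vector), `adjacency` (dense symmetric matrix with
#'   zero diagonal, dimnames = node ids) and `edge_count`.
#' @details Self-edges in the input are an error: unit self-loops enter only
#'   through [augment_adjacency()]. Two records for the same gene pair with
#'   different weights are an error rather than silently averaged, so dirty
#'   input fails loudly; equal-weight duplicates (files often list both
#'   directions) are tolerated.
#' @examples
#' net <- build_network(data.frame(gene_a = c("A", "B"),
#'                                 gene_b = c("B", "C"),
#'                                 weight = c(0.5, 0.7)))
#' net$node_ids
#' @export
build_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 3L) stop("edge list needs columns gene_a, gene_b, weight")
  names(edges)[1:3] <- c("gene_a", "gene_b", "weight")
  if (nrow(edges) == 0L) stop("empty network")
  a <- as.character(edges$gene_a)
  b <- as.character(edges$gene_b)
  w <- as.numeric(edges$weight)
  if (any(is.na(a) | is.na(b) | !nzchar(a) | !nzchar(b)))
    stop("gene identifiers must be non-empty strings")
  if (any(!is.finite(w)) || any(w < 0))
    stop("edge weights must be finite and non-negative")
  if (any(a == b)) stop("self-edge in input: ", a[which(a == b)[1L]])

  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    ws <- w[key == k]
    if (length(unique(ws)) > 1L)
      stop("conflicting edge weight for pair ",
           sub("\r", " - ", k, fixed = TRUE))
  }
  keep <- !duplicated(key)
  lo <- lo[keep]; hi <- hi[keep]; w <- w[keep]
  pos <- w > 0
  lo <- lo[pos]; hi <- hi[pos]; w <- w[pos]
  if (length(w) == 0L) stop("empty network")

  ids <- sort(unique(c(lo, hi)))
  n <- length(ids)
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(lo, ids)
  j <- match(hi, ids)
  adj[cbind(i, j)] <- w
  adj[cbind(j, i)] <- w
  structure(list(node_ids = ids, adjacency = adj, edge_count = length(w)),
            class = "gene_network")
}

#' @exportS3Method base::print
print.gene_network <- function(x, ...) {
  cat("gene_network:", length(x$node_ids), "nodes,", x$edge_count, "edges\n")
  invisible(x)
}

validate_gene_network <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  adj <- net$adjacency
  stopifnot(isSymmetric(unname(adj)), all(adj >= 0), all(diag(adj) == 0),
            all(rowSums(adj) > 0), !anyDuplicated(net$node_ids))
  invisible(net)
}

#' Weighted graph Laplacian
#'
#' Returns `L = D - A` where `D` is the diagonal matrix of weighted degrees.
#' Row sums of `L` are zero. The Laplacian is provided as a standard view of
#' the network; the GCN propagation itself uses [normalize_adjacency()].
#'
#' @param net A `gene_network`.
#' @return A symmetric numeric matrix with zero row sums.
#' @export
laplacian <- function(net) {
  validate_gene_network(net)
  A <- net$adjacency
  diag(rowSums(A)) - A
}

#' Adjacency with unit self-loops
#'
#' Returns `A' = A + I`. The self-loop weight is exactly 1 regardless of the
#' scale of the edge weights, so each node's own features always enter its
#' convolved representation.
#'
#' @param net A `gene_network`.
#' @return A symmetric numeric matrix with unit diagonal.
#' @export
augment_adjacency <- function(net) {
  validate_gene_network(net)
  A <- net$adjacency
  diag(A) <- 1
  A
}

#' Symmetrically normalized augmented adjacency
#'
#' Computes `D'^(-1/2) A' D'^(-1/2)` with `A' = A + I` and `D'` the diagonal
#' matrix of row sums of `A'`. This is the propagation operator applied at
#' every layer of the GCN encoder; it is symmetric, non-negative, and has
#' spectral radius at most 1.
#'
#' @param net A `gene_network`.
#' @return An object of class `normalized_adjacency`: a list with `matrix`
#'   (dense symmetric matrix) and `node_ids`.
#' @export
normalize_adjacency <- function(net) {
  Ap <- augment_adjacency(net)
  d <- rowSums(Ap)
  if (any(d <= 0)) stop("zero row sum in augmented adjacency")
  s <- 1 / sqrt(d)
  S <- Ap * outer(s, s)
  structure(list(matrix = S, node_ids = net$node_ids),
            class = "normalized_adjacency")
}

#' @exportS3Method base::print
print.normalized_adjacency <- function(x, ...) {
  cat("normalized_adjacency over", length(x$node_ids), "nodes\n")
  invisible(x)
}

#' Read a tab-separated weighted edge list
#'
#' Three columns (`gene_a`, `gene_b`, `weight`), tab-separated; lines starting
#' with `#` (such as an optional header) are ignored. HumanNet-style flat
#' files parse under this reader.
#'
#' @param path Path to the file.
#' @return A data frame with columns `gene_a`, `gene_b`, `weight`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          header = FALSE, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"),
                          col.names = c("gene_a", "gene_b", "weight"),
                          quote = "")
  df
}

#' Write a network as a tab-separated edge list
#'
#' One row per undirected edge, the two gene ids sorted within the row and
#' rows sorted lexicographically, preceded by a `#`-prefixed header, so the
#' output is byte-deterministic and round-trips through [read_edge_list()]
#' and [build_network()].
#'
#' @param net A `gene_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  validate_gene_network(net)
  A <- net$adjacency
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  df <- data.frame(gene_a = net$node_ids[idx[, 1L]],
                   gene_b = net$node_ids[idx[, 2L]],
                   weight = A[idx], stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("#gene_a\tgene_b\tweight", con)
  writeLines(sprintf("%s\t%s\t%.17g", df$gene_a, df$gene_b, df$weight), con)
  invisible(path)
}
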