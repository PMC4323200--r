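#' Weighted undirected graphs
#'
#' A `weighted_graph` is the basic container of the package: a symmetric,
#' nonnegative edge-weight matrix `W` with zero diagonal over `n` labelled
#' nodes.  Heat flows along the edges at rates proportional to the weights,
#' so everything downstream (Laplacians, heat kernels, temperatures,
#' clustering) starts from this object.
#'
#' @param data either a data.frame/matrix of edges with columns
#'   (from, to, weight) — weight optional, default 1 — or a dense square
#'   numeric matrix of weights.
#' @param labels optional node labels.  For edge-list input the labels are
#'   taken from the edges themselves; for dense input they default to
#'   `1..n` (or the dimnames when present).
#' @param sym_tol relative tolerance for accepting a nearly-symmetric dense
#'   matrix; beyond it the input is rejected naming the worst pair.
#' @return an object of class `weighted_graph` with fields `n`, `labels`
#'   (character vector) and `W` (n x n numeric matrix).
#' @details Self-loop entries (diagonal weights, or edge-list rows with
#'   `from == to`) are dropped with a warning: the model has no loops, the
#'   diagonal is identically zero.  Duplicate edge-list rows for the same
#'   unordered pair must agree within `sym_tol`.
#' @export
weighted_graph <- function(data, labels = NULL, sym_tol = 1e-8) {
  if (is.data.frame(data) || (is.matrix(data) && ncol(data) <= 3 &&
                              nrow(data) != ncol(data))) {
    graph_from_edges(as.data.frame(data), sym_tol = sym_tol)
  } else if (is.matrix(data)) {
    graph_from_dense(data, labels = labels, sym_tol = sym_tol)
  } else {
    stop("`data` must be an edge data.frame or a dense numeric matrix")
  }
}

graph_from_edges <- function(edges, sym_tol = 1e-8) {
  if (nrow(edges) == 0L) stop("empty edge list")
  if (ncol(edges) < 2L) stop("edge list needs at least two columns")
  from <- as.character(edges[[1L]])
  to   <- as.character(edges[[2L]])
  w    <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else rep(1, nrow(edges))
  if (any(!is.finite(w))) stop("non-finite edge weight")
  if (any(w < 0)) stop("negative edge weight: ", w[which(w < 0)[1L]])
  loops <- from == to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped (diagonal is defined to be zero)")
    from <- from[!loops]; to <- to[!loops]; w <- w[!loops]
    if (length(from) == 0L) stop("empty edge list after dropping self-loops")
  }
  labels <- unique(c(from, to))
  if (!anyNA(suppressWarnings(as.numeric(labels)))) {
    labels <- as.character(sort(as.numeric(labels)))
  } else {
    labels <- sort(labels)
  }
  n <- length(labels)
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  i <- match(from, labels); j <- match(to, labels)
  # merge duplicates / reciprocal rows: last write wins unless they disagree
  for (e in seq_along(i)) {
    prev <- W[i[e], j[e]]
    if (prev != 0 && abs(prev - w[e]) > sym_tol * max(1, abs(prev)))
      stop("conflicting weights for edge (", from[e], ", ", to[e], ")")
    W[i[e], j[e]] <- w[e]
    W[j[e], i[e]] <- w[e]
  }
  new_weighted_graph(n, labels, W)
}

graph_from_dense <- function(W, labels = NULL, sym_tol = 1e-8) {
  if (nrow(W) != ncol(W)) stop("dense weight matrix must be square")
  if (nrow(W) == 0L) stop("empty weight matrix")
  storage.mode(W) <- "double"
  if (any(!is.finite(W))) stop("non-finite weight")
  if (any(W < 0)) stop("negative weight in matrix")
  asym <- abs(W - t(W))
  scale <- max(1, max(abs(W)))
  if (max(asym) > sym_tol * scale) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop(sprintf("matrix not symmetric: worst pair (%d, %d), |W_ij - W_ji| = %g",
                 idx[1L], idx[2L], max(asym)))
  }
  W <- (W + t(W)) / 2
  if (any(diag(W) != 0)) {
    warning("nonzero diagonal zeroed (self-loops are not allowed)")
    diag(W) <- 0
  }
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(W))) rownames(W) else as.character(seq_len(nrow(W)))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(W)) stop("labels length does not match matrix size")
  dimnames(W) <- list(labels, labels)
  new_weighted_graph(nrow(W), labels, W)
}

new_weighted_graph <- function(n, labels, W) {
  structure(list(n = n, labels = labels, W = W), class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  ne <- sum(x$W[upper.tri(x$W)] != 0)
  cat("weighted_graph:", x$n, "nodes,", ne, "edges, total weight",
      format(sum(x$W) / 2), "\n")
  invisible(x)
}

#' Node degrees (weighted)
#' @param g a `weighted_graph`
#' @return numeric vector of row sums of `W`
#' @export
node_degrees <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  rowSums(g$W)
}

#' Graph Laplacian L = D - W
#'
#' `D` is the diagonal degree matrix with `D_ii = sum_j W_ij`; every row of
#' the result sums to zero.
#' @param g a `weighted_graph`
#' @return n x n numeric matrix
#' @export
graph_laplacian <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  L <- -g$W
  diag(L) <- rowSums(g$W)
  L
}

#' Normalized graph Laplacian
#'
#' `L_N = D^{-1/2} (D - W) D^{-1/2}`.  Symmetric with spectrum contained in
#' `[0, 2]`; its smallest eigenvalue is 0 with eigenvector proportional to
#' `sqrt(degree)` on each connected component.
#' @param g a `weighted_graph`
#' @return n x n numeric matrix
#' @details Isolated nodes (zero degree) are rejected, naming the node:
#'   `D^{-1/2}` is undefined there.  Disconnected graphs whose every node
#'   has positive degree are accepted (the zero eigenvalue then has
#'   multiplicity equal to the number of components).
#' @export
normalized_laplacian <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  d <- rowSums(g$W)
  if (any(d <= 0)) {
    bad <- g$labels[which(d <= 0)[1L]]
    stop("isolated node (zero degree): ", bad)
  }
  s <- 1 / sqrt(d)
  LN <- -(s * g$W) * rep(s, each = g$n)
  diag(LN) <- diag(LN) + 1
  LN <- (LN + t(LN)) / 2
  dimnames(LN) <- dimnames(g$W)
  LN
}

#' Gaussian affinity from a distance matrix
#'
#' Converts a pairwise distance matrix into edge weights
#' `W_ij = exp(-d_ij^2 / sigma^2)` with zero diagonal.  By default `sigma`
#' is the median off-diagonal distance — the standard self-tuning choice
#' for spectral methods.  Optionally sparsifies to a mutual k-nearest
#' neighbour graph.
#'
#' @param D symmetric nonnegative distance matrix
#' @param sigma kernel bandwidth; default median off-diagonal distance
#' @param knn if not `NULL`, keep `W_ij` only when `j` is among the `knn`
#'   nearest neighbours of `i` *and* vice versa
#' @return a `weighted_graph`
#' @export
affinity_from_distance <- function(D, sigma = NULL, knn = NULL) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (any(D < 0)) stop("negative distances")
  off <- D[upper.tri(D)]
  if (is.null(sigma)) sigma <- stats::median(off)
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1  # degenerate: all-zero distances
  W <- exp(-(D / sigma)^2)
  diag(W) <- 0
  if (!is.null(knn)) {
    n <- nrow(D)
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      ord <- order(D[i, ], seq_len(n))
      ord <- setdiff(ord, i)[seq_len(min(knn, n - 1L))]
      keep[i, ord] <- TRUE
    }
    W[!(keep & t(keep))] <- 0
  }
  graph_from_dense(W, labels = rownames(D))
}

#' Similarity matrix to weights
#'
#' A similarity matrix is used directly as edge weights after zeroing the
#' diagonal and checking symmetry/nonnegativity.
#' @param S symmetric nonnegative similarity matrix
#' @return a `weighted_graph`
#' @export
affinity_from_similarity <- function(S) {
  graph_from_dense(as.matrix(S))
}
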