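#' Spectral decomposition of a graph Laplacian
#'
#' Computes the `k` smallest eigenpairs of a symmetric Laplacian matrix,
#' eigenvalues ascending, eigenvectors with unit sum of squared entries.
#' The heat kernel, temperature, heat distance and heat coordinates are all
#' functions of this decomposition, so it is computed once and reused for
#' any diffusion time `t`.
#'
#' @param LN symmetric matrix (normalized or unnormalized Laplacian)
#' @param k number of smallest eigenpairs to retain, or `"full"`
#' @return object of class `spectral_decomposition` with fields `k`,
#'   `values` (ascending), `vectors` (n x k, columns are eigenvectors),
#'   `n`, `labels`.
#' @details Eigenvector sign is fixed so that the first entry larger than
#'   `1e-12` in absolute value is positive.  With degenerate eigenvalues the
#'   individual eigenvectors are not unique, but every quantity derived
#'   from them here (kernel, distance, temperature) is basis-invariant.
#'   Truncation trades accuracy for speed: the discarded terms decay like
#'   `exp(-lambda_k t)`, so large eigenvalues (local oscillations) matter
#'   little for cluster-scale structure.
#' @export
spectral_decompose <- function(LN, k = "full") {
  LN <- as.matrix(LN)
  n <- nrow(LN)
  if (n != ncol(LN)) stop("Laplacian must be square")
  if (max(abs(LN - t(LN))) > 1e-8 * max(1, max(abs(LN))))
    stop("Laplacian is not symmetric")
  if (identical(k, "full")) k <- n
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= n (n = ", n, ")")
  e <- eigen((LN + t(LN)) / 2, symmetric = TRUE)
  # eigen() returns values in decreasing order
  ord <- rev(seq_len(n))[seq_len(k)]
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  for (j in seq_len(k)) {
    v <- vectors[, j]
    nz <- which(abs(v) > 1e-12)
    if (length(nz) && v[nz[1L]] < 0) vectors[, j] <- -v
  }
  labels <- if (!is.null(rownames(LN))) rownames(LN) else as.character(seq_len(n))
  structure(list(k = k, values = values, vectors = vectors,
                 n = n, labels = labels),
            class = "spectral_decomposition")
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  cat("spectral_decomposition:", x$k, "of", x$n, "eigenpairs; lambda in [",
      format(min(x$values)), ",", format(max(x$values)), "]\n")
  invisible(x)
}

#' Heat kernel at diffusion time t
#'
#' `H_t(i, j) = sum_k exp(-lambda_k t) phi_k(i) phi_k(j)` over the retained
#' eigenpairs.  With the full spectrum this equals the matrix exponential
#' `expm(-t L_N)`; `H_t(i, j)` is the amount of heat at node `j` after time
#' `t` when a unit of heat is applied at node `i`.
#'
#' @param dec a `spectral_decomposition`
#' @param t diffusion time, `t >= 0`
#' @return object of class `heat_kernel` with fields `t`, `H` (n x n,
#'   symmetric), `k_used`, `labels`.
#' @export
heat_kernel <- function(dec, t) {
  stopifnot(inherits(dec, "spectral_decomposition"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("diffusion time t must be a single finite number >= 0")
  w <- exp(-dec$values * t)
  H <- dec$vectors %*% (w * t(dec$vectors))
  H <- (H + t(H)) / 2
  dimnames(H) <- list(dec$labels, dec$labels)
  structure(list(t = t, H = H, k_used = dec$k, labels = dec$labels),
            class = "heat_kernel")
}

#' @export
print.heat_kernel <- function(x, ...) {
  cat("heat_kernel: t =", x$t, ", n =", nrow(x$H), ", k_used =", x$k_used, "\n")
  invisible(x)
}

#' Average temperature of each node
#'
#' `Temp_t(i) = sum_{j != i} H_t(i, j)`: the total heat received by the rest
#' of the network when a unit of heat is applied at `i`.  Nodes with many
#' paths to the rest of the network dissipate heat faster and score higher;
#' the temperature is therefore used as the heat-center preference.
#'
#' @param hk a `heat_kernel`
#' @return named numeric vector of length n
#' @export
average_temperature <- function(hk) {
  stopifnot(inherits(hk, "heat_kernel"))
  temp <- rowSums(hk$H) - diag(hk$H)
  names(temp) <- hk$labels
  temp
}

#' Heat distance matrix
#'
#' `D_t(i, j) = H_t(i, i) + H_t(j, j) - 2 H_t(i, j)` — the kernel-induced
#' squared distance.  With the full spectrum it equals the squared Euclidean
#' distance between heat-coordinate rows.
#'
#' @param hk a `heat_kernel`
#' @return object of class `heat_distance` with field `D` (symmetric, zero
#'   diagonal) and `labels`.
#' @export
heat_distance <- function(hk) {
  stopifnot(inherits(hk, "heat_kernel"))
  d <- diag(hk$H)
  D <- outer(d, d, `+`) - 2 * hk$H
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(hk$labels, hk$labels)
  structure(list(D = D, t = hk$t, labels = hk$labels), class = "heat_distance")
}

#' Heat coordinates (diffusion embedding)
#'
#' Embeds node `i` at `Cor_t(i) = (e^{-lambda_1 t/2} phi_1(i), ...,
#' e^{-lambda_k t/2} phi_k(i))`.  Squared Euclidean distances between rows
#' reproduce the heat distance when `dim` equals the full spectrum size;
#' higher coordinates decay exponentially faster, so a few dimensions carry
#' the cluster-scale geometry.
#'
#' @param dec a `spectral_decomposition`
#' @param t diffusion time, `t >= 0`
#' @param dim embedding dimension, at most the number of retained eigenpairs
#' @return n x dim matrix with node labels as rownames
#' @export
heat_coordinates <- function(dec, t, dim = min(3L, dec$k)) {
  stopifnot(inherits(dec, "spectral_decomposition"))
  if (!is.numeric(t) || t < 0) stop("t must be >= 0")
  dim <- as.integer(dim)
  if (dim < 1L || dim > dec$k)
    stop("dim must be between 1 and the retained spectrum size (", dec$k, ")")
  scale <- exp(-dec$values[seq_len(dim)] * t / 2)
  coords <- dec$vectors[, seq_len(dim), drop = FALSE] *
    rep(scale, each = dec$n)
  rownames(coords) <- dec$labels
  colnames(coords) <- paste0("cor", seq_len(dim))
  coords
}

#' Rank nodes by heat distance to a query
#'
#' Sorts all nodes by ascending heat distance to `query`; the query itself
#' comes first (its distance is exactly zero) and ties are broken by
#' ascending node label.
#'
#' @param hd a `heat_distance`
#' @param query a node label
#' @return data.frame with columns `label` and `distance`, ordered
#' @export
rank_by_heat_distance <- function(hd, query) {
  stopifnot(inherits(hd, "heat_distance"))
  query <- as.character(query)
  qi <- match(query, hd$labels)
  if (is.na(qi)) stop("unknown query label: ", query)
  d <- hd$D[qi, ]
  lab_rank <- label_order_rank(hd$labels)
  ord <- order(d, lab_rank)
  data.frame(label = hd$labels[ord], distance = unname(d[ord]),
             stringsAsFactors = FALSE)
}

# Rank of each label in its natural order (numeric when all labels parse
# as numbers, lexicographic otherwise) — the package-wide tie-break.
label_order_rank <- function(labels) {
  num <- suppressWarnings(as.numeric(labels))
  if (!anyNA(num)) rank(num, ties.method = "first") else
    rank(labels, ties.method = "first")
}
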