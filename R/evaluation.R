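#' Accuracy index
#'
#' Fraction of elements assigned to the "correct" class after matching
#' predicted clusters to truth classes one-to-one so as to maximize the
#' total matched count (optimal assignment on the contingency table — the
#' only label-invariant reading of "correctly assigned").  Extra clusters
#' on either side stay unmatched and contribute zero.
#'
#' Note the asymmetry: `accuracy_index(pred, truth)` equals
#' `accuracy_index(truth, pred)` in value (the matching is symmetric in
#' the table) but the two arguments play different roles conceptually.
#'
#' @param pred predicted cluster labels (any atomic vector)
#' @param truth ground-truth class labels, same length
#' @return a number in `[0, 1]`
#' @export
accuracy_index <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth differ in length")
  n <- length(pred)
  if (n == 0L) stop("empty partitions")
  M <- table(factor(pred), factor(truth))
  # maximum-weight one-to-one matching, DP over column subsets
  if (ncol(M) > nrow(M)) M <- t(M)
  k2 <- ncol(M)
  if (k2 > 20L) stop("too many clusters for exact matching (> 20)")
  nstates <- bitwShiftL(1L, k2)
  dp <- rep(-Inf, nstates); dp[1L] <- 0
  for (r in seq_len(nrow(M))) {
    ndp <- dp                       # row r unmatched
    for (s in seq_len(nstates) - 1L) {
      if (!is.finite(dp[s + 1L])) next
      for (c in seq_len(k2)) {
        bit <- bitwShiftL(1L, c - 1L)
        if (bitwAnd(s, bit) == 0L) {
          v <- dp[s + 1L] + M[r, c]
          j <- bitwOr(s, bit) + 1L
          if (v > ndp[j]) ndp[j] <- v
        }
      }
    }
    dp <- ndp
  }
  max(dp) / n
}

#' Rand index
#'
#' Over all unordered element pairs, the fraction that the two partitions
#' agree on: co-clustered in both, or separated in both.  `RI = C / (C +
#' I)` with `C` the concordant and `I` the discordant pair count.
#' Symmetric in its arguments and invariant to cluster relabelling.
#'
#' @param pred,truth cluster label vectors of equal length `n >= 2`
#' @return a number in `[0, 1]`
#' @export
rand_index <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth differ in length")
  n <- length(pred)
  if (n < 2L) stop("Rand index needs at least 2 elements")
  M <- table(factor(pred), factor(truth))
  ch2 <- function(x) x * (x - 1) / 2
  a <- sum(ch2(M))                       # co-clustered in both
  b <- sum(ch2(rowSums(M))) - a          # together in pred, apart in truth
  c2 <- sum(ch2(colSums(M))) - a         # together in truth, apart in pred
  total <- ch2(n)
  (total - b - c2) / total
}

#' Quality index (normalized silhouette)
#'
#' Standard silhouette on a distance matrix: for element `i`, `a(i)` is
#' the mean distance to the other members of its own cluster, `b(i)` the
#' smallest mean distance to any other cluster, and `s(i) = (b(i) -
#' a(i)) / max(a(i), b(i))`.  Members of singleton clusters contribute
#' `s(i) = 0`.  The mean silhouette (in `[-1, 1]`, 0 for random
#' clustering) is mapped to `[0, 1]` via `(QI + 1) / 2`.
#'
#' @param D distance matrix (a `heat_distance` or a plain symmetric
#'   matrix)
#' @param pred cluster labels, length `nrow(D)`; at least 2 distinct
#'   clusters
#' @return a number in `[0, 1]`
#' @export
quality_index <- function(D, pred) {
  if (inherits(D, "heat_distance")) D <- D$D
  D <- as.matrix(D)
  n <- nrow(D)
  if (length(pred) != n) stop("labels do not match distance matrix")
  pred <- as.character(pred)
  cl <- unique(pred)
  if (length(cl) < 2L) stop("silhouette undefined for fewer than 2 clusters")
  idx <- split(seq_len(n), pred)
  sizes <- lengths(idx)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- pred[i]
    if (sizes[[own]] == 1L) { s[i] <- 0; next }
    a <- sum(D[i, idx[[own]]]) / (sizes[[own]] - 1L)
    b <- min(vapply(setdiff(names(idx), own),
                    function(k) mean(D[i, idx[[k]]]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  (mean(s) + 1) / 2
}

#' All three indices at once
#' @param pred,truth cluster label vectors
#' @param D optional distance matrix for the quality index
#' @return named list `AI`, `RI`, and `QI` (NA when `D` is missing or the
#'   prediction has a single cluster)
#' @export
evaluate_clustering <- function(pred, truth, D = NULL) {
  qi <- if (!is.null(D) && length(unique(pred)) >= 2L)
    quality_index(D, pred) else NA_real_
  list(AI = accuracy_index(pred, truth),
       RI = rand_index(pred, truth),
       QI = qi)
}
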