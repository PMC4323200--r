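# Random connected weighted graph: a random spanning tree plus extra
# random edges, weights uniform in (0.2, 1.2].  Deterministic given seed.
random_connected_graph <- function(n, seed, extra = n) {
  set.seed(seed)
  W <- matrix(0, n, n)
  perm <- sample.int(n)
  for (i in 2:n) {
    j <- perm[sample.int(i - 1L, 1L)]
    w <- stats::runif(1, 0.2, 1.2)
    W[perm[i], j] <- W[j, perm[i]] <- w
  }
  for (e in seq_len(extra)) {
    ij <- sample.int(n, 2L)
    w <- stats::runif(1, 0.2, 1.2)
    W[ij[1], ij[2]] <- W[ij[2], ij[1]] <- w
  }
  diag(W) <- 0
  weighted_graph(W)
}

# Block-structured affinity problem: within-block affinity ~win, between
# ~btw (ratio win/btw is the separation), diagonal = median preference.
# The first node of each block is a designated hub with boosted
# within-block affinities, so the optimal exemplar of every block is
# unambiguous (near-ties would test tie-breaking luck, not optimization).
block_affinity <- function(sizes, win, btw, seed) {
  set.seed(seed)
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  S <- ifelse(outer(lab, lab, "=="), win, btw)
  S <- S * matrix(stats::runif(n * n, 0.9, 1.1), n, n)
  S <- (S + t(S)) / 2
  hubs <- cumsum(c(1, sizes[-length(sizes)]))
  for (h in hubs) {
    mates <- setdiff(which(lab == lab[h]), h)
    S[h, mates] <- S[h, mates] * 1.2
    S[mates, h] <- S[h, mates]
  }
  diag(S) <- stats::median(S[upper.tri(S)])
  affinity_problem(S)
}

# Path graph 1-2-...-n with unit weights
path_graph <- function(n) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) W[i, i + 1L] <- W[i + 1L, i] <- 1
  weighted_graph(W)
}

expect_symmetric <- function(M, tol = 1e-12) {
  expect_lt(max(abs(M - t(M))), tol)
}

# fresh scratch directory for CLI file outputs
scratch_dir <- function() {
  d <- tempfile("cliwd")
  dir.create(d)
  d
}
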