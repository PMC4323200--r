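#' Zachary's karate-club network
#'
#' The classic 34-member social network observed by Wayne Zachary before
#' the club split into factions led by the instructor (node 1) and the
#' president (node 34).  Unit edge weights; node labels 1-34 follow
#' Zachary's numbering.  The 78-edge list ships with the package.
#'
#' @return a `weighted_graph` with 34 nodes
#' @export
karate_graph <- function() {
  path <- system.file("extdata", "karate.tsv", package = "heatpass",
                      mustWork = TRUE)
  read_edge_list(path)
}

#' Zachary's observed factions after the split
#'
#' Ground-truth club membership: `"1"` for the instructor's faction (node
#' 1), `"34"` for the president's (node 34), in node order 1-34.
#' @return named character vector of length 34
#' @export
karate_factions <- function() {
  instructor <- c(1:9, 11:14, 17, 18, 20, 22)
  f <- rep("34", 34)
  f[instructor] <- "1"
  names(f) <- as.character(1:34)
  f
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Planted-partition (stochastic block model) graph
#'
#' Independent Bernoulli edges: probability `p_in` within a block, `p_out`
#' between blocks.  Deterministic given `seed`.  A node that ends up with
#' zero degree is reconnected to a random node of its own block with a
#' warning, so the normalized Laplacian stays defined.
#'
#' @param block_sizes integer vector of community sizes
#' @param p_in within-block edge probability
#' @param p_out between-block edge probability, `p_out < p_in`
#' @param seed RNG seed (required)
#' @return list with `graph` (a `weighted_graph`) and `truth` (character
#'   vector of block labels, in node order)
#' @export
planted_partition_graph <- function(block_sizes, p_in, p_out, seed) {
  if (missing(seed)) stop("seed is required")
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1))
    stop("need 0 <= p_out < p_in <= 1")
  n <- sum(block_sizes)
  truth <- rep(paste0("B", seq_along(block_sizes)), block_sizes)
  with_seed(seed, {
    P <- ifelse(outer(truth, truth, `==`), p_in, p_out)
    U <- matrix(0, n, n)
    U[upper.tri(U)] <- stats::runif(n * (n - 1) / 2)
    W <- (U < P) * 1
    W[lower.tri(W)] <- 0
    W <- W + t(W)
    diag(W) <- 0
    deg <- rowSums(W)
    for (i in which(deg == 0)) {
      mates <- setdiff(which(truth == truth[i]), i)
      if (!length(mates)) mates <- setdiff(seq_len(n), i)
      j <- mates[sample.int(length(mates), 1L)]
      W[i, j] <- W[j, i] <- 1
      warning("zero-degree node ", i, " reconnected to ", j)
    }
    list(graph = graph_from_dense(W), truth = stats::setNames(truth, seq_len(n)))
  })
}

#' Default phantom parameters
#'
#' A fixed set of Gaussian blobs defining the base conformation: centers in
#' fractions of the box (relative to the box center), widths and the
#' state-2 displacement likewise in box fractions.  State 2 displaces the
#' first blob by 8% of the box along a fixed diagonal direction — small
#' enough that the two states look alike, large enough to be resolvable at
#' moderate noise.
#'
#' @return list with `centers` (8 x 3), `widths`, `amplitudes`,
#'   `displaced_blob`, `displacement` (length-3, box fractions)
#' @export
phantom_params <- function() {
  centers <- matrix(c(
     0.16,  0.05,  0.02,
    -0.14,  0.10, -0.06,
     0.04, -0.16,  0.10,
    -0.06, -0.08, -0.14,
     0.12,  0.14, -0.10,
    -0.18, -0.04,  0.08,
     0.00,  0.18,  0.14,
     0.06, -0.02, -0.02), ncol = 3, byrow = TRUE)
  list(centers = centers,
       # widths ~2-3 px on a 64-box: sharp enough to carry energy into the
       # mid-frequency band where the common-line match discriminates
       widths = c(0.030, 0.028, 0.025, 0.033, 0.023, 0.028, 0.025, 0.040),
       amplitudes = c(1.0, 0.9, 1.1, 0.8, 1.2, 0.9, 1.0, 1.4),
       displaced_blob = 1L,
       # |displacement| = 8% of the box, along the xy diagonal
       displacement = 0.08 * c(1, 1, 0) / sqrt(2))
}

#' Rasterize a phantom conformation on a cubic grid
#'
#' @param v grid side length (voxels)
#' @param state conformation `1` or `2` (state 2 applies the blob
#'   displacement of [phantom_params()])
#' @param params phantom parameter list
#' @return object of class `phantom_volume`: `grid` (v x v x v array,
#'   nonnegative), `blobs`, `state_id`
#' @export
phantom_volume <- function(v, state = 1L, params = phantom_params()) {
  centers <- params$centers
  if (state == 2L)
    centers[params$displaced_blob, ] <-
      centers[params$displaced_blob, ] + params$displacement
  ax <- (seq_len(v) - (v + 1) / 2) / v   # box-fraction coordinates
  grid <- array(0, dim = c(v, v, v))
  gx <- rep(ax, times = v * v)
  gy <- rep(rep(ax, each = v), times = v)
  gz <- rep(ax, each = v * v)
  for (b in seq_len(nrow(centers))) {
    w2 <- 2 * params$widths[b]^2
    d2 <- (gx - centers[b, 1])^2 + (gy - centers[b, 2])^2 + (gz - centers[b, 3])^2
    grid <- grid + params$amplitudes[b] * array(exp(-d2 / w2), dim = dim(grid))
  }
  structure(list(grid = grid, v = v,
                 blobs = list(centers = centers, widths = params$widths,
                              amplitudes = params$amplitudes),
                 state_id = as.integer(state)),
            class = "phantom_volume")
}

# Uniform random rotation matrix: Euler z-y-z angles with the sine
# correction on the middle angle.
random_rotation <- function() {
  a <- stats::runif(1, 0, 2 * pi)
  b <- acos(stats::runif(1, -1, 1))
  g <- stats::runif(1, 0, 2 * pi)
  rz <- function(x) matrix(c(cos(x), -sin(x), 0, sin(x), cos(x), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(x) matrix(c(cos(x), 0, sin(x), 0, 1, 0, -sin(x), 0, cos(x)),
                           3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(g)
}

#' Project a phantom volume along z after rotating it
#'
#' The volume is resampled on the rotated grid by trilinear interpolation
#' (zero outside the box) and summed along the third axis, giving an
#' `s x s` projection image for `s = v`.
#'
#' @param vol a `phantom_volume`
#' @param R 3 x 3 rotation matrix
#' @return s x s numeric matrix
#' @export
project_volume <- function(vol, R) {
  v <- vol$v
  ax <- seq_len(v) - (v + 1) / 2
  gx <- rep(ax, times = v * v)
  gy <- rep(rep(ax, each = v), times = v)
  gz <- rep(ax, each = v * v)
  src <- t(R) %*% rbind(gx, gy, gz)    # sample f(R^T p)
  sx <- src[1, ] + (v + 1) / 2
  sy <- src[2, ] + (v + 1) / 2
  sz <- src[3, ] + (v + 1) / 2
  x0 <- floor(sx); y0 <- floor(sy); z0 <- floor(sz)
  fx <- sx - x0;  fy <- sy - y0;  fz <- sz - z0
  val <- numeric(length(sx))
  g <- vol$grid
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
    ok <- xi >= 1 & xi <= v & yi >= 1 & yi <= v & zi >= 1 & zi <= v
    wgt <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
           (if (dz) fz else 1 - fz)
    idx <- xi[ok] + (yi[ok] - 1) * v + (zi[ok] - 1) * v * v
    val[ok] <- val[ok] + wgt[ok] * g[idx]
  }
  matrix(rowsum(val, group = rep(seq_len(v * v), times = v)), v, v)
}

# integer circular-ish shift with zero fill
shift_image <- function(img, dx, dy) {
  s <- nrow(img)
  out <- matrix(0, s, s)
  xs <- seq_len(s) - dx; ys <- seq_len(s) - dy
  okx <- xs >= 1 & xs <= s; oky <- ys >= 1 & ys <= s
  out[okx, oky] <- img[xs[okx], ys[oky]]
  out
}

#' Simulate a two-state projection-image dataset
#'
#' Emulates the heterogeneity experiment: two conformations of a
#' Gaussian-blob phantom (state 2 displaces one blob), `n_per_state`
#' projections each at uniformly random orientations, an integer center
#' shift uniform within `max_shift_frac` of the image size in each axis,
#' and zero-mean Gaussian noise with variance `var(signal) / snr` computed
#' per image before shifting.  `snr = Inf` disables the noise.
#'
#' @param n_per_state images per conformation
#' @param image_size image side length in pixels (also the voxel grid size)
#' @param snr target signal-to-noise ratio, `var(signal) / var(noise)`
#' @param max_shift_frac maximum center shift as a fraction of the image
#'   size (default 0.06)
#' @param seed RNG seed (required)
#' @param params phantom parameters, see [phantom_params()]
#' @return object of class `simulated_image_set`: `images` (list of
#'   matrices), `true_state`, `true_rotations` (list of 3 x 3 matrices),
#'   `shifts` (m x 2 integer), `snr`, `seed`
#' @export
make_two_state_dataset <- function(n_per_state, image_size, snr,
                                   max_shift_frac = 0.06, seed,
                                   params = phantom_params()) {
  if (missing(seed)) stop("seed is required")
  if (!(snr > 0)) stop("snr must be > 0 (use Inf for noiseless)")
  if (n_per_state < 1L) stop("n_per_state must be >= 1")
  vol1 <- phantom_volume(image_size, 1L, params)
  vol2 <- phantom_volume(image_size, 2L, params)
  m <- 2L * n_per_state
  max_shift <- floor(max_shift_frac * image_size)
  with_seed(seed, {
    images <- vector("list", m)
    rots <- vector("list", m)
    shifts <- matrix(0L, m, 2)
    state <- rep(c(1L, 2L), each = n_per_state)
    for (i in seq_len(m)) {
      R <- random_rotation()
      img <- project_volume(if (state[i] == 1L) vol1 else vol2, R)
      if (is.finite(snr)) {
        sdn <- sqrt(stats::var(as.vector(img)) / snr)
        img <- img + matrix(stats::rnorm(length(img), 0, sdn),
                            nrow(img), ncol(img))
      }
      sh <- if (max_shift > 0)
        sample(seq.int(-max_shift, max_shift), 2L, replace = TRUE) else c(0L, 0L)
      images[[i]] <- shift_image(img, sh[1L], sh[2L])
      rots[[i]] <- R
      shifts[i, ] <- sh
    }
    structure(list(images = images,
                   true_state = state,
                   true_rotations = rots,
                   shifts = shifts,
                   snr = snr, max_shift_frac = max_shift_frac, seed = seed),
              class = "simulated_image_set")
  })
}
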