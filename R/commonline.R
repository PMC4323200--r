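#' Polar Fourier transform of a projection image
#'
#' Samples the 2-D discrete Fourier transform of the (mean-subtracted)
#' image along `n_lines` rays from the frequency-plane origin, at integer
#' radii `1..n_radial` (the DC sample is excluded: it is the
#' shift-invariant total image mass and would dominate every line).
#' Values off the Cartesian frequency grid are obtained by bilinear
#' interpolation.  Ray `l` has angle `theta_l = (l - 1) * 360 / n_lines`
#' degrees.
#'
#' By the Fourier slice theorem, two projections of the same 3-D object
#' share a common line in their 2-D transforms, so some ray of image A
#' matches some ray of image B up to noise and discretization.
#'
#' @param img square numeric matrix, side `s >= 8`
#' @param n_lines number of rays covering 360 degrees (default 200, i.e.
#'   1.8-degree steps)
#' @param n_radial outermost sampled radius (frequency pixels); default
#'   `floor(s/2) - 1`, must not exceed `s/2` (Nyquist)
#' @param r_min innermost sampled radius (default 1, i.e. only DC
#'   excluded).  Raising it drops the lowest-frequency band, which is
#'   dominated by the common projection envelope and carries little
#'   orientation information.
#' @return object of class `polar_fourier`: `values` (n_lines x
#'   `(n_radial - r_min + 1)` complex matrix, one ray per row),
#'   `n_lines`, `n_radial`, `r_min`, `delta_theta` (degrees)
#' @export
polar_fourier <- function(img, n_lines = 200L, n_radial = NULL, r_min = 1L) {
  img <- as.matrix(img)
  s <- nrow(img)
  if (ncol(img) != s) stop("image must be square")
  if (s < 8L) stop("image side must be >= 8")
  if (s %% 2L != 0L) stop("image side must be even")
  if (n_lines < 2L) stop("need at least 2 lines")
  if (is.null(n_radial)) n_radial <- floor(s / 2) - 1L
  if (n_radial > s / 2) stop("n_radial beyond Nyquist (> s/2)")
  r_min <- as.integer(r_min)
  if (r_min < 1L) stop("r_min must be >= 1 (DC is always excluded)")
  if (n_radial - r_min + 1L < 2L) stop("need at least 2 radial samples")
  F <- stats::fft(img - mean(img))
  # center the spectrum: DC moves to (s/2 + 1, s/2 + 1)
  ctr <- floor(s / 2)
  F <- F[c((ctr + 1):s, 1:ctr), c((ctr + 1):s, 1:ctr)]
  c0 <- ctr + 1
  # move the phase origin to the image center ((s+1)/2 in pixel units):
  # without this every ray carries an angle-dependent linear phase ramp
  # and the Fourier values along a true common line would not agree
  freq <- (seq_len(s) - c0)
  ramp <- exp(2i * pi * freq * ((s - 1) / 2) / s)
  F <- F * outer(ramp, ramp)
  theta <- (seq_len(n_lines) - 1) * 2 * pi / n_lines
  r <- seq.int(r_min, n_radial)
  px <- c0 + outer(cos(theta), r)           # n_lines x n_radial
  py <- c0 + outer(sin(theta), r)
  vals <- bilinear_cx(F, px, py)
  structure(list(values = vals, n_lines = n_lines, n_radial = n_radial,
                 r_min = r_min, s = s, delta_theta = 360 / n_lines),
            class = "polar_fourier")
}

# bilinear interpolation of a complex matrix at (x, y) (matrix row/col
# coordinates); zero outside the grid
bilinear_cx <- function(F, x, y) {
  s <- nrow(F)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;   fy <- y - y0
  out <- matrix(0 + 0i, nrow(x), ncol(x))
  for (dx in 0:1) for (dy in 0:1) {
    xi <- x0 + dx; yi <- y0 + dy
    ok <- xi >= 1 & xi <= s & yi >= 1 & yi <= s
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy)
    idx <- (as.vector(yi) - 1L) * s + as.vector(xi)
    add <- matrix(0 + 0i, nrow(x), ncol(x))
    add[ok] <- F[idx[ok]]
    out <- out + w * add
  }
  out
}

#' Ray angles of a polar Fourier transform, in degrees
#' @param pf a `polar_fourier` (or the number of lines)
#' @return numeric vector of length `n_lines`
#' @export
line_angles <- function(pf) {
  n <- if (inherits(pf, "polar_fourier")) pf$n_lines else as.integer(pf)
  (seq_len(n) - 1) * 360 / n
}

#' Discrepancy between two Fourier lines
#'
#' The mean per-sample modulus of the difference, `sum_i |F_A(i) -
#' F_B(i)| / N`: zero iff the lines are identical.  `mode = "literal"`
#' instead places the modulus outside the sum (`|sum_i (F_A - F_B)| / N`),
#' the printed form of the formula, under which lines with equal sums
#' compare as identical — provided for comparison only.  `mode =
#' "magnitude"` compares sample moduli, discarding the phase ramps that
#' image center shifts introduce.
#'
#' @param a,b complex vectors of equal length
#' @param mode `"complex"` (default), `"magnitude"`, or `"literal"`
#' @return nonnegative number
#' @export
line_distance <- function(a, b, mode = c("complex", "magnitude", "literal")) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) stop("lines differ in length")
  switch(mode,
         complex = mean(Mod(a - b)),
         magnitude = mean(abs(Mod(a) - Mod(b))),
         literal = Mod(sum(a - b)) / length(a))
}

cl_mode_code <- function(mode) {
  match(match.arg(mode, c("complex", "magnitude", "literal", "complex-shift")),
        c("complex", "magnitude", "literal", "complex-shift")) - 1L
}

# mode 3 ("complex-shift") minimizes the complex discrepancy over a table
# of relative 1-D shifts along the line; the ramp table must be loaded
# into the C++ side first
load_shift_ramps <- function(pf, max_shift, step = 1) {
  radii <- seq.int(pf$r_min, pf$n_radial)
  deltas <- seq(-max_shift, max_shift, by = step)
  ramps <- exp(-2i * pi * outer(deltas, radii) / pf$s)
  set_shift_ramps(ramps)
}

#' Common-line distance between two images
#'
#' The minimum of [line_distance()] over all `n_lines x n_lines` ordered
#' ray pairs — the best-matching (most similar) candidate common line.
#' Symmetric in its arguments.
#'
#' @param A,B `polar_fourier` objects with matching parameters
#' @param mode see [line_distance()]
#' @return the distance, with the matched 1-based ray indices attached as
#'   attributes `line_a`, `line_b`
#' @export
image_distance <- function(A, B, mode = "complex") {
  stopifnot(inherits(A, "polar_fourier"), inherits(B, "polar_fourier"))
  if (A$n_lines != B$n_lines || A$n_radial != B$n_radial ||
      A$r_min != B$r_min)
    stop("polar Fourier parameters do not match")
  r <- cl_best_match(t(A$values), t(B$values), cl_mode_code(mode))
  structure(r$distance, line_a = r$line_a, line_b = r$line_b)
}

#' Pairwise common-line distance matrix for an image set
#'
#' @param images list of equal-size square matrices, `m >= 2`
#' @param n_lines,n_radial see [polar_fourier()]
#' @param mode see [line_distance()]
#' @return list: `D` (m x m symmetric, zero diagonal), `line_a`/`line_b`
#'   (matched ray index matrices, `line_a[i, j]` is the ray of image `i`
#'   matched against ray `line_b[i, j]` of image `j`), `pf` (the polar
#'   transforms)
#' @export
image_distance_matrix <- function(images, n_lines = 200L, n_radial = NULL,
                                  mode = "complex", r_min = 1L) {
  if (length(images) < 2L) stop("need at least 2 images")
  sizes <- vapply(images, function(x) c(nrow(x), ncol(x)), integer(2))
  if (length(unique(as.vector(sizes))) != 1L) stop("images differ in size")
  pf <- lapply(images, polar_fourier, n_lines = n_lines, n_radial = n_radial,
               r_min = r_min)
  if (mode == "complex-shift")
    load_shift_ramps(pf[[1L]], max_shift = ceiling(0.06 * nrow(images[[1L]]) *
                                                   sqrt(2)))
  r <- cl_pairwise(lapply(pf, function(p) t(p$values)), cl_mode_code(mode))
  list(D = r$D, line_a = r$line_a, line_b = r$line_b, pf = pf)
}

#' Build a heat-passing-ready network from projection images
#'
#' Computes the full pairwise common-line distance matrix and converts it
#' to edge weights with the Gaussian affinity `W_ij = exp(-d_ij^2 /
#' sigma^2)` (`sigma` = median off-diagonal distance by default), zero
#' diagonal.
#'
#' @inheritParams image_distance_matrix
#' @param sigma affinity bandwidth, default median off-diagonal distance
#' @return a `weighted_graph` over the images (labels `1..m`)
#' @export
build_image_network <- function(images, n_lines = 200L, n_radial = NULL,
                                mode = "complex", sigma = NULL, r_min = 1L) {
  dm <- image_distance_matrix(images, n_lines = n_lines,
                              n_radial = n_radial, mode = mode,
                              r_min = r_min)
  affinity_from_distance(dm$D, sigma = sigma)
}

#' Ground-truth common-line angles for a pair of projection directions
#'
#' With projection `I(x, y) = integral of f(R^T (x, y, z)) dz`, the 2-D
#' transform of image A is the slice of the 3-D transform spanned by the
#' first two rows of `R_A`; the slice normal is the third row.  The common
#' line of two slices points along the cross product of the normals, and
#' its in-plane angle in image A is `atan2(r_2 . u, r_1 . u)`.
#'
#' @param Ra,Rb 3 x 3 rotation matrices of the two images
#' @return `c(theta_a, theta_b)` in degrees within `[0, 360)`, or `NA`s
#'   when the projection directions are (anti-)parallel
#' @export
true_common_line <- function(Ra, Rb) {
  na <- Ra[3, ]; nb <- Rb[3, ]
  u <- c(na[2] * nb[3] - na[3] * nb[2],
         na[3] * nb[1] - na[1] * nb[3],
         na[1] * nb[2] - na[2] * nb[1])
  if (sqrt(sum(u^2)) < 1e-12) return(c(NA_real_, NA_real_))
  ang <- function(R) {
    a <- atan2(sum(R[2, ] * u), sum(R[1, ] * u)) * 180 / pi
    (a + 360) %% 360
  }
  c(ang(Ra), ang(Rb))
}

# circular distance between angles in degrees, in [0, 180]
angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Common-line detection error against known projection geometry
#'
#' For every image pair of a simulated set, compares the detected common
#' line (the best-matching ray pair) with the ground truth computed from
#' the true rotations.  Because reversing both rays gives an equally valid
#' common line, the error of a pair is the smaller of the two joint
#' readings; a random detection averages 90 degrees.
#'
#' @param imgset a `simulated_image_set`
#' @param n_lines,n_radial,mode see [image_distance_matrix()]
#' @return list: `mean_error` (degrees), `pct_correct` (fraction of pairs
#'   with error <= 5 degrees), `errors` (per-pair vector), `D` (distance
#'   matrix)
#' @export
common_line_error <- function(imgset, n_lines = 200L, n_radial = NULL,
                              mode = "complex", r_min = 1L) {
  stopifnot(inherits(imgset, "simulated_image_set"))
  dm <- image_distance_matrix(imgset$images, n_lines = n_lines,
                              n_radial = n_radial, mode = mode,
                              r_min = r_min)
  m <- length(imgset$images)
  errors <- c()
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (imgset$true_state[i] != imgset$true_state[j]) next
      tr <- true_common_line(imgset$true_rotations[[i]],
                             imgset$true_rotations[[j]])
      if (anyNA(tr)) next
      da <- line_angles(n_lines)[dm$line_a[i, j]]
      db <- line_angles(n_lines)[dm$line_b[i, j]]
      e1 <- (angle_diff(da, tr[1]) + angle_diff(db, tr[2])) / 2
      e2 <- (angle_diff(da, (tr[1] + 180) %% 360) +
             angle_diff(db, (tr[2] + 180) %% 360)) / 2
      errors <- c(errors, min(e1, e2))
    }
  }
  list(mean_error = mean(errors),
       pct_correct = mean(errors <= 5),
       errors = errors, D = dm$D)
}
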