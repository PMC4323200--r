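# small deterministic test image: a few off-center Gaussian bumps
bump_image <- function(s = 32, centers = rbind(c(0.1, -0.05), c(-0.12, 0.08)),
                       width = 0.06) {
  c0 <- (s + 1) / 2
  x <- (seq_len(s) - c0) / s
  img <- matrix(0, s, s)
  for (b in seq_len(nrow(centers)))
    img <- img + exp(-(outer((x - centers[b, 1])^2, (x - centers[b, 2])^2,
                             "+")) / (2 * width^2))
  img
}

test_that("polar transform basics: flat image, Hermitian pairs, central delta", {
  flat <- matrix(3.7, 32, 32)
  pf <- polar_fourier(flat, n_lines = 36)
  expect_lt(max(Mod(pf$values)), 1e-10)   # all energy was DC

  img <- bump_image()
  pfi <- polar_fourier(img, n_lines = 36)
  # line at theta + 180 is the samplewise conjugate (real input)
  for (l in c(1, 5, 10)) {
    expect_equal(pfi$values[l, ], Conj(pfi$values[l + 18, ]),
                 tolerance = 1e-8)
  }

  # delta function: flat modulus spectrum.  On the axes the polar samples
  # hit exact grid nodes (modulus exactly 1); off-axis samples are bilinear
  # interpolates of a unit-modulus field, so slightly attenuated
  delta <- matrix(0, 32, 32); delta[17, 17] <- 1
  pfd <- polar_fourier(delta, n_lines = 24)
  mods <- Mod(pfd$values)
  axis_lines <- c(1, 7, 13, 19)        # 0, 90, 180, 270 degrees
  expect_equal(as.vector(mods[axis_lines, ]),
               rep(1, 4 * ncol(mods)), tolerance = 1e-10)
  expect_true(all(mods > 0.85 & mods < 1 + 1e-10))

  expect_error(polar_fourier(img, n_radial = 20), "Nyquist")
  expect_error(polar_fourier(matrix(0, 4, 4)), ">= 8")
  expect_error(polar_fourier(matrix(0, 8, 9)), "square")
})

test_that("line distance modes match their formulas", {
  set.seed(2)
  a <- complex(real = rnorm(10), imaginary = rnorm(10))
  b <- complex(real = rnorm(10), imaginary = rnorm(10))
  expect_equal(line_distance(a, a), 0)
  cshift <- 1.5 - 2i
  expect_equal(line_distance(a, a + cshift), Mod(cshift), tolerance = 1e-12)
  # naive loop oracle
  expect_equal(line_distance(a, b), sum(sapply(1:10, function(i)
    Mod(a[i] - b[i]))) / 10, tolerance = 1e-12)
  expect_equal(line_distance(a, b, "literal"), Mod(sum(a - b)) / 10)
  expect_equal(line_distance(a, b, "magnitude"),
               mean(abs(Mod(a) - Mod(b))), tolerance = 1e-12)
  expect_error(line_distance(a, b[1:5]), "length")

  # literal mode can declare different lines identical (why it is not
  # the default): b permuted has the same sum
  expect_equal(line_distance(a, sample(a), "literal"), 0, tolerance = 1e-9)
})

test_that("image distance: identity, symmetry, C++ matches the R loop", {
  imgA <- bump_image()
  imgB <- bump_image(centers = rbind(c(-0.05, 0.1), c(0.14, 0.02)))
  pa <- polar_fourier(imgA, n_lines = 20)
  pb <- polar_fourier(imgB, n_lines = 20)
  expect_equal(as.numeric(image_distance(pa, pa)), 0, tolerance = 1e-10)
  dab <- image_distance(pa, pb)
  dba <- image_distance(pb, pa)
  expect_equal(as.numeric(dab), as.numeric(dba), tolerance = 1e-12)

  # full R-side loop over all line pairs as the independent oracle
  best <- Inf
  for (i in 1:20) for (j in 1:20) {
    d <- line_distance(pa$values[i, ], pb$values[j, ])
    if (d < best) best <- d
  }
  expect_equal(as.numeric(dab), best, tolerance = 1e-12)

  pm <- polar_fourier(imgB, n_lines = 24)
  expect_error(image_distance(pa, pm), "do not match")
})

test_that("in-plane rotation by the angular step permutes lines only", {
  img <- bump_image()
  # 90-degree rotation is exact on the pixel grid; with 5-degree sampling
  # (72 lines) it is 18 angular steps
  rot90 <- t(img)[, rev(seq_len(ncol(img)))]
  pa <- polar_fourier(img, n_lines = 72)
  pb <- polar_fourier(rot90, n_lines = 72)
  ref <- polar_fourier(img, n_lines = 72)
  d_self <- as.numeric(image_distance(pa, ref))
  d_rot <- as.numeric(image_distance(pa, pb))
  expect_equal(d_rot, d_self, tolerance = 1e-8)
})

test_that("distance matrix is symmetric with zero diagonal; network is ready", {
  set.seed(9)
  imgs <- lapply(1:4, function(i)
    bump_image(centers = matrix(runif(4, -0.15, 0.15), 2)))
  dm <- image_distance_matrix(imgs, n_lines = 20)
  expect_symmetric(dm$D)
  expect_equal(diag(dm$D), rep(0, 4))
  expect_true(all(dm$D >= 0))

  g <- build_image_network(imgs, n_lines = 20)
  expect_s3_class(g, "weighted_graph")
  expect_true(all(g$W >= 0 & g$W <= 1))
  expect_equal(unname(diag(g$W)), rep(0, 4))

  # two identical images: edge weight 1
  g2 <- build_image_network(list(imgs[[1]], imgs[[1]]), n_lines = 12)
  expect_equal(g2$W[1, 2], 1)

  expect_error(image_distance_matrix(imgs[1]), "at least 2")
  expect_error(image_distance_matrix(list(imgs[[1]], matrix(0, 16, 16))),
               "differ in size")
})

test_that("noiseless same-phantom projections are closer than cross-state", {
  ds <- make_two_state_dataset(4, 32, Inf, max_shift_frac = 0, seed = 3)
  dm <- image_distance_matrix(ds$images, n_lines = 60, n_radial = 10)
  same <- outer(ds$true_state, ds$true_state, "==") & upper.tri(dm$D)
  diff <- (!outer(ds$true_state, ds$true_state, "==")) & upper.tri(dm$D)
  expect_lt(mean(dm$D[same]), mean(dm$D[diff]))
})

test_that("true common-line geometry is orthogonal to both view axes", {
  set.seed(13)
  for (r in 1:5) {
    Ra <- heatpass:::random_rotation()
    Rb <- heatpass:::random_rotation()
    tr <- true_common_line(Ra, Rb)
    # the 3-D direction reconstructed from each image agrees
    ua <- cos(tr[1] * pi / 180) * Ra[1, ] + sin(tr[1] * pi / 180) * Ra[2, ]
    ub <- cos(tr[2] * pi / 180) * Rb[1, ] + sin(tr[2] * pi / 180) * Rb[2, ]
    expect_equal(ua, ub, tolerance = 1e-10)
  }
  # parallel views have no unique common line
  expect_true(all(is.na(true_common_line(diag(3), diag(3)))))
})

test_that("common-line detection on clean projections is accurate", {
  ds <- make_two_state_dataset(5, 64, Inf, max_shift_frac = 0, seed = 5)
  err <- common_line_error(ds, n_lines = 120, n_radial = 12, r_min = 2)
  expect_lt(err$mean_error, 20)
  expect_gt(err$pct_correct, 0.4)
})
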