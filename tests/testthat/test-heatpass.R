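test_that("affinity construction places preferences on the diagonal", {
  g <- path_graph(3)
  dec <- spectral_decompose(normalized_laplacian(g))
  hk <- heat_kernel(dec, 1)
  temp <- average_temperature(hk)
  p <- build_affinity(hk, temp)
  off <- upper.tri(p$S)
  expect_equal(p$S[off], hk$H[off])
  expect_equal(unname(diag(p$S)), unname(temp) / 2)

  p0 <- build_affinity(hk, temp, pref_scale = 0)
  expect_equal(unname(diag(p0$S)), rep(0, 3))

  # vertex-transitive cycle: all preferences equal
  W <- matrix(0, 5, 5)
  for (i in 1:5) { j <- i %% 5 + 1; W[i, j] <- W[j, i] <- 1 }
  gc <- weighted_graph(W)
  hkc <- heat_kernel(spectral_decompose(normalized_laplacian(gc)), 2)
  pc <- build_affinity(hkc, average_temperature(hkc))
  expect_equal(max(diag(pc$S)) - min(diag(pc$S)), 0, tolerance = 1e-12)

  expect_error(build_affinity(hk, temp[1:2]), "length")
})

test_that("message initialization follows the zero-emission rule", {
  # all-equal S: every absorption difference vanishes
  p <- affinity_problem(matrix(1, 4, 4))
  st <- init_messages(p)
  expect_equal(st$he, matrix(0, 4, 4))
  expect_equal(max(abs(st$ha)), 0)

  # 2-node hand evaluation: ha(1,2) = a - p1
  S <- matrix(c(0.3, 0.8, 0.8, 0.4), 2)
  p2 <- affinity_problem(S)
  st2 <- init_messages(p2)
  expect_equal(st2$ha[1, 2], 0.8 - 0.3)
  expect_equal(st2$ha[2, 1], 0.8 - 0.4)
  # self-absorption: preference minus best off-diagonal affinity
  expect_equal(st2$ha[1, 1], 0.3 - 0.8)
  expect_equal(st2$ha[2, 2], 0.4 - 0.8)
})

# absorption part of one sweep (slow per-pair oracle)
ha_from <- function(st, p) {
  n <- p$n
  out <- matrix(NA_real_, n, n)
  for (s in seq_len(n)) for (cc in seq_len(n)) {
    if (s == cc) out[s, cc] <- p$S[s, s] - max(p$S[s, -s])
    else {
      others <- setdiff(seq_len(n), cc)
      out[s, cc] <- p$S[s, cc] - max(st$he[s, others] + p$S[s, others])
    }
  }
  out
}

test_that("one undamped sweep matches a per-pair hand evaluation", {
  S <- matrix(c(0.9, 0.6, 0.2,
                0.6, 0.5, 0.3,
                0.2, 0.3, 0.1), 3, byrow = TRUE)
  p <- affinity_problem(S)
  st <- init_messages(p, damping = 0)
  st1 <- update_messages(st, p)

  # independent slow oracle for one synchronous sweep from st
  ha_o <- matrix(NA_real_, 3, 3)
  for (s in 1:3) for (cc in 1:3) {
    if (s == cc) {
      ha_o[s, cc] <- S[s, s] - max(S[s, -s])
    } else {
      others <- setdiff(1:3, cc)
      ha_o[s, cc] <- S[s, cc] - max(st$he[s, others] + S[s, others])
    }
  }
  he_o <- matrix(NA_real_, 3, 3)
  for (s in 1:3) for (cc in 1:3) {
    if (s == cc) {
      he_o[cc, cc] <- sum(pmax(0, ha_o[setdiff(1:3, cc), cc]))
    } else {
      rest <- setdiff(1:3, c(s, cc))
      he_o[s, cc] <- min(0, ha_o[cc, cc] + sum(pmax(0, ha_o[rest, cc])))
    }
  }
  expect_equal(unname(st1$ha), ha_o, tolerance = 1e-12)
  expect_equal(unname(st1$he), he_o, tolerance = 1e-12)

  # off-diagonal emissions never positive
  expect_true(all(st1$he[row(st1$he) != col(st1$he)] <= 0))

  # damped sweep is the convex combination of old and computed messages
  stf <- init_messages(p, damping = 0.5)
  st2 <- update_messages(stf, p)
  expect_equal(unname(st2$ha), unname(0.5 * stf$ha) + 0.5 * ha_from(stf, p),
               tolerance = 1e-12)
})

test_that("net similarity scores assignments and rejects infeasible ones", {
  S <- matrix(c(0.3, 0.8, 0.8, 0.4), 2)
  p <- affinity_problem(S)
  expect_equal(net_similarity(c(1L, 2L), p), 0.3 + 0.4)
  expect_equal(net_similarity(c(2L, 2L), p), 0.8 + 0.4)
  expect_equal(net_similarity(c(2L, 1L), p), -Inf)
  expect_error(net_similarity(c(1L, 5L), p), "invalid")
})

test_that("brute force handles the dominant-diagonal / off-diagonal extremes", {
  hiPref <- affinity_problem(matrix(c(5, 0.1, 0.1, 5), 2))
  bf1 <- brute_force_exemplars(hiPref)
  expect_equal(length(bf1$centers), 2L)

  hiCross <- affinity_problem(matrix(c(0.1, 5, 5, 0.1), 2))
  bf2 <- brute_force_exemplars(hiCross)
  expect_equal(length(bf2$centers), 1L)

  # beats 1000 random feasible assignments
  set.seed(4)
  S <- matrix(stats::runif(36), 6); S <- (S + t(S)) / 2
  p <- affinity_problem(S)
  bf <- brute_force_exemplars(p)
  for (r in 1:1000) {
    ex <- sample.int(6, sample.int(6, 1))
    g <- ex[apply(S[, ex, drop = FALSE], 1, which.max)]
    g[ex] <- ex
    expect_lte(net_similarity(g, p), bf$objective + 1e-12)
  }
  expect_error(brute_force_exemplars(affinity_problem(diag(13))), "n <= 12")
})

test_that("heat passing attains the brute-force optimum on separated blocks", {
  for (seed in 1:8) {
    sizes <- if (seed %% 2) c(4, 4) else c(3, 3, 3)
    p <- block_affinity(sizes, 1.0, 0.05, seed)
    bf <- brute_force_exemplars(p)
    hp <- run_heat_passing(p)
    expect_true(hp$converged)
    expect_equal(hp$objective, bf$objective, tolerance = 1e-9)
    expect_equal(length(hp$centers), length(bf$centers))
  }
})

test_that("results are feasible, deterministic, and respect preference extremes", {
  p <- block_affinity(c(5, 5), 1.0, 0.1, 21)
  r1 <- run_heat_passing(p)
  r2 <- run_heat_passing(p)
  expect_identical(r1$assignment, r2$assignment)     # bit-for-bit
  expect_true(all(r1$assignment[r1$centers] == r1$centers))
  expect_true(all(r1$assignment %in% r1$centers))

  # preference extremes: huge diagonal gives all singletons, a strongly
  # negative diagonal (every exemplar heavily penalized) gives one cluster
  Sbig <- p$S; diag(Sbig) <- 1e6
  expect_equal(length(run_heat_passing(affinity_problem(Sbig))$centers), 10L)
  Sneg <- p$S; diag(Sneg) <- -100
  expect_equal(length(run_heat_passing(affinity_problem(Sneg))$centers), 1L)
})

test_that("degenerate sizes are handled", {
  p1 <- affinity_problem(matrix(2, 1, 1))
  r <- run_heat_passing(p1)
  expect_equal(r$centers, "1")
  expect_equal(r$objective, 2)
  expect_error(init_messages(p1), "n >= 2")
})

test_that("karate club yields the published two-faction split", {
  g <- karate_graph()
  expect_equal(g$n, 34L)
  res <- heat_pass_graph(g, t = 4)
  expect_setequal(res$centers, c("1", "34"))
  # the two-center regime is stable across diffusion times 4..10 and the
  # partition moves by at most one borderline member
  for (t in c(6, 8, 10)) {
    rt <- heat_pass_graph(g, t = t)
    expect_setequal(rt$centers, c("1", "34"))
    expect_lte(sum(rt$assignment != res$assignment), 1L)
  }
})
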