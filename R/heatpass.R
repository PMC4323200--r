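#' Affinity problem for heat passing
#'
#' Packs the heat kernel and the heat-center preference values (hcpv) into
#' the single matrix the message-passing loop consumes: off-diagonal
#' entries are the heat affinities `H_t(s, c)`, the diagonal holds each
#' node's preference to be a heat center.
#'
#' @param hk a `heat_kernel`
#' @param temp average-temperature vector from [average_temperature()]
#'   (same graph, same time)
#' @param pref_scale multiplier applied to the raw preference (default 1)
#' @param pref_mode how the raw preference is formed:
#'   `"mean-temperature"` (default) uses `Temp_t(i) / (n - 1)` — the mean
#'   heat received per other node, on the same scale as the affinities;
#'   `"raw-temperature"` uses `Temp_t(i)` unscaled; `"median-similarity"`
#'   gives every node the median off-diagonal affinity.
#' @return object of class `affinity_problem` with fields `n`, `S`,
#'   `labels`.
#' @details The raw temperature sums `n - 1` kernel entries and can exceed
#'   every off-diagonal affinity, which pushes the optimum toward
#'   all-singleton clusters; dividing by `n - 1` keeps preference and
#'   affinity on a common scale while preserving the temperature ranking.
#' @export
build_affinity <- function(hk, temp, pref_scale = 1,
                           pref_mode = c("mean-temperature", "raw-temperature",
                                         "median-similarity")) {
  stopifnot(inherits(hk, "heat_kernel"))
  pref_mode <- match.arg(pref_mode)
  n <- nrow(hk$H)
  if (length(temp) != n) stop("temperature vector length does not match kernel")
  pref <- switch(pref_mode,
    "mean-temperature" = if (n > 1L) temp / (n - 1L) else temp,
    "raw-temperature" = temp,
    "median-similarity" = rep(stats::median(hk$H[upper.tri(hk$H)]), n))
  S <- hk$H
  diag(S) <- pref_scale * pref
  structure(list(n = n, S = S, labels = hk$labels),
            class = "affinity_problem")
}

#' Build an affinity problem directly from an arbitrary matrix (mainly for
#' tests and oracles).
#' @param S square matrix: off-diagonal affinities, diagonal preferences
#' @param labels optional node labels
#' @return an `affinity_problem`
#' @export
affinity_problem <- function(S, labels = NULL) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (n != ncol(S)) stop("S must be square")
  off <- S; diag(off) <- 0
  if (max(abs(off - t(off))) > 1e-8 * max(1, max(abs(off))))
    stop("off-diagonal of S must be symmetric")
  if (any(!is.finite(S))) stop("S must be finite")
  if (is.null(labels))
    labels <- if (!is.null(rownames(S))) rownames(S) else as.character(seq_len(n))
  dimnames(S) <- list(labels, labels)
  structure(list(n = n, S = S, labels = as.character(labels)),
            class = "affinity_problem")
}

#' Initialize heat-passing messages
#'
#' Heat emissions start at zero (every node treated equally); the heat
#' absorption is the first application of the absorption update with zero
#' emissions: `ha_0(s, c) = S(s, c) - max_{c' != c} S(s, c')`, computed for
#' every ordered pair including `s = c` (the diagonal of `S` being the
#' preference).
#'
#' @param p an `affinity_problem` with `n >= 2`
#' @param damping damping factor carried in the state (used by later sweeps)
#' @return object of class `message_state` with fields `ha`, `he`,
#'   `iteration`, `damping`.
#' @export
init_messages <- function(p, damping = 0.5) {
  stopifnot(inherits(p, "affinity_problem"))
  if (p$n < 2L) stop("message passing needs n >= 2 (single node is its own center)")
  if (damping < 0 || damping >= 1) stop("damping must be in [0, 1)")
  he <- matrix(0, p$n, p$n)
  ha <- absorption_update(he, p$S)
  structure(list(ha = ha, he = he, iteration = 1L, damping = damping),
            class = "message_state")
}

# ha(s,c) := S(s,c) - max_{c' != c} (he(s,c') + S(s,c'))  -- row-wise via
# the max / second-max trick.  The self-absorption is pinned to
# ha(c,c) = hcpv(c) - max_{c' != c} H(c,c'): the preference minus the
# largest heat affinity from c to any other candidate center, constant
# across sweeps.  (The responsibility-style alternative, subtracting
# max(he + H) instead, yields systematically more centers.)
absorption_update <- function(he, S) {
  A <- he + S
  n <- nrow(S)
  m1 <- apply(A, 1L, max)
  i1 <- max.col(A, ties.method = "first")
  A2 <- A
  A2[cbind(seq_len(n), i1)] <- -Inf
  m2 <- apply(A2, 1L, max)
  ha <- S - m1
  ha[cbind(seq_len(n), i1)] <- S[cbind(seq_len(n), i1)] - m2
  Off <- S
  diag(Off) <- -Inf
  diag(ha) <- diag(S) - apply(Off, 1L, max)
  ha
}

# he(s,c) := min{0, ha(c,c) + sum_{s' not in {s,c}} max{0, ha(s',c)}} for
# s != c;  he(c,c) := sum_{s != c} max{0, ha(s,c)}.
emission_update <- function(ha) {
  n <- nrow(ha)
  Rp <- pmax(ha, 0)
  diag(Rp) <- diag(ha)           # ha(c,c) enters unclipped
  cs <- colSums(Rp)
  he <- rep(cs, each = n) - Rp   # column sum minus own contribution
  d <- diag(he)                  # = sum_{s != c} max{0, ha(s,c)}
  he <- pmin(he, 0)
  diag(he) <- d
  he
}

#' One synchronous heat-passing sweep
#'
#' Updates the absorption messages from the current emissions, then the
#' emissions from the new absorptions, and damps both:
#' `new = damping * old + (1 - damping) * computed`.
#'
#' @param state a `message_state`
#' @param p the `affinity_problem`
#' @return the updated `message_state`
#' @export
update_messages <- function(state, p) {
  stopifnot(inherits(state, "message_state"), inherits(p, "affinity_problem"))
  lam <- state$damping
  ha <- absorption_update(state$he, p$S)
  ha <- lam * state$ha + (1 - lam) * ha
  he <- emission_update(ha)
  he <- lam * state$he + (1 - lam) * he
  if (any(!is.finite(ha)) || any(!is.finite(he))) {
    bad <- which(!is.finite(ha) | !is.finite(he), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite message at pair (%d, %d): degenerate affinity scale",
                 bad[1L], bad[2L]))
  }
  state$ha <- ha
  state$he <- he
  state$iteration <- state$iteration + 1L
  state
}

#' Extract heat centers and sink assignments from a message state
#'
#' The normalized heat transfer coefficient is `ht(s, c) = he(s, c) +
#' ha(s, c)`.  A node is a heat center when its own column attains its row
#' maximum (`ht(c, c) = max_z ht(c, z)`); every other node is assigned to
#' the center with the largest `ht(s, .)` restricted to the discovered
#' center set.  Ties go to the lowest node label.
#'
#' @param state a `message_state`
#' @param p the `affinity_problem` (for labels and the final objective)
#' @return object of class `heat_clustering`: fields `centers` (labels),
#'   `assignment` (named character vector node -> center label), `ht`,
#'   `objective`, `iterations`, `converged`.
#' @export
criterion_and_assign <- function(state, p) {
  ht <- state$ha + state$he
  n <- nrow(ht)
  lab_rank <- label_order_rank(p$labels)
  rowmax <- apply(ht, 1L, max)
  is_center <- diag(ht) >= rowmax - 0
  if (!any(is_center)) {
    warning("empty center set; falling back to the node with maximal ht(c,c)")
    d <- diag(ht)
    cand <- which(d == max(d))
    is_center[cand[which.min(lab_rank[cand])]] <- TRUE
  }
  centers_idx <- which(is_center)
  assign_idx <- integer(n)
  assign_idx[centers_idx] <- centers_idx
  sinks <- setdiff(seq_len(n), centers_idx)
  if (length(sinks)) {
    sub <- ht[sinks, centers_idx, drop = FALSE]
    for (r in seq_along(sinks)) {
      v <- sub[r, ]
      best <- centers_idx[v == max(v)]
      assign_idx[sinks[r]] <- best[which.min(lab_rank[best])]
    }
  }
  assignment <- p$labels[assign_idx]
  names(assignment) <- p$labels
  structure(list(centers = p$labels[centers_idx],
                 assignment = assignment,
                 ht = ht,
                 objective = net_similarity(assign_idx, p),
                 iterations = state$iteration,
                 converged = NA),
            class = "heat_clustering")
}

#' @export
print.heat_clustering <- function(x, ...) {
  cat("heat_clustering:", length(x$centers), "center(s):",
      paste(x$centers, collapse = ", "), "\n")
  cat("  objective =", format(x$objective), "; iterations =", x$iterations,
      "; converged =", x$converged, "\n")
  invisible(x)
}

#' Run the heat-passing loop
#'
#' Iterates [update_messages()] until the largest absolute message change
#' drops below `tol`, or the center set is unchanged for `stable_window`
#' consecutive sweeps, or `max_iter` sweeps have run.  Entirely
#' deterministic: no randomness anywhere in the loop, so identical inputs
#' give identical results.
#'
#' @param p an `affinity_problem`
#' @param max_iter sweep cap (default 20000)
#' @param tol convergence threshold on the max absolute message change
#' @param damping damping factor in `[0, 1)` (default 0.5); undamped
#'   synchronous updates oscillate on symmetric inputs
#' @param stable_window optional early exit: stop after this many
#'   consecutive sweeps with an unchanged center set.  Disabled by default
#'   (`Inf`): the center set routinely freezes long before the sink
#'   assignments have settled, and exiting early can return a suboptimal
#'   partition, so the message tolerance is the trusted criterion.
#' @return a `heat_clustering`; non-convergence is flagged, not an error
#' @export
run_heat_passing <- function(p, max_iter = 20000L, tol = 1e-6,
                             damping = 0.5, stable_window = Inf) {
  stopifnot(inherits(p, "affinity_problem"))
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (p$n == 1L) {
    assignment <- stats::setNames(p$labels, p$labels)
    return(structure(list(centers = p$labels, assignment = assignment,
                          ht = matrix(0, 1, 1), objective = p$S[1L, 1L],
                          iterations = 0L, converged = TRUE),
                     class = "heat_clustering"))
  }
  state <- init_messages(p, damping = damping)
  prev_centers <- NULL
  stable <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter - 1L)) {
    old_ha <- state$ha; old_he <- state$he
    state <- update_messages(state, p)
    delta <- max(max(abs(state$ha - old_ha)), max(abs(state$he - old_he)))
    if (is.finite(stable_window)) {
      ht <- state$ha + state$he
      centers <- which(diag(ht) >= apply(ht, 1L, max))
      if (!is.null(prev_centers) && length(centers) &&
          identical(centers, prev_centers)) {
        stable <- stable + 1L
      } else stable <- 0L
      prev_centers <- centers
    }
    if (delta < tol || stable >= stable_window) {
      converged <- TRUE
      break
    }
  }
  res <- criterion_and_assign(state, p)
  res$converged <- converged
  res
}

#' Net similarity of an assignment (the exemplar objective)
#'
#' `sum_i S(i, g_i)`, where `S(i, i)` is the preference, subject to the
#' consistency constraint that any node chosen as an exemplar must be its
#' own exemplar; an assignment violating it scores `-Inf`.
#'
#' @param assignment integer vector of exemplar indices, or character
#'   vector of exemplar labels
#' @param p an `affinity_problem`
#' @return a single number (possibly `-Inf`)
#' @export
net_similarity <- function(assignment, p) {
  stopifnot(inherits(p, "affinity_problem"))
  g <- if (is.character(assignment)) match(assignment, p$labels) else
    as.integer(assignment)
  if (anyNA(g) || any(g < 1L) || any(g > p$n))
    stop("assignment contains invalid nodes")
  exemplars <- unique(g)
  if (any(g[exemplars] != exemplars)) return(-Inf)
  sum(p$S[cbind(seq_len(p$n), g)])
}

#' Brute-force exemplar optimization (test oracle)
#'
#' Enumerates every nonempty exemplar subset (so only for `n <= 12`),
#' assigns each node to its best exemplar (itself when chosen), and returns
#' the configuration maximizing [net_similarity()].  Ties are broken by the
#' smaller exemplar set, then lexicographically on the sorted index set.
#'
#' @param p an `affinity_problem` with `n <= 12`
#' @return a `heat_clustering` (fields `ht`, `iterations`, `converged` are
#'   not meaningful and set to placeholders)
#' @export
brute_force_exemplars <- function(p) {
  stopifnot(inherits(p, "affinity_problem"))
  n <- p$n
  if (n > 12L) stop("brute force limited to n <= 12")
  best <- NULL
  for (mask in seq_len(2^n - 1L)) {
    ex <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    g <- integer(n)
    g[ex] <- ex
    rest <- setdiff(seq_len(n), ex)
    if (length(rest)) {
      sub <- p$S[rest, ex, drop = FALSE]
      g[rest] <- ex[max.col(sub, ties.method = "first")]
    }
    obj <- sum(p$S[cbind(seq_len(n), g)])
    key <- list(obj = obj, size = length(ex), ex = ex)
    if (is.null(best) || obj > best$obj + 1e-12 ||
        (abs(obj - best$obj) <= 1e-12 &&
         (length(ex) < best$size ||
          (length(ex) == best$size &&
           isTRUE(order_lex(ex, best$ex)))))) {
      best <- list(obj = obj, size = length(ex), ex = ex, g = g)
    }
  }
  assignment <- p$labels[best$g]
  names(assignment) <- p$labels
  structure(list(centers = p$labels[best$ex], assignment = assignment,
                 ht = matrix(NA_real_, n, n), objective = best$obj,
                 iterations = 0L, converged = TRUE),
            class = "heat_clustering")
}

# TRUE when integer vector a precedes b lexicographically
order_lex <- function(a, b) {
  m <- min(length(a), length(b))
  for (i in seq_len(m)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' End-to-end heat-passing clustering of a graph
#'
#' Convenience pipeline: normalized (or unnormalized) Laplacian, spectral
#' decomposition, heat kernel at time `t`, temperature preferences, then
#' the message-passing loop.
#'
#' @param g a `weighted_graph`
#' @param t diffusion time (default 4)
#' @param laplacian `"normalized"` (default) or `"unnormalized"`
#' @param k spectrum truncation (default `"full"` up to n = 2000, then 200)
#' @param pref_scale,pref_mode see [build_affinity()]
#' @param ... further arguments passed to [run_heat_passing()]
#' @return a `heat_clustering`
#' @export
heat_pass_graph <- function(g, t = 4, laplacian = c("normalized", "unnormalized"),
                            k = NULL, pref_scale = 1,
                            pref_mode = "mean-temperature", ...) {
  stopifnot(inherits(g, "weighted_graph"))
  laplacian <- match.arg(laplacian)
  L <- if (laplacian == "normalized") normalized_laplacian(g) else
    graph_laplacian(g)
  if (is.null(k)) k <- if (g$n <= 2000L) "full" else min(g$n, 200L)
  dec <- spectral_decompose(L, k = k)
  hk <- heat_kernel(dec, t)
  temp <- average_temperature(hk)
  p <- build_affinity(hk, temp, pref_scale = pref_scale, pref_mode = pref_mode)
  run_heat_passing(p, ...)
}
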