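# Path-optimality statistics: observed vs shortest-Hamiltonian-path distance,
# z-scored against participant-specific shuffled lists.

path_total <- function(d, idx) {
  n <- length(idx)
  if (n < 2L) return(0)
  sum(d[cbind(idx[-n], idx[-1L])])
}

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stopf("distance matrix must be square")
  if (any(d < 0)) stopf("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-8) stopf("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stopf("distance matrix must have zero diagonal")
  invisible(TRUE)
}

# Exact shortest Hamiltonian path by Held-Karp dynamic programming over
# subsets. Feasible for n <= ~13; used below the exact/heuristic threshold.
held_karp_path <- function(d, start = NULL) {
  n <- nrow(d)
  full <- bitwShiftL(1L, n) - 1L
  dp <- matrix(Inf, nrow = full, ncol = n)
  par <- matrix(NA_integer_, nrow = full, ncol = n)
  bit <- bitwShiftL(1L, seq_len(n) - 1L)
  if (is.null(start)) {
    for (j in seq_len(n)) dp[bit[j], j] <- 0
  } else {
    dp[bit[start], start] <- 0
  }
  for (mask in seq_len(full)) {
    js <- which(bitwAnd(mask, bit) > 0L)
    js <- js[is.finite(dp[mask, js])]
    if (length(js) == 0L) next
    ks <- which(bitwAnd(mask, bit) == 0L)
    if (length(ks) == 0L) next
    vals <- dp[mask, js]
    for (k in ks) {
      cand <- vals + d[js, k]
      b <- which.min(cand)
      nm <- mask + bit[k]
      if (cand[b] < dp[nm, k]) {
        dp[nm, k] <- cand[b]
        par[nm, k] <- js[b]
      }
    }
  }
  end <- which.min(dp[full, ])
  total <- dp[full, end]
  path <- integer(n)
  mask <- full
  j <- end
  for (i in n:1) {
    path[i] <- j
    pj <- par[mask, j]
    mask <- mask - bit[j]
    j <- pj
  }
  list(order = path, total = total, exact = TRUE)
}

nearest_neighbour_path <- function(d, start) {
  n <- nrow(d)
  path <- integer(n)
  visited <- logical(n)
  path[1L] <- start
  visited[start] <- TRUE
  for (i in 2:n) {
    row <- d[path[i - 1L], ]
    row[visited] <- Inf
    nxt <- which.min(row)
    path[i] <- nxt
    visited[nxt] <- TRUE
  }
  path
}

# 2-opt refinement of an open path: repeatedly reverse the segment [i..j]
# while any reversal shortens the total; with a fixed start, i >= 2.
two_opt_path <- function(d, path, fixed_start = FALSE, max_passes = 200L) {
  n <- length(path)
  lo <- if (fixed_start) 2L else 1L
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (i in lo:(n - 1L)) {
      js <- (i + 1L):n
      left <- if (i > 1L) d[path[i - 1L], path[js]] - d[path[i - 1L], path[i]] else 0
      right <- numeric(length(js))
      inner <- js < n
      if (any(inner)) {
        jin <- js[inner]
        right[inner] <- d[path[i], path[jin + 1L]] -
          d[cbind(path[jin], path[jin + 1L])]
      }
      delta <- left + right
      b <- which.min(delta)
      if (delta[b] < -1e-12) {
        j <- js[b]
        path[i:j] <- path[j:i]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  path
}

#' Shortest Hamiltonian path over a distance matrix
#'
#' Finds an ordering that visits every item exactly once with minimum total
#' edge distance (the "optimal" fluency trajectory). For `n <=
#' exact_max` (default 12) the solution is exactly optimal via Held-Karp
#' dynamic programming; beyond that a deterministic nearest-neighbour
#' construction refined by 2-opt provides a locally optimal upper bound.
#'
#' @param d symmetric nonnegative distance matrix with zero diagonal.
#' @param start optional index the path must begin at; `NULL` leaves both
#'   endpoints free.
#' @param exact_max largest `n` solved exactly.
#' @return list with `order` (index permutation), `total` (path distance)
#'   and `exact` (logical).
#' @export
shortest_hamiltonian_path <- function(d, start = NULL, exact_max = 12L) {
  d <- as.matrix(d)
  validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 2L) stopf("need at least two items for a path")
  if (!is.null(start)) {
    start <- as.integer(start)
    stopifnot(start >= 1L, start <= n)
  }
  if (n == 2L) {
    ord <- if (is.null(start) || start == 1L) c(1L, 2L) else c(2L, 1L)
    return(list(order = ord, total = d[1L, 2L], exact = TRUE))
  }
  if (n <= exact_max) return(held_karp_path(d, start))

  starts <- if (is.null(start)) {
    unique(round(seq(1L, n, length.out = min(n, 8L))))
  } else start
  best <- NULL
  for (s in starts) {
    p <- nearest_neighbour_path(d, s)
    p <- two_opt_path(d, p, fixed_start = !is.null(start))
    tot <- path_total(d, p)
    if (is.null(best) || tot < best$total) best <- list(order = p, total = tot)
  }
  best$exact <- FALSE
  best
}

# Resolve a fluency list (or plain character vector) to indices in sim.
sim_indices <- function(x, sim) {
  items <- if (inherits(x, "fluency_list")) x$items else normalize_word(x)
  idx <- match(items, sim$words)
  if (anyNA(idx))
    stopf("list items missing from similarity matrix: %s",
          paste(items[is.na(idx)], collapse = ", "))
  idx
}

# Core divergence computation on a local distance matrix (items already
# indexed 1..n in emission order). Computes the optimal path once and both
# the global and local statistics against a shared set of shuffles.
divergence_core <- function(d, n_shuffles, seed, start_policy) {
  n <- nrow(d)
  opt <- shortest_hamiltonian_path(d, start = if (start_policy == "first") 1L else NULL)
  obs <- path_total(d, seq_len(n))
  pos <- order(opt$order)   # pos[i] = position of emission i in the optimal path
  graw <- obs - opt$total
  lraw <- sum(abs(diff(pos)))
  gn <- numeric(n_shuffles)
  ln <- numeric(n_shuffles)
  with_seed(seed, {
    for (s in seq_len(n_shuffles)) {
      p <- sample.int(n)
      gn[s] <- path_total(d, p) - opt$total
      ln[s] <- sum(abs(diff(pos[p])))
    }
  })
  gz <- null_z(graw, gn)
  lz <- null_z(lraw, ln)
  list(observed_total = obs, optimal_total = opt$total, exact = opt$exact,
       global_raw = graw, global_z = gz$z,
       local_raw = lraw, local_z = lz$z,
       degenerate = gz$degenerate || lz$degenerate,
       global_null_mean = gz$null_mean, global_null_sd = gz$null_sd,
       local_null_mean = lz$null_mean, local_null_sd = lz$null_sd)
}

prepare_divergence <- function(flist, sim) {
  idx <- sim_indices(flist, sim)
  if (length(idx) < 3L) stopf("need at least 3 items (got %d)", length(idx))
  distance_matrix(sim)[idx, idx, drop = FALSE]
}

#' Global optimality divergence
#'
#' Total observed path distance minus the shortest-Hamiltonian-path total
#' over the same items, z-scored against uniformly shuffled orderings of the
#' participant's own list. z near 0 indicates a random word selection
#' process; negative z indicates similarity-guided (clustered) selection.
#'
#' @param flist a [fluency_list()] (or character vector of items).
#' @param sim a [similarity_matrix()] covering all list items.
#' @param n_shuffles number of list shuffles for the null (default 1000).
#' @param seed integer seed for the shuffle null.
#' @param start_policy `"free"` (default) leaves the optimal path's
#'   endpoints free, which keeps the shuffle null exactly exchangeable
#'   (the optimal path and its positions are then order-invariant);
#'   `"first"` constrains the optimal path to begin at the participant's
#'   first emitted word, mirroring path illustrations, at the cost of a
#'   small negative bias in the local-divergence null.
#' @return list with `observed_total`, `optimal_total`, `raw`
#'   (observed - optimal), `z`, a `degenerate` flag (zero null spread) and
#'   the shuffle-null moments.
#' @export
global_optimality_divergence <- function(flist, sim, n_shuffles = 1000L,
                                         seed = 1L,
                                         start_policy = c("free", "first")) {
  start_policy <- match.arg(start_policy)
  d <- prepare_divergence(flist, sim)
  r <- divergence_core(d, n_shuffles, seed, start_policy)
  list(observed_total = r$observed_total, optimal_total = r$optimal_total,
       raw = r$global_raw, z = r$global_z,
       degenerate = is.na(r$global_z),
       null_mean = r$global_null_mean, null_sd = r$global_null_sd,
       n_shuffles = as.integer(n_shuffles), exact = r$exact)
}

#' Local optimality divergence
#'
#' Each consecutive observed transition (a, b) is scored by the number of
#' edges separating a and b in the optimal path ordering; the raw statistic
#' is the sum of these scores, z-scored against shuffled orderings exactly
#' as in [global_optimality_divergence()].
#'
#' @inheritParams global_optimality_divergence
#' @return list with `raw`, `z`, `degenerate` flag and null moments.
#' @export
local_optimality_divergence <- function(flist, sim, n_shuffles = 1000L,
                                        seed = 1L,
                                        start_policy = c("free", "first")) {
  start_policy <- match.arg(start_policy)
  d <- prepare_divergence(flist, sim)
  r <- divergence_core(d, n_shuffles, seed, start_policy)
  list(raw = r$local_raw, z = r$local_z,
       degenerate = is.na(r$local_z),
       null_mean = r$local_null_mean, null_sd = r$local_null_sd,
       n_shuffles = as.integer(n_shuffles), exact = r$exact)
}

#' Sliding-window trajectory metrics
#'
#' Computes global and local optimality divergence in every contiguous
#' window of the given length (stride 1), z-scores each window against
#' within-window shuffles, and averages across windows. Windowing controls
#' for differences in list length between participants; the conventional
#' window is the task-wide minimum list length. With `window` equal to the
#' list length this reduces to the unwindowed statistics.
#'
#' @inheritParams global_optimality_divergence
#' @param window window length; `NULL` uses the whole list (single window).
#' @return a one-row `data.frame` (class `trajectory_metrics`) with columns
#'   `metric`, `observed_total`, `optimal_total`, `global_raw`, `global_z`,
#'   `local_raw`, `local_z`, `window_length`, `n_windows`, `n_shuffles`,
#'   `degenerate`. Totals and raw divergences are window means.
#' @export
windowed_metrics <- function(flist, sim, window = NULL, n_shuffles = 1000L,
                             seed = 1L, start_policy = c("free", "first")) {
  start_policy <- match.arg(start_policy)
  idx <- sim_indices(flist, sim)
  n <- length(idx)
  if (is.null(window)) window <- n
  window <- as.integer(window)
  if (window > n)
    stopf("window (%d) exceeds list length (%d); lower the window", window, n)
  if (window < 3L) stopf("window must be at least 3")
  d_full <- distance_matrix(sim)
  starts <- seq_len(n - window + 1L)
  res <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    widx <- idx[starts[k]:(starts[k] + window - 1L)]
    # a single whole-list window reproduces the unwindowed statistics
    wseed <- if (length(starts) == 1L) seed else substream_seed(seed, k)
    res[[k]] <- divergence_core(d_full[widx, widx, drop = FALSE], n_shuffles,
                                wseed, start_policy)
  }
  g <- function(f) vapply(res, `[[`, 0, f)
  out <- data.frame(
    metric = sim$metric,
    observed_total = mean(g("observed_total")),
    optimal_total = mean(g("optimal_total")),
    global_raw = mean(g("global_raw")), global_z = mean(g("global_z")),
    local_raw = mean(g("local_raw")), local_z = mean(g("local_z")),
    window_length = window, n_windows = length(starts),
    n_shuffles = as.integer(n_shuffles),
    degenerate = any(vapply(res, `[[`, TRUE, "degenerate")),
    stringsAsFactors = FALSE
  )
  class(out) <- c("trajectory_metrics", class(out))
  out
}

#' Consecutive vs all-pairs distance summary
#'
#' Distances between consecutively emitted word pairs, and between all
#' unique word pairs in the list, for descriptive comparison and pooling.
#'
#' @inheritParams global_optimality_divergence
#' @return list with `mean_consecutive`, `mean_all_pairs`, `consecutive`
#'   (vector of n-1 distances) and `all_pairs` (vector of n(n-1)/2
#'   distances).
#' @export
consecutive_distance_summary <- function(flist, sim) {
  idx <- sim_indices(flist, sim)
  n <- length(idx)
  if (n < 2L) stopf("need at least 2 items")
  d <- distance_matrix(sim)[idx, idx, drop = FALSE]
  consec <- d[cbind(seq_len(n - 1L), 2:n)]
  allp <- d[upper.tri(d)]
  list(mean_consecutive = mean(consec), mean_all_pairs = mean(allp),
       consecutive = consec, all_pairs = allp)
}
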