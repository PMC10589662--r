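# Semantic communities: Louvain partition of the similarity graph and
# community-trajectory statistics (lifetimes, returns, RT regression).

#' Louvain partition of a similarity matrix
#'
#' Builds a complete weighted graph on the unique items with edge weight
#' `max(similarity, 0)` (negative cosines carry no attachment weight under
#' modularity) and runs Louvain modularity maximisation at the given
#' resolution. Deterministic under a fixed seed.
#'
#' @param sim a [similarity_matrix()] with at least 3 items.
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed integer seed controlling the algorithm's internal ordering.
#' @return a `community_partition` object with fields `words`, `labels`
#'   (0-based contiguous community indices per word), `resolution`,
#'   `modularity` and `n_communities`.
#' @export
louvain_partition <- function(sim, resolution = 1, seed = 1L) {
  stopifnot(inherits(sim, "similarity_matrix"))
  n <- length(sim$words)
  if (n < 3L) stopf("need at least 3 items to partition")
  w <- pmax(sim$values, 0)
  diag(w) <- 0
  if (all(w == 0)) stopf("similarity graph has no positive-weight edges")
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(cl)
  labels <- as.integer(factor(memb, levels = unique(memb))) - 1L
  structure(
    list(words = sim$words, labels = labels, resolution = resolution,
         modularity = igraph::modularity(g, memb,
                                         weights = igraph::E(g)$weight,
                                         resolution = resolution),
         n_communities = length(unique(labels)), seed = as.integer(seed)),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d words, %d communities (resolution %g, modularity %.3f)\n",
              length(x$words), x$n_communities, x$resolution, x$modularity))
  invisible(x)
}

# Map a fluency list (or word vector) onto community labels.
community_labels <- function(x, partition) {
  items <- if (inherits(x, "fluency_list")) x$items else normalize_word(x)
  idx <- match(items, partition$words)
  if (anyNA(idx))
    stopf("items missing from community partition: %s",
          paste(items[is.na(idx)], collapse = ", "))
  partition$labels[idx]
}

#' Community lifetimes of a label sequence
#'
#' Maximal runs of identical consecutive community labels; the mean run
#' length is the mean community "lifetime".
#'
#' @param labels vector of community labels in emission order.
#' @return list with `runs` (run lengths) and `mean` lifetime.
#' @export
#' @examples
#' community_lifetimes(c("A", "A", "B", "A"))  # runs 2,1,1; mean 4/3
community_lifetimes <- function(labels) {
  if (length(labels) == 0L) stopf("empty label sequence")
  r <- rle(as.vector(labels))
  list(runs = r$lengths, mean = mean(r$lengths))
}

#' Community returns of a label sequence
#'
#' Number of times the list revisits a community after exiting it: for each
#' community, (number of maximal runs - 1), summed.
#'
#' @param labels vector of community labels in emission order.
#' @return integer count of returns.
#' @export
#' @examples
#' community_returns(c("A", "B", "A", "B"))  # 2
community_returns <- function(labels) {
  if (length(labels) == 0L) stopf("empty label sequence")
  r <- rle(as.vector(labels))
  as.integer(length(r$lengths) - length(unique(r$values)))
}

#' Windowed community-trajectory statistics
#'
#' Mean community lifetime and number of community returns, z-scored
#' against shuffled item orders within each sliding window (stride 1) and
#' averaged across windows, mirroring [windowed_metrics()].
#'
#' @param flist a [fluency_list()] (or character vector of items).
#' @param partition a [louvain_partition()] labelling every list item.
#' @param n_shuffles shuffles per window (default 1000).
#' @param seed integer seed.
#' @param window window length; `NULL` uses the whole list.
#' @return one-row `data.frame` with `lifetime_raw`, `lifetime_z`,
#'   `returns_raw`, `returns_z`, `window_length`, `n_windows`,
#'   `n_shuffles`, `degenerate` (TRUE when the shuffle null has no spread,
#'   e.g. a single-community list, in which case z is NA).
#' @export
community_stats_z <- function(flist, partition, n_shuffles = 1000L, seed = 1L,
                              window = NULL) {
  lab <- community_labels(flist, partition)
  n <- length(lab)
  if (n < 3L) stopf("need at least 3 items (got %d)", n)
  if (is.null(window)) window <- n
  window <- as.integer(window)
  if (window > n)
    stopf("window (%d) exceeds list length (%d); lower the window", window, n)
  if (window < 3L) stopf("window must be at least 3")
  starts <- seq_len(n - window + 1L)
  lt_raw <- lt_z <- rt_raw <- rt_z <- numeric(length(starts))
  degen <- FALSE
  for (k in seq_along(starts)) {
    wl <- lab[starts[k]:(starts[k] + window - 1L)]
    olt <- community_lifetimes(wl)$mean
    ort <- community_returns(wl)
    nl <- numeric(n_shuffles)
    nr <- numeric(n_shuffles)
    with_seed(substream_seed(seed, k), {
      for (s in seq_len(n_shuffles)) {
        p <- wl[sample.int(window)]
        r <- rle(p)
        nl[s] <- mean(r$lengths)
        nr[s] <- length(r$lengths) - length(unique(r$values))
      }
    })
    zl <- null_z(olt, nl); zr <- null_z(ort, nr)
    lt_raw[k] <- olt; rt_raw[k] <- ort
    lt_z[k] <- zl$z; rt_z[k] <- zr$z
    degen <- degen || zl$degenerate || zr$degenerate
  }
  data.frame(
    lifetime_raw = mean(lt_raw), lifetime_z = mean(lt_z),
    returns_raw = mean(rt_raw), returns_z = mean(rt_z),
    window_length = window, n_windows = length(starts),
    n_shuffles = as.integer(n_shuffles), degenerate = degen,
    stringsAsFactors = FALSE
  )
}

#' Retrieval-time regression
#'
#' Per-participant OLS of log inter-item retrieval time on (1) the demeaned
#' semantic distance between the current and previous item, (2) a
#' community-switch indicator, (3) the response number as a proportion of
#' list length, and (4) an intercept. The first item has no predecessor and
#' is excluded; transitions with nonpositive retrieval time are dropped and
#' counted.
#'
#' @param flist a timed [fluency_list()].
#' @param sim a [similarity_matrix()] (semantic) covering the list items.
#' @param partition a [louvain_partition()] labelling the list items.
#' @return list with `coefficients` (named: `intercept`, `semantic_distance`,
#'   `community_switch`, `response_number`), `n_items` (usable transitions),
#'   `n_dropped` and the fitted `model`.
#' @export
rt_regression <- function(flist, sim, partition) {
  stopifnot(inherits(flist, "fluency_list"))
  if (is.null(flist$times_s)) stopf("fluency list has no retrieval times")
  idx <- sim_indices(flist, sim)
  lab <- community_labels(flist, partition)
  n <- length(idx)
  d <- distance_matrix(sim)
  rt <- diff(flist$times_s)
  semd <- d[cbind(idx[-n], idx[-1L])]
  switch_ind <- as.numeric(lab[-n] != lab[-1L])
  resp_prop <- (2:n) / n
  keep <- rt > 0
  n_dropped <- sum(!keep)
  if (sum(keep) < 6L)
    stopf("need at least 6 usable transitions (got %d)", sum(keep))
  df <- data.frame(
    log_rt = log(rt[keep]),
    semantic_distance = semd[keep] - mean(semd[keep]),
    community_switch = switch_ind[keep],
    response_number = resp_prop[keep]
  )
  fit <- lm(log_rt ~ semantic_distance + community_switch + response_number,
            data = df)
  if (any(is.na(coef(fit)))) stopf("rank-deficient retrieval-time design")
  co <- coef(fit)
  names(co) <- c("intercept", "semantic_distance", "community_switch",
                 "response_number")
  list(coefficients = co, n_items = nrow(df), n_dropped = n_dropped,
       model = fit)
}

#' Label communities by their most central vocabulary words
#'
#' For each community, the centroid is the mean member vector; the `k`
#' vocabulary words with highest cosine similarity to the centroid are
#' returned (ties broken by similarity descending, then lexicographically).
#'
#' @param partition a [louvain_partition()].
#' @param space an [embedding_space()] supplying candidate vocabulary.
#' @param k number of label words per community.
#' @return named list (one element per community index) of character
#'   vectors of length `k`.
#' @export
label_communities <- function(partition, space, k = 3L) {
  v <- space$vectors / sqrt(rowSums(space$vectors^2))
  out <- list()
  for (cm in sort(unique(partition$labels))) {
    members <- partition$words[partition$labels == cm]
    mi <- match(members, space$words)
    if (anyNA(mi))
      stopf("community members missing from embedding space: %s",
            paste(members[is.na(mi)], collapse = ", "))
    centroid <- colMeans(space$vectors[mi, , drop = FALSE])
    cn <- sqrt(sum(centroid^2))
    if (cn == 0) stopf("community %d has a zero centroid", cm)
    sims <- as.vector(v %*% (centroid / cn))
    ord <- order(-sims, space$words)
    out[[as.character(cm)]] <- space$words[ord][seq_len(min(k, length(sims)))]
  }
  out
}
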