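# Independent oracles and fixture builders used across the suite.

# Textbook dynamic-programming Levenshtein, independent of utils::adist.
dp_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                               d[i, j] + (x[i] != y[j]))
    }
  }
  d[n + 1L, m + 1L]
}

# Exhaustive-enumeration shortest Hamiltonian path (recursive permutation
# search), independent of the package solver.
brute_force_path <- function(d, start = NULL) {
  n <- nrow(d)
  best <- Inf
  recurse <- function(remaining, last, acc) {
    if (length(remaining) == 0L) {
      if (acc < best) best <<- acc
      return(invisible())
    }
    for (i in seq_along(remaining)) {
      nxt <- remaining[i]
      a2 <- acc + if (is.na(last)) 0 else d[last, nxt]
      if (a2 < best) recurse(remaining[-i], nxt, a2)
    }
  }
  if (is.null(start)) recurse(seq_len(n), NA_integer_, 0)
  else recurse(setdiff(seq_len(n), start), start, 0)
  best
}

# Random symmetric distance matrix with zero diagonal.
random_distance_matrix <- function(n) {
  m <- matrix(runif(n * n), n, n)
  d <- (m + t(m)) / 2
  diag(d) <- 0
  d
}

# Hand-built similarity_matrix over explicit values.
manual_similarity <- function(words, values, metric = "semantic") {
  dimnames(values) <- list(words, words)
  structure(list(words = words, values = values, metric = metric,
                 normalized = TRUE),
            class = "similarity_matrix")
}

# Manual 2x2 mixed-design ANOVA by sums of squares (oracle for mixed_anova).
manual_mixed_anova_F <- function(data) {
  y <- xtabs(value ~ participant_id + task, data)
  grp <- data$group[match(rownames(y), data$participant_id)]
  subj_mean <- rowMeans(y)
  grand <- mean(y)
  cellm <- do.call(rbind, lapply(split(seq_len(nrow(y)), grp),
                                 function(i) colMeans(y[i, , drop = FALSE])))
  gm <- rowMeans(cellm); tm <- colMeans(cellm)
  N <- nrow(y)
  ss_group <- 2 * sum(table(grp) * (gm - grand)^2)
  ss_subj <- 2 * sum((subj_mean - gm[grp])^2)
  ss_task <- N * sum((tm - grand)^2)
  ss_int <- (N / 2) * sum((sweep(sweep(cellm, 1, gm), 2, tm) + grand)^2)
  ss_err <- sum((y - cellm[grp, ] - (subj_mean - gm[grp]))^2)
  c(group = (ss_group / 1) / (ss_subj / (N - 2)),
    task = (ss_task / 1) / (ss_err / (N - 2)),
    interaction = (ss_int / 1) / (ss_err / (N - 2)))
}

# Small planted space + matching similarity matrices, shared across tests.
test_space_cache <- new.env(parent = emptyenv())
small_task_setup <- function(vocab = 120L, dim = 60L, n_communities = 4L,
                             within = 0.55, between = 0.10, seed = 42L,
                             key = NULL) {
  key <- key %||% paste(vocab, dim, n_communities, within, between, seed,
                        sep = "_")
  if (!is.null(test_space_cache[[key]])) return(test_space_cache[[key]])
  sp <- make_embedding_space(vocab, dim, n_communities, within, between,
                             seed = seed)
  out <- list(
    space = sp,
    sims = list(semantic = similarity_matrix(sp$words, sp, "semantic"),
                orthographic = similarity_matrix(sp$words,
                                                 metric = "orthographic")))
  test_space_cache[[key]] <- out
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a tiny word2vec-format embedding file; returns its path.
write_vec_file <- function(lines) {
  path <- tempfile(fileext = ".vec")
  writeLines(lines, path)
  path
}
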