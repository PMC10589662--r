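# Similarity-space construction: embedding cosine (semantic) and
# normalised Levenshtein (orthographic) similarity over a task vocabulary.

#' Load a word-embedding table
#'
#' Reads word vectors from word2vec/fastText text format: an optional header
#' line `"<n> <d>"` followed by one `word v1 ... vd` row per line. Words are
#' normalised with [normalize_word()]; when the same normalised token occurs
#' more than once the first row wins.
#'
#' @param path path to a `.vec`-style text file.
#' @param vocabulary optional character vector; only matching rows are
#'   returned (in vocabulary order). Requested words missing from the file
#'   are reported in the `oov` field, not silently dropped.
#' @return an object of class `embedding_space` with fields `words`,
#'   `vectors` (matrix, one row per word), `dim` and `oov` (character vector
#'   of out-of-vocabulary requests, empty when none).
#' @export
load_embeddings <- function(path, vocabulary = NULL) {
  if (!file.exists(path)) stopf("embedding file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("embedding file is empty: %s", path)

  toks1 <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  has_header <- length(toks1) == 2L &&
    !anyNA(suppressWarnings(as.integer(toks1)))
  body <- if (has_header) lines[-1L] else lines
  if (length(body) == 0L) stopf("embedding file has a header but no rows: %s", path)

  parsed <- strsplit(trimws(body), "\\s+")
  dims <- lengths(parsed) - 1L
  d <- dims[[1L]]
  if (d < 1L) stopf("malformed embedding line %d: no vector values", if (has_header) 2L else 1L)
  bad <- which(dims != d)
  if (length(bad) > 0L) {
    stopf("malformed embedding line %d: expected %d values, found %d",
          bad[[1L]] + if (has_header) 1L else 0L, d, dims[[bad[[1L]]]])
  }
  words <- normalize_word(vapply(parsed, `[[`, "", 1L))
  vals <- suppressWarnings(
    vapply(parsed, function(p) as.numeric(p[-1L]), numeric(d))
  )
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 2L, any))[[1L]]
    stopf("malformed embedding line %d: non-numeric vector value",
          bad + if (has_header) 1L else 0L)
  }
  vectors <- t(vals)
  keep <- !duplicated(words)
  words <- words[keep]
  vectors <- vectors[keep, , drop = FALSE]

  oov <- character(0)
  if (!is.null(vocabulary)) {
    vocab <- unique(normalize_word(vocabulary))
    idx <- match(vocab, words)
    oov <- vocab[is.na(idx)]
    idx <- idx[!is.na(idx)]
    words <- words[idx]
    vectors <- vectors[idx, , drop = FALSE]
  }
  rownames(vectors) <- words
  embedding_space(words, vectors, oov = oov)
}

#' Construct an embedding space
#'
#' @param words character vector of unique normalised words.
#' @param vectors numeric matrix, one row per word.
#' @param oov character vector of out-of-vocabulary words recorded at load.
#' @return an `embedding_space` object.
#' @export
embedding_space <- function(words, vectors, oov = character(0)) {
  vectors <- as.matrix(vectors)
  if (anyDuplicated(words)) stopf("duplicate words in embedding space")
  if (nrow(vectors) != length(words))
    stopf("vector row count (%d) != word count (%d)", nrow(vectors), length(words))
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) stopf("zero-norm vector for word(s): %s",
                           paste(words[nrm == 0], collapse = ", "))
  rownames(vectors) <- words
  structure(
    list(words = as.character(words), vectors = vectors,
         dim = ncol(vectors), oov = oov),
    class = "embedding_space"
  )
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("<embedding_space> %d words, dim %d", length(x$words), x$dim))
  if (length(x$oov)) cat(sprintf(" (%d OOV requests recorded)", length(x$oov)))
  cat("\n")
  invisible(x)
}

#' Cosine similarity of two vectors
#'
#' `v . w / (||v|| ||w||)`; semantic distance is one minus this value.
#'
#' @param v,w numeric vectors of equal length, both nonzero.
#' @return cosine similarity in \[-1, 1\].
#' @export
#' @examples
#' cosine_similarity(c(1, 1), c(1, 0))  # 1/sqrt(2)
cosine_similarity <- function(v, w) {
  if (length(v) != length(w)) stopf("vectors differ in dimension (%d vs %d)",
                                    length(v), length(w))
  nv <- sqrt(sum(v^2)); nw <- sqrt(sum(w^2))
  if (nv == 0 || nw == 0) stopf("cosine similarity undefined for a zero vector")
  max(-1, min(1, sum(v * w) / (nv * nw)))
}

#' Levenshtein (orthographic) edit distance
#'
#' Minimum number of single-character insertions, deletions or substitutions
#' transforming `a` into `b`.
#'
#' @param a,b character scalars (empty strings allowed).
#' @return nonnegative integer edit distance.
#' @export
#' @examples
#' levenshtein_distance("kitten", "sitting")  # 3
levenshtein_distance <- function(a, b) {
  as.integer(adist(as.character(a), as.character(b))[1L, 1L])
}

#' Pairwise similarity matrix over a set of items
#'
#' Semantic similarity is the pairwise embedding cosine; orthographic
#' similarity defaults to `1 - levenshtein(a, b) / max(nchar(a), nchar(b))`
#' so that both metrics live on comparable bounded scales (`normalize =
#' FALSE` keeps the raw negated edit distance instead).
#'
#' @param items character vector of words (unique after normalisation).
#' @param space an `embedding_space`; required for `metric = "semantic"`.
#' @param metric `"semantic"` or `"orthographic"`.
#' @param normalize logical; normalise orthographic similarity by the longer
#'   word length (default `TRUE`).
#' @return a `similarity_matrix` object with fields `words`, `values`
#'   (symmetric matrix) and `metric`.
#' @export
similarity_matrix <- function(items, space = NULL,
                              metric = c("semantic", "orthographic"),
                              normalize = TRUE) {
  metric <- match.arg(metric)
  items <- normalize_word(items)
  if (anyDuplicated(items)) stopf("duplicate items after normalisation: %s",
                                  paste(unique(items[duplicated(items)]), collapse = ", "))
  n <- length(items)
  if (n < 1L) stopf("no items supplied")

  if (metric == "semantic") {
    if (is.null(space)) stopf("semantic metric requires an embedding space")
    idx <- match(items, space$words)
    if (anyNA(idx)) stopf("items missing from embedding vocabulary: %s",
                          paste(items[is.na(idx)], collapse = ", "))
    v <- space$vectors[idx, , drop = FALSE]
    v <- v / sqrt(rowSums(v^2))
    s <- tcrossprod(v)
    s[s > 1] <- 1; s[s < -1] <- -1
    diag(s) <- 1
  } else {
    if (any(!nzchar(items))) stopf("orthographic metric requires nonempty strings")
    d <- adist(items)
    if (normalize) {
      len <- nchar(items)
      s <- 1 - d / outer(len, len, pmax)
      diag(s) <- 1
    } else {
      s <- -d
    }
  }
  s <- (s + t(s)) / 2
  dimnames(s) <- list(items, items)
  structure(list(words = items, values = s, metric = metric,
                 normalized = if (metric == "orthographic") normalize else TRUE),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %s, %d items\n", x$metric, length(x$words)))
  invisible(x)
}

#' Distance matrix corresponding to a similarity matrix
#'
#' Semantic distance is `1 - cosine similarity`; normalised orthographic
#' distance is `1 - orthographic similarity` (i.e. edit distance over the
#' longer word length); unnormalised orthographic similarity maps back to
#' the raw edit distance.
#'
#' @param sim a `similarity_matrix`.
#' @return symmetric nonnegative matrix with zero diagonal.
#' @export
distance_matrix <- function(sim) {
  stopifnot(inherits(sim, "similarity_matrix"))
  d <- if (sim$metric == "orthographic" && !isTRUE(sim$normalized))
    -sim$values else 1 - sim$values
  diag(d) <- 0
  d[d < 0] <- 0
  d
}
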