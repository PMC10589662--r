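# Internal helpers shared across modules.

#' Normalise a response word
#'
#' Lowercases, trims surrounding whitespace and joins multiword responses
#' with underscores (the token convention of pretrained fastText-style
#' embeddings, where "polar bear" is stored as "polar_bear").
#'
#' @param x character vector of raw responses.
#' @return character vector of normalised tokens.
#' @export
#' @examples
#' normalize_word(c("  Polar Bear ", "CAT"))
normalize_word <- function(x) {
  gsub("\\s+", "_", trimws(tolower(as.character(x))))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. seed = NULL runs code untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seed for participant/replicate i under master seed.
# Kept below 2^31 - 1.
substream_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1009L + as.double(i) * 9973L) %% 2147483563)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# z-score of an observed value against a permutation null; returns NA with a
# degenerate flag when the null has (near) zero spread.
null_z <- function(observed, null_values) {
  m <- mean(null_values)
  s <- sd(null_values)
  if (!is.finite(s) || s < 1e-12) {
    list(z = NA_real_, degenerate = TRUE, null_mean = m, null_sd = s)
  } else {
    list(z = (observed - m) / s, degenerate = FALSE, null_mean = m, null_sd = s)
  }
}
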