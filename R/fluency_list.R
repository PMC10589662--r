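# FluencyList: one participant x task ordered word sequence with optional
# per-item retrieval timestamps.

#' Construct a fluency list
#'
#' @param participant_id scalar id.
#' @param group `"control"` or `"patient"`.
#' @param task `"category"` or `"letter"`.
#' @param items ordered character vector of responses; normalised with
#'   [normalize_word()] and required to be unique afterwards.
#' @param times_s optional numeric vector of cumulative response times in
#'   seconds, same length as `items`, nondecreasing.
#' @return a `fluency_list` object.
#' @export
fluency_list <- function(participant_id, group = c("control", "patient"),
                         task = c("category", "letter"),
                         items, times_s = NULL) {
  group <- match.arg(group)
  task <- match.arg(task)
  items <- normalize_word(items)
  if (anyDuplicated(items))
    stopf("fluency list for %s/%s contains repeated items after normalisation: %s",
          participant_id, task,
          paste(unique(items[duplicated(items)]), collapse = ", "))
  if (!is.null(times_s)) {
    times_s <- as.numeric(times_s)
    if (length(times_s) != length(items))
      stopf("times_s length (%d) != items length (%d)",
            length(times_s), length(items))
    if (any(diff(times_s) < 0))
      stopf("times_s must be nondecreasing for %s/%s", participant_id, task)
  }
  structure(
    list(participant_id = as.character(participant_id), group = group,
         task = task, items = items, times_s = times_s),
    class = "fluency_list"
  )
}

#' @export
print.fluency_list <- function(x, ...) {
  cat(sprintf("<fluency_list> %s [%s, %s]: %d items%s\n",
              x$participant_id, x$group, x$task, length(x$items),
              if (is.null(x$times_s)) "" else ", timed"))
  invisible(x)
}

#' @export
length.fluency_list <- function(x) length(x$items)
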