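# Ingestion, validation and end-to-end orchestration.

#' Read and validate fluency lists
#'
#' Accepts a CSV/TSV path or a data.frame with columns `participant_id`,
#' `group`, `task`, `position`, `word` and optionally `time_s`. Words are
#' normalised; exact within-list repeats are dropped and logged as
#' perseverations; non-monotone timestamps disable time-based analyses for
#' that list (flagged, not fatal).
#'
#' @param x file path or data.frame.
#' @return list with `lists` (list of [fluency_list()]) and `report`
#'   (data.frame: one row per participant x task with raw/unique counts,
#'   perseveration count and a `times_ok` flag).
#' @export
validate_lists <- function(x) {
  df <- if (is.character(x)) {
    if (!file.exists(x)) stopf("list file not found: %s", x)
    sep <- if (grepl("\\.tsv$", x, ignore.case = TRUE)) "\t" else ","
    read.delim(x, sep = sep, stringsAsFactors = FALSE)
  } else as.data.frame(x)
  need <- c("participant_id", "group", "task", "position", "word")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stopf("missing required columns: %s", paste(miss, collapse = ", "))
  has_time <- "time_s" %in% names(df)
  key <- paste(df$participant_id, df$task, df$position, sep = "\r")
  if (anyDuplicated(key))
    stopf("duplicate (participant_id, task, position) keys: %s",
          paste(head(unique(key[duplicated(key)]), 3L), collapse = "; "))

  lists <- list()
  rep_rows <- list()
  for (pid in unique(df$participant_id)) {
    for (task in unique(df$task[df$participant_id == pid])) {
      sub <- df[df$participant_id == pid & df$task == task, , drop = FALSE]
      sub <- sub[order(sub$position), , drop = FALSE]
      words <- normalize_word(sub$word)
      dup <- duplicated(words)
      times <- if (has_time) as.numeric(sub$time_s)[!dup] else NULL
      times_ok <- TRUE
      if (!is.null(times)) {
        if (anyNA(times) || any(diff(times) < 0)) {
          times_ok <- FALSE
          times <- NULL
        }
      }
      lists[[length(lists) + 1L]] <- fluency_list(
        pid, group = unique(sub$group)[1L], task = task,
        items = words[!dup], times_s = times)
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        participant_id = pid, task = task,
        n_raw = nrow(sub), n_unique = sum(!dup),
        n_perseverations = sum(dup), times_ok = !has_time || times_ok,
        stringsAsFactors = FALSE)
    }
  }
  list(lists = lists, report = do.call(rbind, rep_rows))
}

# Restrict a similarity matrix to a subset of its words.
subset_similarity <- function(sim, words) {
  idx <- match(words, sim$words)
  if (anyNA(idx)) stopf("words missing from similarity matrix: %s",
                        paste(words[is.na(idx)], collapse = ", "))
  structure(list(words = words,
                 values = sim$values[idx, idx, drop = FALSE],
                 metric = sim$metric, normalized = sim$normalized),
            class = "similarity_matrix")
}

lists_meta <- function(lists) {
  data.frame(
    participant_id = vapply(lists, `[[`, "", "participant_id"),
    group = vapply(lists, `[[`, "", "group"),
    task = vapply(lists, `[[`, "", "task"),
    n_items = vapply(lists, function(l) length(l$items), 0L),
    timed = vapply(lists, function(l) !is.null(l$times_s), TRUE),
    stringsAsFactors = FALSE)
}

#' End-to-end analysis of a cohort
#'
#' Runs the full pipeline on a set of fluency lists: per-list trajectory
#' metrics (optimality divergence z-scores), per-task Louvain partitions
#' with community-trajectory statistics and retrieval-time regressions,
#' per-participant choice-model fits with delta-omega, and the group-level
#' statistical report.
#'
#' @param lists list of [fluency_list()] objects (both tasks per
#'   participant for choice modelling).
#' @param sims named per-task list of similarity matrices over each task's
#'   pooled vocabulary (`sims$category$semantic` etc.), e.g. from
#'   [simulate_cohort()] or built from an embedding via
#'   [similarity_matrix()].
#' @param covariates optional data.frame with `participant_id` and scalar
#'   covariates (`ripple`, `symptom`, `medication`, ...).
#' @param metric similarity channel for the trajectory stage.
#' @param window `"full"` (whole list), `"auto"` (task-wide minimum list
#'   length) or an integer window length.
#' @param n_shuffles shuffles for every permutation null.
#' @param seed master seed.
#' @param models character vector of [model_registry()] names to fit.
#' @param policy candidate-set policy for the choice model.
#' @param n_starts optimizer starts per fit.
#' @param resolution Louvain resolution.
#' @param trajectory_tasks tasks to run the trajectory/community stages on
#'   (default both).
#' @return list with `trajectory`, `consecutive`, `partitions`,
#'   `community_stats`, `rt_fits`, `fits`, `modulation`, `model_comparison`
#'   (when more than one model), `report` and `meta`.
#' @export
analyze_cohort <- function(lists, sims, covariates = NULL,
                           metric = "semantic", window = "full",
                           n_shuffles = 1000L, seed = 1L,
                           models = "semantic_orthographic_task",
                           policy = "without_replacement", n_starts = 5L,
                           resolution = 1,
                           trajectory_tasks = c("category", "letter")) {
  meta <- lists_meta(lists)
  registry <- model_registry()
  unknown <- setdiff(models, names(registry))
  if (length(unknown) > 0L)
    stopf("unknown model(s): %s", paste(unknown, collapse = ", "))

  # --- trajectory stage ---------------------------------------------------
  traj <- list()
  consec <- list()
  for (i in seq_along(lists)) {
    fl <- lists[[i]]
    if (!fl$task %in% trajectory_tasks) next
    sim <- sims[[fl$task]][[metric]]
    win <- if (identical(window, "full")) length(fl$items)
    else if (identical(window, "auto"))
      min(meta$n_items[meta$task == fl$task])
    else as.integer(window)
    tm <- windowed_metrics(fl, sim, window = win, n_shuffles = n_shuffles,
                           seed = substream_seed(seed, i))
    cd <- consecutive_distance_summary(fl, sims[[fl$task]]$semantic)
    traj[[length(traj) + 1L]] <- cbind(
      data.frame(participant_id = fl$participant_id, group = fl$group,
                 task = fl$task, n_items = length(fl$items),
                 stringsAsFactors = FALSE), tm)
    consec[[length(consec) + 1L]] <- data.frame(
      participant_id = fl$participant_id, group = fl$group, task = fl$task,
      mean_consecutive = cd$mean_consecutive,
      mean_all_pairs = cd$mean_all_pairs, stringsAsFactors = FALSE)
  }
  trajectory <- do.call(rbind, traj)
  consecutive <- do.call(rbind, consec)

  # --- community stage (pooled unique items per task) ---------------------
  partitions <- list()
  cstats <- list()
  rt_rows <- list()
  for (task in intersect(trajectory_tasks, unique(meta$task))) {
    task_lists <- lists[vapply(lists, function(l) l$task == task, TRUE)]
    pooled <- unique(unlist(lapply(task_lists, `[[`, "items")))
    psim <- subset_similarity(sims[[task]]$semantic, pooled)
    part <- louvain_partition(psim, resolution = resolution,
                              seed = substream_seed(seed, 7L))
    partitions[[task]] <- part
    for (fl in task_lists) {
      win <- if (identical(window, "full")) length(fl$items)
      else if (identical(window, "auto"))
        min(meta$n_items[meta$task == task])
      else as.integer(window)
      cs <- community_stats_z(fl, part, n_shuffles = n_shuffles,
                              seed = substream_seed(seed, 5000L + length(cstats)),
                              window = win)
      cstats[[length(cstats) + 1L]] <- cbind(
        data.frame(participant_id = fl$participant_id, group = fl$group,
                   task = task, stringsAsFactors = FALSE), cs)
      if (!is.null(fl$times_s) && length(fl$items) >= 8L) {
        rt <- tryCatch(rt_regression(fl, sims[[task]]$semantic, part),
                       error = function(e) NULL)
        if (!is.null(rt)) {
          rt_rows[[length(rt_rows) + 1L]] <- data.frame(
            participant_id = fl$participant_id, group = fl$group, task = task,
            switch_coef = rt$coefficients[["community_switch"]],
            semdist_coef = rt$coefficients[["semantic_distance"]],
            respnum_coef = rt$coefficients[["response_number"]],
            intercept = rt$coefficients[["intercept"]],
            n_items = rt$n_items, stringsAsFactors = FALSE)
        }
      }
    }
  }
  community_stats <- if (length(cstats)) do.call(rbind, cstats) else NULL
  rt_fits <- if (length(rt_rows)) do.call(rbind, rt_rows) else NULL

  # --- choice-model stage -------------------------------------------------
  ids <- unique(meta$participant_id)
  fits <- list()
  fit_rows <- list()
  for (i in seq_along(ids)) {
    plists <- lists[vapply(lists, function(l) l$participant_id == ids[i], TRUE)]
    grp <- plists[[1L]]$group
    for (mname in models) {
      fit <- fit_participant(plists, registry[[mname]], sims, policy = policy,
                             n_starts = n_starts,
                             seed = substream_seed(seed, 20000L + i))
      fits[[length(fits) + 1L]] <- fit
      row <- data.frame(participant_id = ids[i], group = grp, model = mname,
                        log_likelihood = fit$log_likelihood, aic = fit$aic,
                        converged = fit$converged, stringsAsFactors = FALSE)
      row <- cbind(row, as.data.frame(as.list(fit$beta4)))
      if (mname == "semantic_orthographic_task") {
        sm <- semantic_modulation(fit)
        row$omega_cat <- sm$omega_cat
        row$omega_lett <- sm$omega_lett
        row$delta_omega <- sm$delta_omega
      }
      fit_rows[[length(fit_rows) + 1L]] <- row
    }
  }
  fit_table <- do.call(rbind, lapply(fit_rows, function(r) {
    r[setdiff(union(names(fit_rows[[which.max(lengths(fit_rows))]]), names(r)),
              names(r))] <- NA
    r
  }))
  modulation <- fit_table[fit_table$model == "semantic_orthographic_task", ,
                          drop = FALSE]
  model_comparison <- if (length(models) > 1L) compare_models(fits) else NULL

  analysis <- list(trajectory = trajectory, consecutive = consecutive,
                   partitions = partitions, community_stats = community_stats,
                   rt_fits = rt_fits, fits = fit_table,
                   modulation = if (nrow(modulation)) modulation else NULL,
                   model_comparison = model_comparison, meta = meta,
                   settings = list(metric = metric, window = window,
                                   n_shuffles = n_shuffles, seed = seed,
                                   models = models, policy = policy,
                                   resolution = resolution))
  analysis$report <- run_report(analysis, covariates)
  analysis
}

#' Run the full pipeline from a configuration
#'
#' Thin orchestration over the package's stages: simulate a cohort (when
#' `config$simulate` is a [cohort_config()]) or load lists/embeddings from
#' files, then run [analyze_cohort()] and optionally write every output
#' table (TSV) and the report (JSON) to `config$out_dir`, stamped with the
#' seed and settings.
#'
#' @param config list with either `simulate` (a [cohort_config()]) or
#'   `lists` + `embeddings` paths (and optional `covariates` path), plus
#'   any [analyze_cohort()] settings (`metric`, `window`, `n_shuffles`,
#'   `models`, `policy`, `n_starts`, `resolution`, `trajectory_tasks`) and
#'   a mandatory `seed`; optional `out_dir`.
#' @return the [analyze_cohort()] result, invisibly when writing outputs.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stopf("config$seed is mandatory")
  settings <- config[intersect(names(config),
                               c("metric", "window", "n_shuffles", "models",
                                 "policy", "n_starts", "resolution",
                                 "trajectory_tasks"))]
  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate)
    lists <- cohort$lists
    sims <- cohort$sims
    covariates <- cohort$covariates
  } else {
    if (is.null(config$lists)) stopf("config needs either $simulate or $lists")
    vl <- validate_lists(config$lists)
    lists <- vl$lists
    metric <- if (is.null(config$metric)) "semantic" else config$metric
    if (metric == "semantic" && is.null(config$embeddings))
      stopf("semantic metric requested but config$embeddings is missing")
    vocab <- lapply(split(lists, vapply(lists, `[[`, "", "task")),
                    function(ls) unique(unlist(lapply(ls, `[[`, "items"))))
    space <- if (!is.null(config$embeddings))
      load_embeddings(config$embeddings, unique(unlist(vocab))) else NULL
    sims <- lapply(vocab, function(v) {
      v_in <- if (!is.null(space)) intersect(v, space$words) else v
      list(
        semantic = if (!is.null(space))
          similarity_matrix(v_in, space, metric = "semantic") else NULL,
        orthographic = similarity_matrix(v, metric = "orthographic"))
    })
    if (!is.null(space) && length(space$oov) > 0L) {
      lists <- lapply(lists, function(fl) {
        keep <- fl$items %in% sims[[fl$task]]$semantic$words
        fluency_list(fl$participant_id, fl$group, fl$task, fl$items[keep],
                     times_s = if (!is.null(fl$times_s)) fl$times_s[keep])
      })
    }
    covariates <- if (!is.null(config$covariates))
      read.delim(config$covariates, sep = ",", stringsAsFactors = FALSE)
    else NULL
  }
  analysis <- do.call(analyze_cohort,
                      c(list(lists = lists, sims = sims,
                             covariates = covariates, seed = config$seed),
                        settings[setdiff(names(settings), "seed")]))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) {
      if (!is.null(df))
        write.table(df, file.path(config$out_dir, paste0(name, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    wt(analysis$trajectory, "trajectory")
    wt(analysis$consecutive, "consecutive_distances")
    wt(analysis$community_stats, "community_stats")
    wt(analysis$rt_fits, "rt_regression")
    wt(analysis$fits, "fits")
    for (task in names(analysis$partitions)) {
      p <- analysis$partitions[[task]]
      wt(data.frame(word = p$words, community = p$labels), paste0("partition_", task))
    }
    if (!is.null(analysis$model_comparison))
      wt(analysis$model_comparison$summary, "model_comparison")
    jsonlite::write_json(
      list(seed = config$seed, settings = analysis$settings,
           report = analysis$report),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null", force = TRUE)
    return(invisible(analysis))
  }
  analysis
}
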