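# Group-level results document: routes every measure through the
# statistical layer and assembles the cohort's inferential summary.

safe <- function(expr) tryCatch(expr, error = function(e) NULL)

split_groups <- function(df, col) {
  list(x = df[[col]][df$group == "control"],
       y = df[[col]][df$group == "patient"])
}

#' Assemble the group-level results document
#'
#' Reproduces the study's inferential layer on any cohort: consecutive
#' semantic-distance comparisons and group-by-task ANOVA, optimality-z
#' comparisons with performance correlations, community-trajectory
#' comparisons, retrieval-time switch-coefficient tests, choice-model
#' parameter ANOVA, delta-omega comparisons and its correlations with
#' performance rank, optimality, symptom and ripple covariates, plus
#' medication-subgroup comparisons when a `medication` column exists. No
#' multiple-testing correction is applied; `n_tests` counts the tests run
#' so users can apply their own.
#'
#' @param analysis result of [analyze_cohort()] (the `report` element is
#'   ignored).
#' @param covariates optional data.frame with `participant_id` plus
#'   `ripple`, `symptom`, `alpha`, `medication` columns as available.
#' @return nested list of results; `NULL` entries mark analyses whose
#'   inputs were unavailable.
#' @export
run_report <- function(analysis, covariates = NULL) {
  out <- list()
  n_tests <- 0L
  tick <- function(x) {
    if (!is.null(x)) n_tests <<- n_tests + 1L
    x
  }
  two_groups <- length(unique(analysis$meta$group)) == 2L

  # consecutive semantic distance ------------------------------------------
  cons <- analysis$consecutive
  if (!is.null(cons) && two_groups) {
    out$consecutive_distance <- list()
    for (task in unique(cons$task)) {
      g <- split_groups(cons[cons$task == task, ], "mean_consecutive")
      out$consecutive_distance[[task]] <-
        tick(safe(compare_groups(g$x, g$y,
                                 paste0("mean_consecutive_", task))))
    }
    if (length(unique(cons$task)) == 2L) {
      out$consecutive_distance$anova <- tick(safe(mixed_anova(
        data.frame(participant_id = cons$participant_id, group = cons$group,
                   task = cons$task, value = cons$mean_consecutive))))
    }
  }

  # path optimality ----------------------------------------------------------
  tr <- analysis$trajectory
  if (!is.null(tr)) {
    out$optimality <- list()
    for (task in unique(tr$task)) {
      sub <- tr[tr$task == task, ]
      if (two_groups) {
        g <- split_groups(sub, "global_z")
        l <- split_groups(sub, "local_z")
        out$optimality[[task]] <- list(
          global = tick(safe(compare_groups(g$x, g$y, paste0("global_z_", task)))),
          local = tick(safe(compare_groups(l$x, l$y, paste0("local_z_", task)))))
      } else out$optimality[[task]] <- list()
      out$optimality[[task]]$performance_correlation <-
        tick(safe(correlate(sub$global_z, sub$n_items, "spearman")))
      out$optimality[[task]]$performance_interaction <-
        if (two_groups)
          tick(safe(interaction_regression(sub$n_items, sub$global_z,
                                           sub$group))) else NULL
    }
  }

  # community trajectories ---------------------------------------------------
  cs <- analysis$community_stats
  if (!is.null(cs) && two_groups) {
    out$communities <- list()
    for (task in unique(cs$task)) {
      sub <- cs[cs$task == task, ]
      lt <- split_groups(sub, "lifetime_z")
      rtn <- split_groups(sub, "returns_z")
      out$communities[[task]] <- list(
        lifetime = tick(safe(compare_groups(lt$x, lt$y, paste0("lifetime_z_", task)))),
        returns = tick(safe(compare_groups(rtn$x, rtn$y, paste0("returns_z_", task)))))
    }
  }

  # retrieval-time regression -------------------------------------------------
  rt <- analysis$rt_fits
  if (!is.null(rt)) {
    out$rt_switch <- list()
    for (grp in unique(rt$group)) {
      v <- rt$switch_coef[rt$group == grp]
      out$rt_switch[[grp]] <- tick(safe({
        ht <- t.test(v)
        list(mean = mean(v), sem = sd(v) / sqrt(length(v)),
             t = unname(ht$statistic), p = ht$p.value, n = length(v))
      }))
    }
    if (two_groups) {
      g <- split_groups(rt, "switch_coef")
      out$rt_switch$group_comparison <-
        tick(safe(compare_groups(g$x, g$y, "rt_switch_coef")))
    }
  }

  # choice model ---------------------------------------------------------------
  if (!is.null(analysis$model_comparison))
    out$model_comparison <- list(
      winner = analysis$model_comparison$winner,
      summary = analysis$model_comparison$summary)

  mod <- analysis$modulation
  if (!is.null(mod)) {
    out$salience <- list()
    if (two_groups) {
      long <- rbind(
        data.frame(participant_id = mod$participant_id, group = mod$group,
                   task = "category", beta_sem = mod$beta_sem_cat,
                   beta_orth = mod$beta_orth_cat, stringsAsFactors = FALSE),
        data.frame(participant_id = mod$participant_id, group = mod$group,
                   task = "letter", beta_sem = mod$beta_sem_lett,
                   beta_orth = mod$beta_orth_lett, stringsAsFactors = FALSE))
      out$salience$anova_beta_sem <- tick(safe(mixed_anova(
        data.frame(participant_id = long$participant_id, group = long$group,
                   task = long$task, value = long$beta_sem))))
      out$salience$anova_beta_orth <- tick(safe(mixed_anova(
        data.frame(participant_id = long$participant_id, group = long$group,
                   task = long$task, value = long$beta_orth))))
      g <- split_groups(mod, "delta_omega")
      out$delta_omega <- list(
        group_comparison = tick(safe(compare_groups(g$x, g$y, "delta_omega"))))
    } else out$delta_omega <- list()

    # delta-omega vs optimality and performance
    if (!is.null(tr) && "category" %in% tr$task) {
      sub <- tr[tr$task == "category", ]
      m <- merge(mod[, c("participant_id", "delta_omega")],
                 sub[, c("participant_id", "global_z", "local_z")],
                 by = "participant_id")
      out$delta_omega$optimality_global <-
        tick(safe(correlate(m$delta_omega, m$global_z, "spearman")))
      out$delta_omega$optimality_local <-
        tick(safe(correlate(m$delta_omega, m$local_z, "spearman")))
    }
    perf <- safe(rank_performance(analysis$meta$n_items, analysis$meta$task,
                                  analysis$meta$participant_id))
    if (!is.null(perf)) {
      m <- merge(mod[, c("participant_id", "delta_omega")], perf,
                 by = "participant_id")
      out$delta_omega$performance <-
        tick(safe(correlate(m$delta_omega, m$mean_rank, "spearman")))
    }

    if (!is.null(covariates)) {
      m <- merge(mod, covariates, by = intersect(c("participant_id", "group"),
                                                 names(covariates)))
      if ("ripple" %in% names(m)) {
        out$ripple <- list(
          correlation = tick(safe(correlate(m$delta_omega, m$ripple, "spearman"))),
          correlation_patients = tick(safe(correlate(
            m$delta_omega[m$group == "patient"],
            m$ripple[m$group == "patient"], "spearman"))),
          interaction = if (two_groups)
            tick(safe(interaction_regression(m$ripple, m$delta_omega,
                                             m$group))) else NULL)
      }
      if ("symptom" %in% names(m)) {
        p <- m[m$group == "patient", ]
        out$symptoms <- list(
          correlation = tick(safe(correlate(p$delta_omega, p$symptom,
                                            "spearman"))))
      }
      if ("alpha" %in% names(m)) {
        out$alpha_control <- list(
          interaction = if (two_groups)
            tick(safe(interaction_regression(m$alpha, m$delta_omega,
                                             m$group))) else NULL)
      }
      if ("medication" %in% names(m)) {
        p <- m[m$group == "patient" & !is.na(m$medication), ]
        if (nrow(p) >= 6L) {
          out$medication <- list(
            delta_omega = tick(safe(compare_groups(
              p$delta_omega[p$medication == 1], p$delta_omega[p$medication == 0],
              "delta_omega_by_medication"))))
        }
      }
    }
  }

  out$n_tests <- n_tests
  out
}
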