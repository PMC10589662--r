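# Group-level inferential layer: normality-routed two-group comparisons,
# 2x2 mixed ANOVA, correlations and interaction regressions.

#' Two-group comparison with normality routing
#'
#' A Shapiro-Wilk test on the pooled group-demeaned residuals (alpha =
#' 0.05) routes the comparison to a two-sample Student t test (normal) or
#' a Wilcoxon rank-sum test (non-normal). The Wilcoxon statistic is
#' reported as a normal-approximation z (tie-corrected), the convention
#' used when reporting "z(df)" alongside t statistics.
#'
#' @param x,y numeric vectors (e.g. controls and patients), each n >= 3.
#' @param measure label carried into the output.
#' @return a `group_comparison` data.frame row: measure, test (`"t"` or
#'   `"wilcoxon"`), statistic, p (two-tailed), group means, SEMs and ns.
#' @export
compare_groups <- function(x, y, measure = "measure") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L) stopf("need at least 3 values per group")
  resid <- c(x - mean(x), y - mean(y))
  if (sd(resid) < 1e-12) stopf("constant data: group comparison undefined")
  normal <- tryCatch(shapiro.test(resid)$p.value >= 0.05,
                     error = function(e) FALSE)
  if (normal) {
    ht <- t.test(x, y, var.equal = TRUE)
    stat <- unname(ht$statistic)
    p <- ht$p.value
    test <- "t"
  } else {
    # normal approximation with tie correction, matching the reported z
    r <- rank(c(x, y))
    n1 <- length(x); n2 <- length(y); N <- n1 + n2
    w <- sum(r[seq_len(n1)])
    mu <- n1 * (N + 1) / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    stat <- (w - mu) / sqrt(sig2)
    p <- 2 * pnorm(-abs(stat))
    test <- "wilcoxon"
  }
  structure(
    data.frame(measure = measure, test = test, statistic = stat, p = p,
               mean_x = mean(x), sem_x = sd(x) / sqrt(length(x)),
               mean_y = mean(y), sem_y = sd(y) / sqrt(length(y)),
               n_x = length(x), n_y = length(y), stringsAsFactors = FALSE),
    class = c("group_comparison", "data.frame")
  )
}

#' Two-by-two mixed-design ANOVA
#'
#' Group (between-participant) by task (within-participant) ANOVA on one
#' measure per participant per task. F and p are reported for the group
#' main effect, the task main effect and the group-by-task interaction
#' (each on 1 and n-2 degrees of freedom).
#'
#' @param data data.frame with columns `participant_id`, `group`, `task`,
#'   `value`; complete two-task data per participant.
#' @return data.frame with rows `group`, `task`, `group:task` and columns
#'   `effect`, `F`, `df1`, `df2`, `p`.
#' @export
mixed_anova <- function(data) {
  need <- c("participant_id", "group", "task", "value")
  if (!all(need %in% names(data)))
    stopf("missing columns: %s", paste(setdiff(need, names(data)), collapse = ", "))
  tab <- table(data$participant_id, data$task)
  if (any(tab != 1L) || ncol(tab) != 2L)
    stopf("mixed ANOVA requires exactly one value per participant per task (both tasks)")
  d <- data
  d$participant_id <- factor(d$participant_id)
  d$group <- factor(d$group)
  d$task <- factor(d$task)
  fit <- aov(value ~ group * task + Error(participant_id / task), data = d)
  s <- summary(fit)
  between <- s[["Error: participant_id"]][[1L]]
  within <- s[["Error: participant_id:task"]][[1L]]
  pick <- function(tabl, term) {
    i <- match(term, trimws(rownames(tabl)))
    c(F = tabl[i, "F value"], df1 = tabl[i, "Df"],
      df2 = tabl[nrow(tabl), "Df"], p = tabl[i, "Pr(>F)"])
  }
  out <- rbind(group = pick(between, "group"),
               task = pick(within, "task"),
               `group:task` = pick(within, "group:task"))
  data.frame(effect = rownames(out), out, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Correlation with two-tailed p value
#'
#' Spearman rank (tie-corrected, normal/t approximation) or Pearson
#' product-moment correlation.
#'
#' @param x,y numeric vectors of equal length >= 5.
#' @param method `"spearman"` or `"pearson"`.
#' @return list with `estimate`, `p`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5L) stopf("need at least 5 complete pairs")
  if (sd(x) < 1e-12 || sd(y) < 1e-12) stopf("constant vector: correlation undefined")
  ht <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(estimate = unname(ht$estimate), p = ht$p.value, n = length(x),
       method = method)
}

#' Group-by-covariate interaction regression
#'
#' OLS of `outcome ~ covariate * group` with the covariate demeaned before
#' the product term is formed (decorrelating main and interaction
#' effects); the raw-covariate fit is returned alongside. Group is coded
#' control = 0, patient = 1.
#'
#' @param outcome numeric outcome vector.
#' @param covariate numeric covariate vector.
#' @param group character/factor vector (`"control"`/`"patient"`) or 0/1.
#' @param demean logical; demean the covariate (default TRUE).
#' @return list with `coefficients` (data.frame: term, estimate, se, t, p),
#'   `n`, `df` and `raw_coefficients` (same fit without demeaning).
#' @export
interaction_regression <- function(outcome, covariate, group, demean = TRUE) {
  ok <- complete.cases(outcome, covariate, group)
  outcome <- outcome[ok]; covariate <- covariate[ok]; group <- group[ok]
  n <- length(outcome)
  if (n < 8L) stopf("need at least 8 complete cases (got %d)", n)
  if (sd(covariate) < 1e-12) stopf("zero-variance covariate")
  g <- if (is.numeric(group)) as.numeric(group)
  else as.numeric(group == "patient")
  fit_one <- function(x) {
    fit <- lm(outcome ~ x * g)
    if (any(is.na(coef(fit)))) stopf("collinear interaction design")
    cf <- summary(fit)$coefficients
    data.frame(term = c("intercept", "covariate", "group", "group:covariate"),
               estimate = cf[, 1L], se = cf[, 2L], t = cf[, 3L], p = cf[, 4L],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  co <- fit_one(if (demean) covariate - mean(covariate) else covariate)
  raw <- fit_one(covariate)
  list(coefficients = co, raw_coefficients = raw, n = n, df = n - 4L)
}

#' Task-specific rank transform of list lengths
#'
#' Expresses each participant's list length as a rank within its task
#' before averaging across tasks, accounting for different list-length
#' distributions between tasks.
#'
#' @param lengths numeric vector of list lengths.
#' @param task task label per entry.
#' @param participant_id participant label per entry.
#' @return data.frame with `participant_id` and `mean_rank`.
#' @export
rank_performance <- function(lengths, task, participant_id) {
  r <- ave(lengths, task, FUN = rank)
  agg <- aggregate(r, list(participant_id = participant_id), mean)
  names(agg)[2L] <- "mean_rank"
  agg
}
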