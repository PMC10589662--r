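# Generative softmax local-search choice models: the probability of the
# t-th emitted word is a softmax over the not-yet-emitted task vocabulary,
# with semantic and orthographic similarity to the previous word scaled by
# free salience (beta) parameters. Fitted per participant by maximum
# likelihood over the concatenated category + letter lists; models compared
# by AIC; the winning 4-parameter model yields omega = beta_sem - beta_orth
# per task and delta-omega = omega_category - omega_letter ("goal-induced
# semantic modulation").

# The full parameter space is beta4 = (sem.CAT, orth.CAT, sem.LETT,
# orth.LETT); each model is a linear map from its free parameters into
# beta4, so the registry stores a 4 x k map matrix.
BETA4_NAMES <- c("beta_sem_cat", "beta_orth_cat", "beta_sem_lett", "beta_orth_lett")

make_model_spec <- function(name, params, map) {
  dimnames(map) <- list(BETA4_NAMES, params)
  structure(list(name = name, params = params, map = map,
                 n_params = length(params)),
            class = "model_spec")
}

#' Registry of softmax local-search model variants
#'
#' Six members: semantic-only, orthographic-only and semantic+orthographic
#' channels, each either shared across tasks or task-specific. The
#' 4-parameter task-specific semantic+orthographic model
#' (`"semantic_orthographic_task"`) is the full model from which
#' delta-omega is derived.
#'
#' @return named list of `model_spec` objects.
#' @export
model_registry <- function() {
  m <- function(...) matrix(c(...), nrow = 4L)
  list(
    semantic_shared = make_model_spec(
      "semantic_shared", "beta_sem", m(1, 0, 1, 0)),
    orthographic_shared = make_model_spec(
      "orthographic_shared", "beta_orth", m(0, 1, 0, 1)),
    semantic_orthographic_shared = make_model_spec(
      "semantic_orthographic_shared", c("beta_sem", "beta_orth"),
      m(1, 0, 1, 0, 0, 1, 0, 1)),
    semantic_task = make_model_spec(
      "semantic_task", c("beta_sem_cat", "beta_sem_lett"),
      m(1, 0, 0, 0, 0, 0, 1, 0)),
    orthographic_task = make_model_spec(
      "orthographic_task", c("beta_orth_cat", "beta_orth_lett"),
      m(0, 1, 0, 0, 0, 0, 0, 1)),
    semantic_orthographic_task = make_model_spec(
      "semantic_orthographic_task", BETA4_NAMES, diag(4))
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%d free parameters: %s)\n",
              x$name, x$n_params, paste(x$params, collapse = ", ")))
  invisible(x)
}

#' Softmax transition probabilities
#'
#' `P(w) = exp(b_sem * S_sem(prev, w) + b_orth * S_orth(prev, w)) /
#' sum over candidates`, the single-step choice rule of the local-search
#' model.
#'
#' @param prev_word previous emitted word.
#' @param candidate_set nonempty character vector of candidate words (must
#'   not contain `prev_word`).
#' @param betas named or length-2 numeric: `b_sem`, `b_orth`.
#' @param sem_sim,orth_sim [similarity_matrix()] objects covering
#'   `prev_word` and all candidates (either may be `NULL` when the
#'   corresponding beta is 0).
#' @return named probability vector over `candidate_set` (sums to 1).
#' @export
transition_probability <- function(prev_word, candidate_set, betas,
                                   sem_sim = NULL, orth_sim = NULL) {
  prev_word <- normalize_word(prev_word)
  candidate_set <- normalize_word(candidate_set)
  if (length(candidate_set) == 0L) stopf("empty candidate set")
  if (prev_word %in% candidate_set) stopf("previous word present in candidate set")
  b_sem <- if (!is.null(names(betas))) betas[["b_sem"]] else betas[[1L]]
  b_orth <- if (!is.null(names(betas))) betas[["b_orth"]] else betas[[2L]]
  sim_row <- function(sim, b) {
    if (b == 0 && is.null(sim)) return(numeric(length(candidate_set)))
    if (is.null(sim)) stopf("similarity matrix required for nonzero beta")
    i <- match(prev_word, sim$words)
    j <- match(candidate_set, sim$words)
    if (is.na(i) || anyNA(j)) stopf("words missing from similarity matrix")
    sim$values[i, j]
  }
  a <- b_sem * sim_row(sem_sim, b_sem) + b_orth * sim_row(orth_sim, b_orth)
  a <- a - max(a)
  p <- exp(a) / sum(exp(a))
  names(p) <- candidate_set
  p
}

# Precompute per-transition design blocks for one participant. `sims` is a
# named list: sims[[task]]$semantic and sims[[task]]$orthographic, each a
# similarity_matrix over the pooled task vocabulary (all unique words
# generated across participants for that task).
prepare_choice_data <- function(lists, sims,
                                policy = c("without_replacement",
                                           "with_replacement")) {
  policy <- match.arg(policy)
  if (inherits(lists, "fluency_list")) lists <- list(lists)
  blocks <- list()
  for (fl in lists) {
    stopifnot(inherits(fl, "fluency_list"))
    task <- fl$task
    if (is.null(sims[[task]]))
      stopf("no similarity matrices supplied for task '%s'", task)
    sem <- sims[[task]]$semantic
    orth <- sims[[task]]$orthographic
    ref <- if (!is.null(sem)) sem else orth
    vocab <- ref$words
    idx <- match(fl$items, vocab)
    if (anyNA(idx))
      stopf("emitted word(s) absent from the pooled task vocabulary: %s",
            paste(fl$items[is.na(idx)], collapse = ", "))
    tn <- length(idx)
    if (tn < 2L) next
    nv <- length(vocab)
    rows <- tn - 1L
    mask <- matrix(TRUE, rows, nv)
    if (policy == "without_replacement") {
      for (t in seq_len(rows)) mask[t, idx[seq_len(t)]] <- FALSE
    } else {
      mask[cbind(seq_len(rows), idx[seq_len(rows)])] <- FALSE
    }
    blocks[[length(blocks) + 1L]] <- list(
      task = task,
      s_sem = if (!is.null(sem)) sem$values[idx[-tn], , drop = FALSE] else NULL,
      s_orth = if (!is.null(orth)) orth$values[idx[-tn], , drop = FALSE] else NULL,
      mask = mask,
      obs = idx[-1L]
    )
  }
  if (length(blocks) == 0L) stopf("no modellable transitions in supplied lists")
  structure(list(blocks = blocks, policy = policy), class = "choice_data")
}

# Log-likelihood and gradient in beta4 space.
choice_ll <- function(data, beta4, gradient = FALSE) {
  ll <- 0
  grad <- numeric(4L)
  for (blk in data$blocks) {
    ch <- if (blk$task == "category") c(1L, 2L) else c(3L, 4L)
    bs <- beta4[ch[1L]]; bo <- beta4[ch[2L]]
    rows <- length(blk$obs)
    a <- matrix(0, rows, ncol(blk$mask))
    if (!is.null(blk$s_sem) && bs != 0) a <- a + bs * blk$s_sem
    if (!is.null(blk$s_orth) && bo != 0) a <- a + bo * blk$s_orth
    a[!blk$mask] <- -Inf
    m <- apply(a, 1L, max)
    e <- exp(a - m)
    denom <- rowSums(e)
    oi <- cbind(seq_len(rows), blk$obs)
    ll <- ll + sum(a[oi] - m - log(denom))
    if (gradient) {
      if (!is.null(blk$s_sem)) {
        es <- rowSums(e * blk$s_sem) / denom
        grad[ch[1L]] <- grad[ch[1L]] + sum(blk$s_sem[oi] - es)
      }
      if (!is.null(blk$s_orth)) {
        eo <- rowSums(e * blk$s_orth) / denom
        grad[ch[2L]] <- grad[ch[2L]] + sum(blk$s_orth[oi] - eo)
      }
    }
  }
  if (gradient) list(ll = ll, grad = grad) else ll
}

#' Log-likelihood of a participant's lists under a model
#'
#' Sums `log transition_probability` over all transitions (t >= 2) of the
#' participant's lists; the first item of each list is conditioned on, not
#' modelled. The candidate set at step t is the pooled task vocabulary
#' minus the participant's previous emissions (default) or minus only the
#' immediately preceding word (`"with_replacement"`).
#'
#' @param lists a [fluency_list()] or list of them (one per task).
#' @param model a `model_spec` from [model_registry()].
#' @param betas numeric vector of the model's free parameters (in
#'   `model$params` order).
#' @param sims named list of per-task similarity matrices:
#'   `sims[[task]]$semantic`, `sims[[task]]$orthographic` over the pooled
#'   task vocabulary.
#' @param policy candidate-set policy.
#' @return log-likelihood (scalar, <= 0).
#' @export
list_log_likelihood <- function(lists, model, betas, sims,
                                policy = c("without_replacement",
                                           "with_replacement")) {
  stopifnot(inherits(model, "model_spec"), length(betas) == model$n_params)
  data <- prepare_choice_data(lists, sims, match.arg(policy))
  choice_ll(data, as.vector(model$map %*% as.numeric(betas)))
}

#' Fit the choice model to one participant by maximum likelihood
#'
#' Maximises [list_log_likelihood()] with bounded L-BFGS-B (analytic
#' gradient) from multiple seeded random starts drawn uniformly on
#' \[0, 5\]; bounds are beta in \[-20, 50\]. The log-likelihood is concave
#' in the betas (conditional-logit form), so the starts guard convergence
#' rather than explore modes; `converged` requires an optimizer success and
#' agreement of the two best starts.
#'
#' @inheritParams list_log_likelihood
#' @param participant_id optional id recorded in the fit (defaults to the
#'   first list's id).
#' @param n_starts number of random starts (default 5).
#' @param seed integer seed for the starts.
#' @param lower,upper box bounds on each beta.
#' @return a `choice_model_fit`: `participant_id`, `model`, `betas` (named
#'   free parameters), `beta4` (expanded), `log_likelihood`, `aic`,
#'   `converged`, `n_transitions`.
#' @export
fit_participant <- function(lists, model, sims,
                            policy = c("without_replacement",
                                       "with_replacement"),
                            participant_id = NULL, n_starts = 5L, seed = 1L,
                            lower = -20, upper = 50) {
  stopifnot(inherits(model, "model_spec"))
  policy <- match.arg(policy)
  data <- prepare_choice_data(lists, sims, policy)
  if (is.null(participant_id)) {
    fl <- if (inherits(lists, "fluency_list")) lists else lists[[1L]]
    participant_id <- fl$participant_id
  }
  k <- model$n_params
  mapM <- model$map
  nll <- function(th) -choice_ll(data, as.vector(mapM %*% th))
  ngr <- function(th) {
    g <- choice_ll(data, as.vector(mapM %*% th), gradient = TRUE)$grad
    -as.vector(crossprod(mapM, g))
  }
  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) runif(k, 0, 5))
  })
  runs <- lapply(starts, function(s) {
    tryCatch(
      optim(s, nll, ngr, method = "L-BFGS-B",
            lower = rep(lower, k), upper = rep(upper, k),
            control = list(maxit = 500L, factr = 1e7)),
      error = function(e) list(value = Inf, par = s, convergence = 99L)
    )
  })
  vals <- vapply(runs, `[[`, 0, "value")
  best <- runs[[which.min(vals)]]
  ll <- -best$value
  agree <- if (n_starts >= 2L) {
    sv <- sort(vals)
    is.finite(sv[2L]) && (sv[2L] - sv[1L]) < 1e-4
  } else TRUE
  converged <- is.finite(ll) && best$convergence == 0L && agree
  betas <- setNames(as.numeric(best$par), model$params)
  n_trans <- sum(vapply(data$blocks, function(b) length(b$obs), 0L))
  structure(
    list(participant_id = participant_id, model = model,
         betas = betas, beta4 = setNames(as.vector(mapM %*% betas), BETA4_NAMES),
         log_likelihood = ll, aic = 2 * k - 2 * ll,
         converged = converged, n_transitions = n_trans, policy = policy),
    class = "choice_model_fit"
  )
}

#' @export
print.choice_model_fit <- function(x, ...) {
  cat(sprintf("<choice_model_fit> %s under %s: LL %.2f, AIC %.2f%s\n",
              x$participant_id, x$model$name, x$log_likelihood, x$aic,
              if (x$converged) "" else " (not converged)"))
  print(round(x$betas, 3))
  invisible(x)
}

#' Group-level AIC model comparison
#'
#' Sums AIC over participants per model; the winner is the model with the
#' minimum summed AIC.
#'
#' @param fits list of `choice_model_fit` objects (every participant fitted
#'   under every compared model).
#' @return list with `summary` (data.frame: model, n_participants,
#'   summed_aic, delta_aic), `winner` (model name) and `per_participant`
#'   (data.frame of participant-level AICs).
#' @export
compare_models <- function(fits) {
  if (length(fits) == 0L) stopf("no fits supplied")
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(participant_id = f$participant_id, model = f$model$name,
               aic = f$aic, log_likelihood = f$log_likelihood,
               stringsAsFactors = FALSE)
  }))
  counts <- table(tab$model)
  if (length(unique(counts)) != 1L)
    stopf("missing fits: models were not fitted to the same participants (%s)",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  per_part <- table(tab$participant_id, tab$model)
  if (any(per_part != 1L))
    stopf("missing fits: each participant must be fitted once under each model")
  agg <- aggregate(aic ~ model, data = tab, FUN = sum)
  names(agg) <- c("model", "summed_aic")
  agg$n_participants <- as.integer(counts[agg$model])
  agg <- agg[order(agg$summed_aic), ]
  agg$delta_aic <- agg$summed_aic - agg$summed_aic[1L]
  rownames(agg) <- NULL
  list(summary = agg, winner = agg$model[1L], per_participant = tab)
}

#' Goal-induced semantic modulation from a full-model fit
#'
#' From the 4-parameter task-specific model: `omega = beta_sem - beta_orth`
#' per task and `delta_omega = omega_category - omega_letter`, the
#' context-driven boost of semantic over orthographic guidance.
#'
#' @param fit a `choice_model_fit` under `"semantic_orthographic_task"`.
#' @return list with `omega_cat`, `omega_lett`, `delta_omega`.
#' @export
semantic_modulation <- function(fit) {
  stopifnot(inherits(fit, "choice_model_fit"))
  if (fit$model$name != "semantic_orthographic_task")
    stopf("delta-omega requires the 4-parameter task-specific model (got '%s')",
          fit$model$name)
  b <- fit$beta4
  omega_cat <- b[["beta_sem_cat"]] - b[["beta_orth_cat"]]
  omega_lett <- b[["beta_sem_lett"]] - b[["beta_orth_lett"]]
  list(omega_cat = omega_cat, omega_lett = omega_lett,
       delta_omega = omega_cat - omega_lett)
}
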