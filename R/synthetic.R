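# Synthetic ground-truth cohorts: a community-structured embedding space,
# softmax local-search agents in two task contexts, lognormal retrieval
# times that slow at community switches, and covariates (ripple-power and
# symptom proxies) coupled to the true delta-omega.

# Phonotactically plausible pseudowords built from a small Zipf-weighted
# syllable pool, so the lexicon contains word families with shared
# morphemes and a realistic spread of pairwise edit distances (uniform
# random letter strings are nearly equidistant, which real lexicons are
# not).
random_words <- function(n, n_syllables = 20L, first_letter = NULL,
                         first_letter_fraction = 0) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t")
  vows <- c("a", "e", "i", "o", "u")
  pool <- sample(as.vector(outer(cons, vows, paste0)), n_syllables)
  prob <- 1 / seq_len(n_syllables)
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    k <- sample(2:3, need, replace = TRUE)
    w <- vapply(k, function(ki)
      paste(sample(pool, ki, replace = TRUE, prob = prob), collapse = ""), "")
    if (!is.null(first_letter) && first_letter_fraction > 0) {
      fix <- runif(need) < first_letter_fraction
      substr(w[fix], 1L, 1L) <- first_letter
    }
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

#' Generate a community-structured embedding space
#'
#' Draws unit-norm word vectors around `n_communities` random centroids.
#' Centroids share a common component sized so that the mean
#' between-community cosine hits `between_cos`; member dispersion around
#' the centroid is calibrated by bisection so that the mean
#' within-community cosine hits `within_cos` (tolerance 0.05, at most 3
#' bisection iterations). Word strings are random lowercase strings, a
#' configurable fraction starting with a fixed letter (the letter-task
#' vocabulary).
#'
#' @param vocab_size number of words.
#' @param dim embedding dimension.
#' @param n_communities number of planted communities.
#' @param within_cos,between_cos target mean cosine similarity within and
#'   between communities (`within_cos > between_cos`).
#' @param n_subclusters optional within-community substructure: each
#'   community's members are spread over this many subclusters, giving the
#'   graded (rather than two-valued) similarity profile of real embedding
#'   spaces. Default 1 (no substructure).
#' @param subcluster_share share of the member dispersion carried by the
#'   subcluster component when `n_subclusters > 1`.
#' @param first_letter optional single letter word strings may start with.
#' @param first_letter_fraction fraction of words forced to start with
#'   `first_letter`.
#' @param seed integer seed.
#' @return an [embedding_space()] with an extra `communities` field
#'   (0-based planted community label per word) and `realized` field
#'   (realised mean within/between cosines).
#' @export
make_embedding_space <- function(vocab_size = 300L, dim = 300L,
                                 n_communities = 8L,
                                 within_cos = 0.55, between_cos = 0.10,
                                 n_subclusters = 1L, subcluster_share = 0.6,
                                 first_letter = NULL,
                                 first_letter_fraction = 0, seed = 1L) {
  if (within_cos <= between_cos)
    stopf("infeasible cosine targets: within (%g) must exceed between (%g)",
          within_cos, between_cos)
  if (within_cos <= 0 || within_cos > 1 || between_cos < 0)
    stopf("infeasible cosine targets: need 0 <= between < within <= 1")
  with_seed(seed, {
    words <- random_words(vocab_size, first_letter = first_letter,
                          first_letter_fraction = first_letter_fraction)
    labels <- sort(rep_len(seq_len(n_communities) - 1L, vocab_size))
    rho <- between_cos / within_cos
    u0 <- rnorm(dim); u0 <- u0 / sqrt(sum(u0^2))
    # graded community placement: community loadings on the shared
    # component vary, so between-community similarity is a continuum
    # rather than a single value (as in real semantic spaces)
    s <- sqrt(pmin(runif(n_communities, 0, 2 * rho), 1))
    if (n_communities > 1L) {
      # rescale so the mean pairwise centroid cosine hits rho for the
      # loadings actually drawn (small-sample correction)
      m <- (sum(s)^2 - sum(s^2)) / (n_communities * (n_communities - 1L))
      if (m > 0) s <- pmin(s * sqrt(rho / m), 1)
    }
    centroids <- t(vapply(seq_len(n_communities), function(i) {
      g <- rnorm(dim); g <- g - sum(g * u0) * u0; g <- g / sqrt(sum(g^2))
      s[i] * u0 + sqrt(1 - s[i]^2) * g
    }, numeric(dim)))
    noise <- matrix(rnorm(vocab_size * dim), vocab_size, dim)
    noise <- noise / sqrt(rowSums(noise^2))
    if (n_subclusters > 1L) {
      subs <- (seq_len(vocab_size) %% n_subclusters) +
        labels * n_subclusters   # subcluster id nested in community
      sub_noise <- matrix(rnorm((n_communities * n_subclusters) * dim),
                          ncol = dim)
      sub_noise <- sub_noise / sqrt(rowSums(sub_noise^2))
      noise <- sqrt(subcluster_share) * sub_noise[subs + 1L, , drop = FALSE] +
        sqrt(1 - subcluster_share) * noise
    }

    build <- function(tau) {
      v <- centroids[labels + 1L, , drop = FALSE] + tau * noise
      v / sqrt(rowSums(v^2))
    }
    realized_within <- function(v) {
      s <- tcrossprod(v)
      same <- outer(labels, labels, `==`) & upper.tri(s)
      mean(s[same])
    }
    tau <- sqrt(max(1 / within_cos - 1, 1e-6))
    v <- build(tau)
    rw <- realized_within(v)
    if (abs(rw - within_cos) > 0.05) {
      # f(tau) is decreasing in tau; bracket then bisect (<= 3 iterations)
      if (rw > within_cos) { lo <- tau; hi <- 2 * tau } else { lo <- tau / 2; hi <- tau }
      for (it in 1:3) {
        mid <- (lo + hi) / 2
        vm <- build(mid)
        rm_ <- realized_within(vm)
        if (abs(rm_ - within_cos) <= 0.05) { v <- vm; rw <- rm_; break }
        if (rm_ > within_cos) lo <- mid else hi <- mid
        v <- vm; rw <- rm_
      }
    }
    s <- tcrossprod(v)
    between_mask <- outer(labels, labels, `!=`) & upper.tri(s)
    rb <- mean(s[between_mask])
    space <- embedding_space(words, v)
    space$communities <- labels
    space$realized <- c(within = rw, between = rb)
    space
  })
}

# Sample one softmax local-search trajectory (indices into the vocabulary).
softmax_walk <- function(sem_vals, orth_vals, b_sem, b_orth, n_items) {
  nv <- nrow(sem_vals)
  if (n_items > nv) stopf("requested length (%d) exceeds vocabulary (%d)",
                          n_items, nv)
  idx <- integer(n_items)
  idx[1L] <- sample.int(nv, 1L)
  avail <- rep(TRUE, nv)
  avail[idx[1L]] <- FALSE
  for (t in 2:n_items) {
    prev <- idx[t - 1L]
    a <- b_sem * sem_vals[prev, ] + b_orth * orth_vals[prev, ]
    a[!avail] <- -Inf
    a <- a - max(a)
    p <- exp(a)
    nxt <- sample.int(nv, 1L, prob = p)
    idx[t] <- nxt
    avail[nxt] <- FALSE
  }
  idx
}

#' Simulate one participant's fluency list
#'
#' Forward model of the softmax local-search choice rule: the first word is
#' uniform over the task vocabulary; each subsequent word is sampled
#' without replacement with probability proportional to
#' `exp(b_sem * S_sem + b_orth * S_orth)` to the previous word. Retrieval
#' times are lognormal: `log RT = intercept + switch_effect * (community
#' switch) + sem_slope * semantic distance + noise`, cumulated into
#' timestamps.
#'
#' @param task `"category"` or `"letter"`.
#' @param sims list with `semantic` and `orthographic`
#'   [similarity_matrix()] objects over the task vocabulary.
#' @param betas length-2 numeric `c(b_sem, b_orth)`.
#' @param n_items list length to generate.
#' @param labels community labels (one per vocabulary word) driving the
#'   retrieval-time switch effect.
#' @param rt list: `intercept`, `switch_effect`, `sem_slope`, `noise_sd`
#'   (log-seconds scale).
#' @param participant_id,group passed to [fluency_list()].
#' @param seed integer seed.
#' @return a timed [fluency_list()].
#' @export
simulate_participant <- function(task, sims, betas, n_items, labels,
                                 rt = list(intercept = 1.8, switch_effect = 0.5,
                                           sem_slope = 0.3, noise_sd = 0.4),
                                 participant_id = "sim", group = "control",
                                 seed = 1L) {
  sem <- sims$semantic; orth <- sims$orthographic
  with_seed(seed, {
    idx <- softmax_walk(sem$values, orth$values, betas[[1L]], betas[[2L]],
                        n_items)
    n <- length(idx)
    semd <- 1 - sem$values[cbind(idx[-n], idx[-1L])]
    sw <- as.numeric(labels[idx[-n]] != labels[idx[-1L]])
    log_rt <- c(rt$intercept + rnorm(1L, 0, rt$noise_sd),
                rt$intercept + rt$switch_effect * sw + rt$sem_slope * semd +
                  rnorm(n - 1L, 0, rt$noise_sd))
    fluency_list(participant_id, group, task, sem$words[idx],
                 times_s = cumsum(exp(log_rt)))
  })
}

#' Cohort configuration
#'
#' Bundles every generator setting with defaults emulating a two-group
#' (control/patient), two-task fluency study: 26 participants per group,
#' 300-word task vocabularies in a 300-dimensional space with 8 planted
#' communities, group-specific salience parameters whose planted
#' delta-omega means are 5.2 (controls) vs 3.6 (patients) with SD ~ 2,
#' lognormal retrieval times slowed by community switches, and a
#' ripple-power proxy linearly coupled to the true delta-omega.
#'
#' @param n_per_group participants per group.
#' @param vocab_size named vector: vocabulary size per task.
#' @param embedding_dim embedding dimension.
#' @param n_communities planted communities per task space.
#' @param within_cos,between_cos community cosine targets.
#' @param group_betas list per group with `mean` and `sd` length-4 vectors
#'   over (sem.CAT, orth.CAT, sem.LETT, orth.LETT).
#' @param list_length list per task with `mean`, `sd`, `min` of the
#'   (rounded normal) list-length distribution.
#' @param rt retrieval-time model parameters (see
#'   [simulate_participant()]).
#' @param ripple list `intercept`, `slope`, `noise_sd`: ripple proxy =
#'   intercept + slope * delta_omega_true + noise.
#' @param symptom list `intercept`, `slope`, `noise_sd`: negative-symptom
#'   proxy for patients = intercept + slope * delta_omega_true + noise.
#' @param shared_across_tasks when TRUE each participant's category betas
#'   are reused for the letter task (the shared 2-parameter generative
#'   regime, e.g. for model-recovery studies); default FALSE
#'   (task-specific regime).
#' @param seed master seed; all other randomness derives from it.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 26L,
                          vocab_size = c(category = 300L, letter = 300L),
                          embedding_dim = 300L, n_communities = 8L,
                          within_cos = 0.55, between_cos = 0.10,
                          group_betas = list(
                            control = list(mean = c(4.2, 0.5, 0.5, 2.0),
                                           sd = c(1.9, 0.3, 0.3, 0.5)),
                            patient = list(mean = c(2.6, 0.5, 0.5, 2.0),
                                           sd = c(1.9, 0.3, 0.3, 0.5))),
                          list_length = list(
                            category = c(mean = 42, sd = 5, min = 32),
                            letter = c(mean = 24, sd = 4, min = 15)),
                          rt = list(intercept = 1.8, switch_effect = 0.5,
                                    sem_slope = 0.3, noise_sd = 0.4),
                          ripple = list(intercept = 2.4, slope = 0.16,
                                        noise_sd = 0.45),
                          symptom = list(intercept = 14, slope = -1.0,
                                         noise_sd = 4.3),
                          shared_across_tasks = FALSE,
                          seed = 1L) {
  stopifnot(all(unlist(lapply(group_betas, `[[`, "sd")) >= 0),
            within_cos > between_cos)
  structure(as.list(environment()), class = "cohort_config")
}

# Build the two task spaces and their similarity matrices for a config.
cohort_spaces <- function(config) {
  spaces <- list(
    category = make_embedding_space(
      config$vocab_size[["category"]], config$embedding_dim,
      config$n_communities, config$within_cos, config$between_cos,
      seed = substream_seed(config$seed, 1L)),
    letter = make_embedding_space(
      config$vocab_size[["letter"]], config$embedding_dim,
      config$n_communities, config$within_cos, config$between_cos,
      first_letter = "p", first_letter_fraction = 1,
      seed = substream_seed(config$seed, 2L))
  )
  sims <- lapply(spaces, function(sp) list(
    semantic = similarity_matrix(sp$words, sp, metric = "semantic"),
    orthographic = similarity_matrix(sp$words, metric = "orthographic")
  ))
  list(spaces = spaces, sims = sims)
}

#' Simulate a full cohort with known ground truth
#'
#' Draws per-participant true salience parameters from the group
#' distributions, simulates category and letter lists with retrieval
#' times, and generates covariates: a ripple-power proxy coupled to the
#' true delta-omega for all participants, a negative-symptom proxy
#' (patients only) inversely coupled to it, and a medication indicator for
#' half the patients.
#'
#' @param config a [cohort_config()].
#' @return list with `lists` (list of timed [fluency_list()]s),
#'   `covariates` (data.frame: participant_id, group, ripple, symptom,
#'   medication), `truth` (data.frame of true betas, omegas and
#'   delta-omega), `spaces`, `sims` and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  sp <- cohort_spaces(config)
  n <- config$n_per_group
  ids <- c(sprintf("ctrl%02d", seq_len(n)), sprintf("pat%02d", seq_len(n)))
  groups <- rep(c("control", "patient"), each = n)

  truth <- with_seed(substream_seed(config$seed, 3L), {
    betas <- t(vapply(groups, function(g) {
      gb <- config$group_betas[[g]]
      rnorm(4L, gb$mean, gb$sd)
    }, numeric(4L)))
    if (isTRUE(config$shared_across_tasks)) {
      betas[, 3L] <- betas[, 1L]
      betas[, 4L] <- betas[, 2L]
    }
    colnames(betas) <- BETA4_NAMES
    lens <- vapply(c("category", "letter"), function(task) {
      p <- config$list_length[[task]]
      pmin(pmax(round(rnorm(length(ids), p[["mean"]], p[["sd"]])),
                p[["min"]]),
           length(sp$spaces[[task]]$words))
    }, numeric(length(ids)))
    data.frame(participant_id = ids, group = groups,
               betas,
               n_category = as.integer(lens[, 1L]),
               n_letter = as.integer(lens[, 2L]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  truth$omega_cat_true <- truth$beta_sem_cat - truth$beta_orth_cat
  truth$omega_lett_true <- truth$beta_sem_lett - truth$beta_orth_lett
  truth$delta_omega_true <- truth$omega_cat_true - truth$omega_lett_true

  lists <- list()
  for (i in seq_along(ids)) {
    for (task in c("category", "letter")) {
      betas <- if (task == "category")
        c(truth$beta_sem_cat[i], truth$beta_orth_cat[i])
      else c(truth$beta_sem_lett[i], truth$beta_orth_lett[i])
      n_items <- if (task == "category") truth$n_category[i] else truth$n_letter[i]
      lists[[length(lists) + 1L]] <- simulate_participant(
        task, sp$sims[[task]], betas, n_items,
        labels = sp$spaces[[task]]$communities, rt = config$rt,
        participant_id = ids[i], group = groups[i],
        seed = substream_seed(config$seed,
                              10L + i * 2L + (task == "letter")))
    }
  }

  covariates <- with_seed(substream_seed(config$seed, 4L), {
    ripple <- config$ripple$intercept +
      config$ripple$slope * truth$delta_omega_true +
      rnorm(length(ids), 0, config$ripple$noise_sd)
    symptom <- ifelse(
      groups == "patient",
      config$symptom$intercept +
        config$symptom$slope * truth$delta_omega_true +
        rnorm(length(ids), 0, config$symptom$noise_sd),
      NA_real_)
    medication <- ifelse(groups == "patient",
                         rep_len(c(1L, 0L), length(ids)), NA_integer_)
    data.frame(participant_id = ids, group = groups, ripple = ripple,
               symptom = symptom, medication = medication,
               stringsAsFactors = FALSE)
  })

  list(lists = lists, covariates = covariates, truth = truth,
       spaces = sp$spaces, sims = sp$sims, config = config)
}
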