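make_sim_pair <- function(words, sem_vals, orth_vals) {
  list(semantic = manual_similarity(words, sem_vals, "semantic"),
       orthographic = manual_similarity(words, orth_vals, "orthographic"))
}

test_that("transition probabilities follow the softmax rule", {
  words <- c("a", "b", "c")
  sem <- matrix(c(1, .9, .1, .9, 1, 0, .1, 0, 1), 3,
                dimnames = list(words, words))
  s <- manual_similarity(words, sem)

  p0 <- transition_probability("a", c("b", "c"), c(b_sem = 0, b_orth = 0),
                               sem_sim = s)
  expect_equal(unname(p0), c(0.5, 0.5))

  p1 <- transition_probability("a", c("b", "c"), c(b_sem = 1, b_orth = 0),
                               sem_sim = s)
  expect_equal(unname(round(p1, 4)), c(0.6900, 0.3100))
  expect_equal(sum(p1), 1, tolerance = 1e-12)

  p_big <- transition_probability("a", c("b", "c"), c(b_sem = 60, b_orth = 0),
                                  sem_sim = s)
  expect_gt(p_big[["b"]], 0.999)

  expect_error(transition_probability("a", character(0), c(0, 0), s), "empty")
  expect_error(transition_probability("a", c("a", "b"), c(0, 0), s),
               "previous word")
})

test_that("softmax probabilities are invariant to similarity shifts", {
  words <- letters[1:4]
  set.seed(51)
  m <- matrix(runif(16), 4); m <- (m + t(m)) / 2; diag(m) <- 1
  s1 <- manual_similarity(words, m)
  s2 <- manual_similarity(words, m + 0.37)
  p1 <- transition_probability("a", words[-1], c(b_sem = 2, b_orth = 0),
                               sem_sim = s1)
  p2 <- transition_probability("a", words[-1], c(b_sem = 2, b_orth = 0),
                               sem_sim = s2)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("list log-likelihood matches closed forms for the uniform model", {
  setup <- small_task_setup(vocab = 80L, dim = 40L)
  sims <- list(category = setup$sims)
  reg <- model_registry()
  fl <- simulate_participant("category", setup$sims, c(0, 0), 12,
                             setup$space$communities, seed = 3)
  N <- length(setup$space$words)
  ll_wo <- list_log_likelihood(fl, reg$semantic_orthographic_task,
                               c(0, 0, 0, 0), sims)
  expect_equal(ll_wo, sum(log(1 / (N - (1:11)))), tolerance = 1e-12)
  ll_w <- list_log_likelihood(fl, reg$semantic_orthographic_task,
                              c(0, 0, 0, 0), sims,
                              policy = "with_replacement")
  expect_equal(ll_w, 11 * log(1 / (N - 1)), tolerance = 1e-12)
})

test_that("a single transition composes with transition_probability", {
  words <- c("a", "b", "c")
  sem <- matrix(c(1, .9, .1, .9, 1, 0, .1, 0, 1), 3,
                dimnames = list(words, words))
  orth <- matrix(0.2, 3, 3, dimnames = list(words, words)); diag(orth) <- 1
  sims <- list(category = make_sim_pair(words, sem, orth))
  reg <- model_registry()
  fl <- fluency_list("p", "control", "category", c("a", "b"))
  ll <- list_log_likelihood(fl, reg$semantic_orthographic_task,
                            c(1, 0, 0, 0), sims)
  p <- transition_probability("a", c("b", "c"), c(b_sem = 1, b_orth = 0),
                              sem_sim = sims$category$semantic,
                              orth_sim = sims$category$orthographic)
  expect_equal(ll, log(p[["b"]]), tolerance = 1e-12)
})

test_that("generating parameters beat perturbed parameters in likelihood", {
  setup <- small_task_setup(vocab = 100L, dim = 50L)
  sims <- list(category = setup$sims)
  reg <- model_registry()
  truth <- c(3, 0.5)
  diffs <- vapply(1:20, function(i) {
    fl <- simulate_participant("category", setup$sims, truth, 25,
                               setup$space$communities, seed = 400 + i)
    list_log_likelihood(fl, reg$semantic_orthographic_task,
                        c(truth, 0, 0), sims) -
      list_log_likelihood(fl, reg$semantic_orthographic_task,
                          c(truth + 2, 0, 0), sims)
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("fits report the AIC identity and survive degenerate lists", {
  setup <- small_task_setup(vocab = 80L, dim = 40L)
  sims <- list(category = setup$sims)
  reg <- model_registry()
  fl <- simulate_participant("category", setup$sims, c(2, 0.5), 15,
                             setup$space$communities, seed = 9,
                             participant_id = "p1")
  fit <- fit_participant(fl, reg$semantic_orthographic_task, sims,
                         n_starts = 3, seed = 2)
  expect_equal(fit$aic, 2 * 4 - 2 * fit$log_likelihood, tolerance = 1e-12)
  expect_lte(fit$log_likelihood, 0)
  expect_equal(fit$participant_id, "p1")

  tiny <- fluency_list("p2", "control", "category", setup$space$words[1:2])
  fit2 <- fit_participant(tiny, reg$semantic_shared, sims, n_starts = 2,
                          seed = 1)
  expect_s3_class(fit2, "choice_model_fit")
  expect_true(is.finite(fit2$log_likelihood))
})

test_that("uniform-random lists fit salience parameters centred on zero", {
  setup <- small_task_setup(vocab = 100L, dim = 50L)
  sims <- list(category = setup$sims)
  reg <- model_registry()
  betas <- t(vapply(1:24, function(i) {
    fl <- simulate_participant("category", setup$sims, c(0, 0), 30,
                               setup$space$communities, seed = 700 + i)
    fit_participant(fl, reg$semantic_orthographic_task, sims, n_starts = 2,
                    seed = i)$beta4[1:2]
  }, numeric(2)))
  # single-list estimates are noisy (SE ~ 1); the cross-participant mean
  # is the unbiasedness check
  expect_lt(abs(mean(betas[, 1])), 0.45)
  expect_lt(abs(mean(betas[, 2])), 0.45)
})

test_that("model comparison sums AIC and spots missing fits", {
  setup <- small_task_setup(vocab = 80L, dim = 40L)
  sims <- list(category = setup$sims)
  reg <- model_registry()
  fits <- list()
  for (i in 1:3) {
    fl <- simulate_participant("category", setup$sims, c(3, 0.5), 15,
                               setup$space$communities, seed = 40 + i,
                               participant_id = paste0("p", i))
    for (m in c("semantic_shared", "orthographic_shared")) {
      fits[[length(fits) + 1L]] <- fit_participant(
        fl, reg[[m]], sims, n_starts = 2, seed = i)
    }
  }
  cmp <- compare_models(fits)
  expect_equal(nrow(cmp$summary), 2L)
  expect_equal(cmp$summary$delta_aic[1], 0)
  expect_equal(cmp$winner, "semantic_shared")
  agg <- tapply(cmp$per_participant$aic, cmp$per_participant$model, sum)
  expect_equal(unname(sort(agg)[1]),
               cmp$summary$summed_aic[1])
  expect_error(compare_models(fits[-1]), "missing fits")
})

test_that("delta-omega arithmetic follows the omega contrasts", {
  reg <- model_registry()
  fit <- structure(
    list(participant_id = "p", model = reg$semantic_orthographic_task,
         betas = setNames(c(3, 1, 1, 2), reg$semantic_orthographic_task$params),
         beta4 = setNames(c(3, 1, 1, 2),
                          c("beta_sem_cat", "beta_orth_cat",
                            "beta_sem_lett", "beta_orth_lett")),
         log_likelihood = -10, aic = 28, converged = TRUE,
         n_transitions = 10L, policy = "without_replacement"),
    class = "choice_model_fit")
  sm <- semantic_modulation(fit)
  expect_equal(sm$omega_cat, 2)
  expect_equal(sm$omega_lett, -1)
  expect_equal(sm$delta_omega, 3)

  fit$beta4[] <- 1
  expect_equal(semantic_modulation(fit)$delta_omega, 0)

  fit$model <- reg$semantic_shared
  expect_error(semantic_modulation(fit), "4-parameter")
})

test_that("model registry parameter counts match their maps", {
  reg <- model_registry()
  expect_named(reg, c("semantic_shared", "orthographic_shared",
                      "semantic_orthographic_shared", "semantic_task",
                      "orthographic_task", "semantic_orthographic_task"))
  for (m in reg) {
    expect_equal(m$n_params, ncol(m$map))
    expect_equal(m$n_params, length(m$params))
  }
})
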