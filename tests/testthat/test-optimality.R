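test_that("shortest Hamiltonian path solves collinear and forced cases", {
  pts <- c(0, 1, 2, 4)
  d <- abs(outer(pts, pts, "-"))
  res <- shortest_hamiltonian_path(d)
  expect_equal(res$total, 4)
  expect_true(identical(res$order, 1:4) || identical(res$order, 4:1))

  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  res2 <- shortest_hamiltonian_path(d2)
  expect_equal(res2$total, 0.3)

  expect_error(shortest_hamiltonian_path(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
  expect_error(shortest_hamiltonian_path(matrix(c(0, -1, -1, 0), 2, 2)),
               "negative")
})

test_that("exact solver matches exhaustive enumeration, free and fixed start", {
  set.seed(11)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    d <- random_distance_matrix(n)
    expect_equal(shortest_hamiltonian_path(d)$total, brute_force_path(d),
                 tolerance = 1e-10)
    s <- sample(n, 1)
    res <- shortest_hamiltonian_path(d, start = s)
    expect_equal(res$total, brute_force_path(d, start = s), tolerance = 1e-10)
    expect_equal(res$order[1], s)
    expect_setequal(res$order, seq_len(n))
  }
})

test_that("heuristic path is a valid permutation bounded below by the optimum", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(9:12, 1)
    d <- random_distance_matrix(n)
    ex <- shortest_hamiltonian_path(d)               # Held-Karp
    he <- shortest_hamiltonian_path(d, exact_max = 2L)  # force heuristic
    expect_setequal(he$order, seq_len(n))
    expect_gte(he$total + 1e-10, ex$total)
    expect_lte(he$total, ex$total * 1.25)  # 2-opt local optimum stays close
  }
})

test_that("optimal path total is invariant to the emission order of the items", {
  setup <- small_task_setup()
  sim <- setup$sims$semantic
  set.seed(3)
  items <- sample(sim$words, 14)
  g1 <- global_optimality_divergence(items, sim, n_shuffles = 50, seed = 1,
                                     start_policy = "free")
  g2 <- global_optimality_divergence(sample(items), sim, n_shuffles = 50,
                                     seed = 1, start_policy = "free")
  expect_equal(g1$optimal_total, g2$optimal_total, tolerance = 1e-10)
})

test_that("a list already in optimal order has zero global divergence", {
  setup <- small_task_setup()
  sim <- setup$sims$semantic
  set.seed(4)
  items <- sample(sim$words, 10)
  d <- distance_matrix(sim)[match(items, sim$words), match(items, sim$words)]
  opt <- shortest_hamiltonian_path(d, start = NULL)
  ordered <- items[opt$order]
  g <- global_optimality_divergence(ordered, sim, n_shuffles = 300, seed = 2,
                                    start_policy = "free")
  expect_equal(g$raw, 0, tolerance = 1e-10)
  expect_lte(g$z, 0)
  expect_equal(g$observed_total, g$optimal_total, tolerance = 1e-10)
})

test_that("local divergence is n-1 for the optimal order and its reversal", {
  setup <- small_task_setup()
  sim <- setup$sims$semantic
  set.seed(5)
  items <- sample(sim$words, 9)
  d <- distance_matrix(sim)[match(items, sim$words), match(items, sim$words)]
  opt <- shortest_hamiltonian_path(d, start = NULL)
  ordered <- items[opt$order]
  l1 <- local_optimality_divergence(ordered, sim, n_shuffles = 100, seed = 1,
                                    start_policy = "free")
  l2 <- local_optimality_divergence(rev(ordered), sim, n_shuffles = 100,
                                    seed = 1, start_policy = "free")
  expect_equal(l1$raw, length(items) - 1)
  expect_equal(l2$raw, length(items) - 1)
})

test_that("shuffle-null z is calibrated for random lists and seeded", {
  setup <- small_task_setup(vocab = 150L, dim = 60L)
  sim <- setup$sims$semantic
  set.seed(6)
  gz <- lz <- numeric(40)
  for (i in 1:40) {
    items <- sample(sim$words, 20)
    g <- global_optimality_divergence(items, sim, n_shuffles = 400,
                                      seed = 100 + i)
    l <- local_optimality_divergence(items, sim, n_shuffles = 400,
                                     seed = 100 + i)
    gz[i] <- g$z; lz[i] <- l$z
  }
  expect_lt(abs(mean(gz)), 0.4)
  expect_lt(abs(mean(lz)), 0.4)
  expect_gt(sd(gz), 0.6); expect_lt(sd(gz), 1.5)
  expect_gt(sd(lz), 0.6); expect_lt(sd(lz), 1.5)

  expect_identical(
    global_optimality_divergence(sim$words[1:12], sim, 200, seed = 9)$z,
    global_optimality_divergence(sim$words[1:12], sim, 200, seed = 9)$z)
})

test_that("stronger semantic guidance drives optimality z more negative", {
  setup <- small_task_setup(vocab = 150L, dim = 60L)
  sim <- setup$sims$semantic
  orth <- setup$sims$orthographic
  sp <- setup$space
  means <- vapply(c(0, 1, 3, 5), function(beta) {
    zs <- vapply(1:12, function(i) {
      fl <- simulate_participant("category",
                                 list(semantic = sim, orthographic = orth),
                                 c(beta, 0), 20, sp$communities,
                                 seed = 1000 * beta + i)
      global_optimality_divergence(fl, sim, n_shuffles = 300,
                                   seed = 300 + i)$z
    }, 0)
    mean(zs)
  }, 0)
  expect_true(all(diff(means) < 0))
  expect_lt(means[4], -2)
})

test_that("degenerate equal-distance lists flag an undefined z", {
  s <- manual_similarity(letters[1:5], {
    m <- matrix(0.5, 5, 5); diag(m) <- 1; m
  })
  g <- global_optimality_divergence(letters[1:5], s, n_shuffles = 50, seed = 1)
  expect_true(g$degenerate)
  expect_true(is.na(g$z))
})

test_that("windowing reduces to the unwindowed statistics and averages windows", {
  setup <- small_task_setup()
  sim <- setup$sims$semantic
  set.seed(8)
  items <- sample(sim$words, 12)
  w <- windowed_metrics(items, sim, window = 12, n_shuffles = 200, seed = 3)
  g <- global_optimality_divergence(items, sim, 200, seed = 3)
  l <- local_optimality_divergence(items, sim, 200, seed = 3)
  expect_equal(w$global_z, g$z)
  expect_equal(w$local_z, l$z)
  expect_equal(w$n_windows, 1L)

  w2 <- windowed_metrics(items, sim, window = 8, n_shuffles = 100, seed = 3)
  expect_equal(w2$n_windows, 5L)
  expect_error(windowed_metrics(items, sim, window = 13, n_shuffles = 10),
               "lower the window")
})

test_that("consecutive distances separate clustered from random sampling", {
  setup <- small_task_setup(vocab = 150L, dim = 60L)
  sim <- setup$sims$semantic
  sp <- setup$space
  two <- consecutive_distance_summary(sim$words[1:2], sim)
  expect_equal(two$mean_consecutive, distance_matrix(sim)[1, 2])

  fl <- simulate_participant("category",
                             list(semantic = sim,
                                  orthographic = setup$sims$orthographic),
                             c(5, 0), 25, sp$communities, seed = 21)
  cd <- consecutive_distance_summary(fl, sim)
  expect_lt(cd$mean_consecutive, cd$mean_all_pairs)

  s <- manual_similarity(letters[1:4], {
    m <- matrix(0.4, 4, 4); diag(m) <- 1; m
  })
  cd2 <- consecutive_distance_summary(letters[1:4], s)
  expect_equal(cd2$mean_consecutive, cd2$mean_all_pairs)
})
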