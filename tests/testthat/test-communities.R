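test_that("lifetimes and returns decompose label runs correctly", {
  lt <- community_lifetimes(c("A", "A", "A", "B", "B", "B"))
  expect_equal(lt$runs, c(3L, 3L))
  expect_equal(lt$mean, 3)
  expect_equal(community_lifetimes(c("A", "B", "C"))$mean, 1)
  expect_equal(community_lifetimes(c("A", "A", "B", "A"))$mean, 4 / 3)

  expect_equal(community_returns(c("A", "A", "B", "A")), 1L)
  expect_equal(community_returns(c("A", "B", "C")), 0L)
  expect_equal(community_returns(c("A", "B", "A", "B")), 2L)
  expect_error(community_lifetimes(character(0)), "empty")
})

test_that("run-length decomposition conserves length and counts returns", {
  set.seed(31)
  for (i in 1:25) {
    labs <- sample(letters[1:4], sample(3:30, 1), replace = TRUE)
    lt <- community_lifetimes(labs)
    expect_equal(sum(lt$runs), length(labs))
    expect_equal(community_returns(labs),
                 length(lt$runs) - length(unique(labs)))
  }
})

test_that("Louvain recovers planted structure deterministically", {
  # two tight orthogonal clusters
  set.seed(32)
  base1 <- c(1, rep(0, 9)); base2 <- c(rep(0, 9), 1)
  v <- rbind(
    t(replicate(10, base1 + rnorm(10, 0, 0.08))),
    t(replicate(10, base2 + rnorm(10, 0, 0.08))))
  sp <- embedding_space(sprintf("w%02d", 1:20), v)
  sim <- similarity_matrix(sp$words, sp, "semantic")
  part <- louvain_partition(sim, 1, seed = 5)
  expect_equal(part$n_communities, 2L)
  expect_equal(length(unique(part$labels[1:10])), 1L)
  expect_equal(length(unique(part$labels[11:20])), 1L)
  expect_true(part$labels[1] != part$labels[11])
  expect_equal(sort(unique(part$labels)), 0:1)

  # planted 4-community space: adjusted Rand > 0.9
  sp4 <- make_embedding_space(160, 80, 4, 0.6, 0.1, seed = 3)
  sim4 <- similarity_matrix(sp4$words, sp4, "semantic")
  p4 <- louvain_partition(sim4, 1, seed = 5)
  ari <- igraph::compare(p4$labels + 1L, sp4$communities + 1L,
                         method = "adjusted.rand")
  expect_gt(ari, 0.9)

  p4b <- louvain_partition(sim4, 1, seed = 5)
  expect_identical(p4$labels, p4b$labels)
  expect_gte(p4$modularity, 0)
})

test_that("single clique collapses to one community; empty graphs error", {
  sim <- manual_similarity(letters[1:4], matrix(1, 4, 4))
  part <- louvain_partition(sim, 1, seed = 1)
  expect_equal(part$n_communities, 1L)

  zero <- manual_similarity(letters[1:4], {
    m <- matrix(-0.2, 4, 4); diag(m) <- 1; m
  })
  expect_error(louvain_partition(zero, 1, seed = 1), "no positive-weight")
})

test_that("community z statistics calibrate on random lists and detect structure", {
  setup <- small_task_setup(vocab = 150L, dim = 60L)
  part <- louvain_partition(setup$sims$semantic, 1, seed = 5)
  set.seed(33)
  lt <- rt <- numeric(40)
  for (i in 1:40) {
    items <- sample(setup$space$words, 20)
    cs <- community_stats_z(items, part, n_shuffles = 400, seed = 600 + i)
    lt[i] <- cs$lifetime_z; rt[i] <- cs$returns_z
  }
  expect_lt(abs(mean(lt)), 0.4)
  expect_lt(abs(mean(rt)), 0.4)

  # community-faithful order: visit each community exhaustively
  labs <- part$labels
  faithful <- setup$space$words[order(labs)][1:40]
  cs <- community_stats_z(faithful, part, n_shuffles = 400, seed = 9)
  expect_gt(cs$lifetime_z, 2)
  expect_lt(cs$returns_z, -2)
})

test_that("single-community lists flag an undefined z", {
  part <- structure(list(words = letters[1:6], labels = rep(0L, 6),
                         resolution = 1, modularity = 0, n_communities = 1L,
                         seed = 1L),
                    class = "community_partition")
  cs <- community_stats_z(letters[1:6], part, n_shuffles = 50, seed = 1)
  expect_true(cs$degenerate)
  expect_true(is.na(cs$lifetime_z))
})

test_that("retrieval-time regression recovers a planted switch effect", {
  sp <- make_embedding_space(200, 80, 8, 0.40, 0.20, n_subclusters = 4,
                             seed = 44)
  sim <- similarity_matrix(sp$words, sp, "semantic")
  osim <- similarity_matrix(sp$words, metric = "orthographic")
  part <- structure(list(words = sp$words, labels = sp$communities,
                         resolution = 1, modularity = NA_real_,
                         n_communities = 8L, seed = 1L),
                    class = "community_partition")
  co <- vapply(1:30, function(i) {
    fl <- simulate_participant("category",
                               list(semantic = sim, orthographic = osim),
                               c(0, 0), 35, sp$communities,
                               rt = list(intercept = 1.8, switch_effect = 0.5,
                                         sem_slope = 0, noise_sd = 0.4),
                               seed = 100 + i)
    rt_regression(fl, sim, part)$coefficients[["community_switch"]]
  }, 0)
  expect_lt(abs(mean(co) - 0.5), 0.15)

  # group-level one-sample test over switch coefficients
  expect_lt(t.test(co, mu = 0)$p.value, 1e-4)
})

test_that("retrieval-time regression handles degenerate designs", {
  sp <- make_embedding_space(60, 30, 3, 0.5, 0.1, seed = 45)
  sim <- similarity_matrix(sp$words, sp, "semantic")
  part <- structure(list(words = sp$words, labels = sp$communities,
                         resolution = 1, modularity = NA_real_,
                         n_communities = 3L, seed = 1L),
                    class = "community_partition")
  items <- sp$words[c(1:5, 21:25, 41:44)]
  # constant retrieval times: all coefficients collapse to zero
  fl <- fluency_list("p", "control", "category", items,
                     times_s = seq(2, by = 2, length.out = length(items)))
  rr <- rt_regression(fl, sim, part)
  expect_lt(abs(rr$coefficients[["community_switch"]]), 1e-10)

  # zero-duration transitions are dropped and counted
  times <- seq(2, by = 2, length.out = length(items))
  times[5] <- times[4]
  fl2 <- fluency_list("p", "control", "category", items, times_s = times)
  rr2 <- rt_regression(fl2, sim, part)
  expect_equal(rr2$n_dropped, 1L)
  expect_error(rt_regression(
    fluency_list("p", "control", "category", items), sim, part),
    "no retrieval times")
})

test_that("community labels come from the nearest centroid vocabulary words", {
  v <- diag(4)
  sp <- embedding_space(c("a", "b", "c", "d"), v)
  part <- structure(list(words = c("a", "b"), labels = c(0L, 1L),
                         resolution = 1, modularity = 0, n_communities = 2L,
                         seed = 1L),
                    class = "community_partition")
  lab <- label_communities(part, sp, k = 1)
  expect_equal(lab[["0"]], "a")
  expect_equal(lab[["1"]], "b")

  # symmetric two-member community: ties broken lexicographically
  v2 <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  sp2 <- embedding_space(c("b", "d", "a", "c"), v2)
  part2 <- structure(list(words = c("b", "d", "a", "c"),
                          labels = rep(0L, 4), resolution = 1,
                          modularity = 0, n_communities = 1L, seed = 1L),
                     class = "community_partition")
  lab2 <- label_communities(part2, sp2, k = 4)
  # centroid equidistant from all four: order alphabetical
  expect_equal(lab2[["0"]], c("a", "b", "c", "d"))

  # planted clusters: labels drawn from the correct cluster
  sp3 <- make_embedding_space(120, 60, 3, 0.6, 0.1, seed = 46)
  sim3 <- similarity_matrix(sp3$words, sp3, "semantic")
  part3 <- louvain_partition(sim3, 1, seed = 2)
  labs3 <- label_communities(part3, sp3, k = 3)
  for (cm in names(labs3)) {
    members <- part3$words[part3$labels == as.integer(cm)]
    expect_true(all(labs3[[cm]] %in% members))
  }
})
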