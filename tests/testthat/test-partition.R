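test_that("Louvain finds the brute-force modularity optimum on two 4-cliques", {
  W <- two_cliques(4)
  got <- louvain_once(W, gamma = 1, seed = 5)
  # exhaustive search over all 4140 partitions of 8 nodes
  parts <- all_partitions(8)
  qs <- vapply(parts, function(a) modularity_naive(W, a), numeric(1))
  best <- parts[[which.max(qs)]]
  expect_equal(unname(got), best)
  expect_equal(modularity_score(W, got), max(qs), tolerance = 1e-12)
  # the optimum is the two cliques
  expect_equal(unname(got), rep(1:2, each = 4))
})

test_that("a single edge joins both nodes into one module", {
  W <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  # enumerate both partitions: together Q = 0, apart Q = -0.5
  expect_equal(modularity_naive(W, c(1, 1)), 0)
  expect_equal(modularity_naive(W, c(1, 2)), -0.5)
  expect_equal(unname(louvain_once(W, seed = 1)), c(1, 1))
})

test_that("Louvain runs are deterministic given a seed", {
  set.seed(99)
  W <- random_symmetric(20, density = 0.4)
  a1 <- louvain_once(W, gamma = 1, seed = 123)
  a2 <- louvain_once(W, gamma = 1, seed = 123)
  expect_identical(a1, a2)
})

test_that("modularity matches the naive double-loop oracle", {
  # all nodes in one module at gamma = 1 gives exactly 0
  W <- two_cliques(3)
  expect_equal(modularity_score(W, rep(1, 6), gamma = 1), 0, tolerance = 1e-12)
  # two disjoint unit-weight 3-cliques split correctly: Q = 0.5 by hand
  expect_equal(modularity_score(W, rep(1:2, each = 3)), 0.5, tolerance = 1e-12)
  # random graphs, several resolutions
  set.seed(11)
  for (rep in 1:5) {
    Wr <- random_symmetric(12, density = 0.5)
    a <- sample(1:3, 12, replace = TRUE)
    for (g in c(0.6, 1, 1.7)) {
      expect_equal(modularity_score(Wr, a, gamma = g),
                   modularity_naive(Wr, a, gamma = g), tolerance = 1e-10)
    }
  }
})

test_that("consensus on disjoint cliques returns the cliques with a block agreement matrix", {
  W <- two_cliques(4)
  for (tau in c(0.3, 0.5, 0.8)) {
    p <- consensus_partition(W, gamma = 1, n_runs = 25, tau = tau, seed = 2)
    expect_equal(p$n_modules, 2)
    expect_equal(p$assignment$module, rep(1:2, each = 4))
    block <- (outer(rep(1:2, each = 4), rep(1:2, each = 4), `==`)) * 1
    expect_equal(unname(p$agreement), block)
  }
})

test_that("single-run consensus equals the single Louvain partition", {
  set.seed(4)
  W <- random_symmetric(15, density = 0.5)
  p <- consensus_partition(W, gamma = 1, n_runs = 1, seed = 77)
  # with one run the agreement matrix is that run's co-assignment indicator,
  # so the consensus must reproduce its module blocks
  runs_partition <- apply(p$agreement == 1, 1, function(r) which(r)[1])
  expect_equal(p$assignment$module, canonical <- match(runs_partition, unique(runs_partition)))
})

test_that("consensus is idempotent on its own agreement matrix", {
  cfg <- sim_config(n_cortical = 24, seed = 8)
  truth <- simulate_base_network(cfg)
  cort <- truth$atlas$tissue_class == "cortical"
  W <- truth$B[cort, cort]
  p <- consensus_partition(W, gamma = 1, n_runs = 50, seed = 3)
  p2 <- consensus_partition(p$agreement, gamma = 1, n_runs = 50, seed = 9)
  expect_equal(p2$assignment$module, p$assignment$module)
})

test_that("consensus recovers the planted partition and respects the gamma sweep", {
  cfg <- sim_config(seed = 21)
  truth <- simulate_base_network(cfg)
  atlas <- truth$atlas
  cort <- atlas$tissue_class == "cortical"
  W <- truth$B[cort, cort]
  counts <- integer(0)
  for (g in c(0.6, 1, 1.7)) {
    p <- consensus_partition(W, gamma = g, n_runs = 60, seed = 14)
    counts <- c(counts, p$n_modules)
    if (g == 1) {
      planted <- truth$partition
      expect_equal(
        p$assignment$module[match(planted$name, p$assignment$name)],
        as.integer(planted$module)
      )
    }
  }
  expect_true(all(diff(counts) >= 0))
})

test_that("module labels are canonical: lowest contained region first", {
  W <- two_cliques(3)
  a <- louvain_once(W, seed = 10)
  expect_equal(unname(a[1]), 1L)
  expect_equal(sort(unique(unname(a))), seq_along(unique(a)))
})

test_that("modal consensus returns the most frequent assignment", {
  W <- two_cliques(4)
  p <- consensus_partition(W, gamma = 1, n_runs = 20, seed = 6, method = "modal")
  expect_equal(p$assignment$module, rep(1:2, each = 4))
  expect_equal(p$method, "modal")
})

test_that("degenerate graphs are rejected", {
  expect_error(louvain_once(matrix(numeric(0), 0, 0)), "empty")
  expect_error(modularity_score(two_cliques(2), rep(1, 3)), "cover")
})
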