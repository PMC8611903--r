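two_cliques <- function() {
  w <- matrix(0, 6, 6)
  for (i in 1:2) {
    idx <- ((i - 1) * 3 + 1):(i * 3)
    w[idx, idx] <- 1
  }
  diag(w) <- 0
  w
}

test_that("modularity matches hand values and the brute-force double sum", {
  w <- two_cliques()
  expect_equal(modularity_score(w, rep(1, 6)), 0)
  expect_equal(modularity_score(w, c(1, 1, 1, 2, 2, 2)), 0.5)
  set.seed(13)
  for (rep in 1:5) {
    wr <- random_weighted_graph(8, 0.7)
    memb <- sample(1:3, 8, replace = TRUE)
    expect_equal(modularity_score(wr, memb), oracle_modularity(wr, memb),
      tolerance = 1e-12
    )
  }
  expect_error(modularity_score(matrix(0, 4, 4), rep(1, 4)),
    class = "geonull_undefined_metric"
  )
  # invariance under relabeling and uniform scaling
  wr <- random_weighted_graph(7, 0.8)
  memb <- c(1, 2, 1, 3, 2, 3, 1)
  expect_equal(
    modularity_score(wr, memb),
    modularity_score(5 * wr, c(3, 1, 3, 2, 1, 2, 3))
  )
})

test_that("louvain recovers planted cliques and matches exhaustive search", {
  w <- two_cliques()
  p <- louvain_partition(w, seed = 3, n_restarts = 5)
  expect_equal(p$Q, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(p$assignment)), 2)
  expect_equal(p$assignment[1:3], rep(p$assignment[1], 3))
  # exhaustive oracle over all set partitions of 6 nodes
  set.seed(17)
  for (rep in 1:3) {
    wr <- random_weighted_graph(6, 0.8)
    if (sum(wr) == 0) next
    best <- oracle_best_partition(wr)
    p <- louvain_partition(wr, seed = rep, n_restarts = 20)
    expect_lte(p$Q, best$q + 1e-9)
  }
  # determinism
  wr <- random_weighted_graph(12, 0.5)
  p1 <- louvain_partition(wr, seed = 9, n_restarts = 5)
  p2 <- louvain_partition(wr, seed = 9, n_restarts = 5)
  expect_identical(p1$assignment, p2$assignment)
})

test_that("label alignment maximizes agreement over permutations", {
  ref <- module_partition(c(1, 1, 2, 2, 3, 3, 1, 2, 3, 1))
  # permuted labels realign to 100%
  permuted <- module_partition(c(3, 3, 1, 1, 2, 2, 3, 1, 2, 3))
  aligned <- align_labels(permuted, ref)
  expect_equal(partition_agreement(aligned, ref), 100)
  # self-alignment is the identity
  expect_identical(align_labels(ref, ref)$assignment, ref$assignment)
  # brute force over all 3! mappings on a noisy 10-node case
  set.seed(23)
  for (rep in 1:10) {
    p <- sample(1:3, 10, replace = TRUE)
    r <- sample(1:3, 10, replace = TRUE)
    aligned <- align_labels(p, r)
    best <- 0
    perms <- list(
      c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
    )
    for (pm in perms) best <- max(best, mean(pm[p] == r))
    expect_equal(partition_agreement(aligned, r), 100 * best)
  }
})

test_that("consensus takes per-node majorities with low-ID ties", {
  ref <- module_partition(c(1, 1, 2, 2))
  same <- list(ref, ref, ref)
  expect_identical(consensus_partition(same, ref)$assignment, ref$assignment)
  # node-level majority (1,1,2) -> 1; tie (1,2) -> 1
  ps <- list(c(1, 1, 2, 2), c(1, 2, 2, 2), c(2, 1, 2, 1))
  cons <- consensus_partition(ps, ref)
  counts <- sapply(1:4, function(k) {
    tab <- tabulate(sapply(ps, function(p) align_labels(p, ref)$assignment[k]))
    which.max(tab)
  })
  expect_identical(cons$assignment, as.integer(counts))
  # planted consensus with label noise is recovered
  set.seed(31)
  planted <- sample(1:4, 20, replace = TRUE)
  reps <- lapply(1:20, function(i) {
    noisy <- planted
    flip <- sample(20, 3)
    noisy[flip] <- sample(1:4, 3, replace = TRUE)
    noisy
  })
  cons <- consensus_partition(reps, module_partition(planted))
  agree <- partition_agreement(cons, planted)
  # per-node counting oracle
  aligned_mat <- sapply(reps, function(p) {
    align_labels(p, module_partition(planted))$assignment
  })
  oracle_cons <- apply(aligned_mat, 1, function(v) which.max(tabulate(v)))
  expect_identical(cons$assignment, as.integer(oracle_cons))
  expect_gte(agree, 95)
  expect_error(consensus_partition(list(), ref), class = "geonull_invalid_input")
})

test_that("partition agreement counts matching labels", {
  p <- c(1, 2, 1, 2)
  expect_equal(partition_agreement(p, p), 100)
  expect_equal(partition_agreement(c(1, 1, 2, 2), c(2, 2, 1, 1)), 0)
  set.seed(37)
  a <- sample(1:4, 50, replace = TRUE)
  b <- sample(1:4, 50, replace = TRUE)
  cnt <- 0
  for (i in 1:50) if (a[i] == b[i]) cnt <- cnt + 1
  expect_equal(partition_agreement(a, b), 100 * cnt / 50)
})

test_that("participation coefficients match formula cases and loops", {
  w <- two_cliques()
  p <- participation_coefficients(w, c(1, 1, 1, 2, 2, 2))
  expect_equal(as.numeric(p), rep(0, 6))
  # node with equal weight to 4 modules
  w4 <- matrix(0, 5, 5)
  w4[1, 2:5] <- w4[2:5, 1] <- 1
  p4 <- participation_coefficients(w4, c(1, 1, 2, 3, 4))
  expect_equal(as.numeric(p4[1]), 0.75)
  set.seed(41)
  wr <- random_weighted_graph(8, 0.7)
  memb <- sample(1:3, 8, replace = TRUE)
  expect_equal(
    as.numeric(suppressWarnings(participation_coefficients(wr, memb))),
    oracle_participation(wr, memb),
    tolerance = 1e-12
  )
  # bound: P in [0, 1 - 1/M]
  expect_true(all(p4 <= 1 - 1 / 4 + 1e-12))
})

test_that("eigenvector centrality matches dense eigendecomposition", {
  # uniform ring: all equal
  ring <- matrix(0, 6, 6)
  for (i in 1:6) {
    j <- i %% 6 + 1
    ring[i, j] <- ring[j, i] <- 1
  }
  ec <- eigenvector_centrality(ring)
  expect_equal(as.numeric(ec), rep(1 / sqrt(6), 6), tolerance = 1e-8)
  # star: hub = sqrt(3) x leaf
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  ecs <- eigenvector_centrality(star)
  expect_equal(ecs[[1]] / ecs[[2]], sqrt(3), tolerance = 1e-7)
  expect_equal(as.numeric(ecs), oracle_eigenvector(star), tolerance = 1e-7)
  # scale invariance
  set.seed(43)
  wr <- random_weighted_graph(8, 0.9)
  expect_equal(
    as.numeric(eigenvector_centrality(wr)),
    as.numeric(eigenvector_centrality(10 * wr)),
    tolerance = 1e-8
  )
  expect_error(eigenvector_centrality(matrix(0, 3, 3)),
    class = "geonull_undefined_metric"
  )
})

test_that("node strengths are row sums", {
  expect_equal(node_strengths(matrix(0, 4, 4)), rep(0, 4))
  tri <- matrix(1, 3, 3)
  diag(tri) <- 0
  expect_equal(node_strengths(tri), rep(2, 3))
  set.seed(47)
  wr <- random_weighted_graph(10, 0.6)
  s <- numeric(10)
  for (i in 1:10) for (j in 1:10) s[i] <- s[i] + wr[i, j]
  expect_equal(node_strengths(wr), s)
})

test_that("efficiencies match hand values and brute-force BFS", {
  cg <- matrix(1, 5, 5)
  diag(cg) <- 0
  expect_equal(global_efficiency(cg), 1)
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(global_efficiency(path3), 5 / 6)
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  tri <- matrix(1, 3, 3)
  diag(tri) <- 0
  expect_equal(local_efficiency(tri), rep(1, 3), ignore_attr = TRUE)
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(local_efficiency(star), rep(0, 5), ignore_attr = TRUE)
  expect_error(global_efficiency(matrix(0, 1, 1)),
    class = "geonull_undefined_metric"
  )
})

test_that("clustering and path length match brute force", {
  cg <- matrix(1, 5, 5)
  diag(cg) <- 0
  cp <- clustering_and_path_length(cg)
  expect_equal(cp$clustering, 1)
  expect_equal(cp$path_length, 1)
  ring5 <- matrix(0, 5, 5)
  for (i in 1:5) {
    j <- i %% 5 + 1
    ring5[i, j] <- ring5[j, i] <- 1
  }
  expect_equal(clustering_and_path_length(ring5)$clustering, 0)
})

test_that("centrality table assembles all measures", {
  b <- tiny_graph_fixture(n = 10, seed = 5)
  part <- louvain_partition(b$graph$weights, seed = 1, n_restarts = 5)
  tab <- node_centralities(b$graph, part)
  expect_equal(nrow(tab), 10)
  expect_true(all(c("strength", "eigenvector", "participation") %in% names(tab)))
  expect_equal(tab$strength, unname(rowSums(b$graph$weights)))
})
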