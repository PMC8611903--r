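test_that("symmetrize_directed sums bidirectional weights", {
  expect_equal(symmetrize_directed(matrix(0, 3, 3)), matrix(0, 3, 3))
  wd <- matrix(c(0, 3, 2, 0), 2, 2, byrow = TRUE) # (1,2)=2 after byrow? set explicitly
  wd <- matrix(0, 2, 2)
  wd[1, 2] <- 2
  wd[2, 1] <- 3
  out <- symmetrize_directed(wd)
  expect_equal(out[1, 2], 5)
  expect_equal(out[2, 1], 5)
  s <- matrix(runif(16), 4, 4)
  s <- (s + t(s)) / 2
  diag(s) <- 0
  expect_equal(symmetrize_directed(s), 2 * s)
  set.seed(1)
  wr <- matrix(runif(25), 5, 5)
  expect_equal(max(abs(symmetrize_directed(wr) - t(symmetrize_directed(wr)))), 0)
  expect_error(symmetrize_directed(matrix(1, 2, 3)), class = "geonull_invalid_input")
  expect_error(symmetrize_directed(-diag(3)), class = "geonull_invalid_input")
})

test_that("hemispheric symmetry enforcement averages mirrored entries", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 4 # mirrored entry (3,4) is 0
  out <- enforce_hemispheric_symmetry(w, mirror_homolog4)
  expect_equal(out[1, 2], 2)
  expect_equal(out[3, 4], 2)
  # mirror identity, idempotence, weight conservation on a random graph
  set.seed(3)
  n <- 6
  hom <- c(4L, 5L, 6L, 1L, 2L, 3L)
  w <- random_weighted_graph(n, 1)
  out <- enforce_hemispheric_symmetry(w, hom)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      expect_equal(out[i, j], out[hom[i], hom[j]], tolerance = 1e-12)
    }
  }
  expect_equal(enforce_hemispheric_symmetry(out, hom), out)
  expect_equal(sum(out), sum(w))
  # mirror-symmetric input is a fixed point
  expect_equal(enforce_hemispheric_symmetry(out, hom), out)
  expect_error(
    enforce_hemispheric_symmetry(w, c(2L, 1L, 4L, 3L, 6L, 6L)),
    class = "geonull_invalid_input"
  )
})

test_that("normalize_connection_density divides by volume products", {
  cnt <- matrix(0, 2, 2)
  cnt[1, 2] <- cnt[2, 1] <- 6
  out <- normalize_connection_density(cnt, c(2, 3))
  expect_equal(out[1, 2], 1)
  cnt <- matrix(runif(9), 3, 3)
  expect_equal(normalize_connection_density(cnt, rep(1, 3)), cnt)
  expect_equal(normalize_connection_density(matrix(0, 3, 3), runif(3, 1, 2)), matrix(0, 3, 3))
  # homogeneity: scaling volumes by c scales weights by c^-2
  v <- runif(3, 1, 2)
  expect_equal(
    normalize_connection_density(cnt, 2 * v),
    normalize_connection_density(cnt, v) / 4
  )
  expect_error(normalize_connection_density(cnt, c(1, 0, 1)), class = "geonull_invalid_input")
})

test_that("threshold_to_density keeps the top-weight pairs deterministically", {
  set.seed(5)
  w <- random_weighted_graph(4, 1)
  expect_equal(sum(threshold_to_density(w, 1)) / 2, 6)
  expect_equal(sum(threshold_to_density(w, 0)), 0)
  # d = 0.5 keeps exactly the top-3 pairs, checked by exhaustive sort
  a <- threshold_to_density(w, 0.5)
  iu <- which(upper.tri(w), arr.ind = TRUE)
  top3 <- iu[order(-w[upper.tri(w)])[1:3], ]
  expect_equal(sum(a) / 2, 3)
  for (k in 1:3) expect_equal(a[top3[k, 1], top3[k, 2]], 1)
  # monotone nesting over a density sweep (includes tied weights)
  wt <- matrix(0, 5, 5)
  wt[upper.tri(wt)] <- c(1, 2, 2, 3, 1, 2, 4, 4, 1, 5)
  wt <- wt + t(wt)
  prev <- threshold_to_density(wt, 0)
  for (d in seq(0.1, 1, by = 0.1)) {
    cur <- threshold_to_density(wt, d)
    expect_true(all(cur - prev >= 0))
    prev <- cur
  }
  expect_error(threshold_to_density(w, 1.5), class = "geonull_invalid_input")
})

test_that("spatial graphs round-trip through the TSV dialect", {
  b <- tiny_graph_fixture()
  g <- b$graph
  dir <- withr::local_tempdir()
  paths <- write_spatial_graph(g, dir)
  g2 <- read_spatial_graph(paths[["weights"]], paths[["distances"]], paths[["parcellation"]])
  expect_equal(g2$weights, g$weights, tolerance = 1e-12)
  expect_equal(g2$fiber_distances, g$fiber_distances, tolerance = 1e-12)
  expect_equal(g2$coordinates, g$coordinates, tolerance = 1e-12)
  expect_equal(g2$volumes, g$volumes, tolerance = 1e-12)
  expect_identical(g2$region_ids, g$region_ids)
  expect_identical(g2$homolog, g$homolog)
})

test_that("reader reorders permuted matrices and rejects bad input", {
  b <- tiny_graph_fixture()
  g <- b$graph
  dir <- withr::local_tempdir()
  paths <- write_spatial_graph(g, dir)
  # permute matrix rows/cols relative to the parcellation
  perm <- rev(seq_along(g$region_ids))
  wp <- g$weights[perm, perm]
  df <- data.frame(region_id = rownames(wp), wp, check.names = FALSE)
  write.table(df, paths[["weights"]], sep = "\t", quote = FALSE, row.names = FALSE)
  g3 <- read_spatial_graph(paths[["weights"]], paths[["distances"]], paths[["parcellation"]])
  expect_equal(g3$weights, g$weights, tolerance = 1e-12)
  # NaN rejected
  wn <- g$weights
  wn[1, 2] <- wn[2, 1] <- NaN
  df <- data.frame(region_id = rownames(wn), wn, check.names = FALSE)
  write.table(df, paths[["weights"]], sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(
    read_spatial_graph(paths[["weights"]], paths[["distances"]], paths[["parcellation"]]),
    class = "geonull_invalid_input"
  )
  # asymmetry beyond 1e-9 rejected with offending indices
  wa <- g$weights
  wa[1, 2] <- wa[1, 2] + 1
  df <- data.frame(region_id = rownames(wa), wa, check.names = FALSE)
  write.table(df, paths[["weights"]], sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(
    read_spatial_graph(paths[["weights"]], paths[["distances"]], paths[["parcellation"]]),
    "(1,2)",
    fixed = TRUE
  )
})

test_that("spatial_graph validates its invariants", {
  b <- tiny_graph_fixture()
  g <- b$graph
  w <- g$weights
  w[1, 2] <- w[1, 2] + 1 # asymmetric
  expect_error(
    spatial_graph(
      w, g$fiber_distances, g$coordinates, g$volumes, g$region_ids,
      g$hemisphere, g$division, g$homolog
    ),
    class = "geonull_invalid_input"
  )
  fd <- g$fiber_distances / 10 # below Euclidean
  expect_error(
    spatial_graph(
      g$weights, fd, g$coordinates, g$volumes, g$region_ids,
      g$hemisphere, g$division, g$homolog
    ),
    class = "geonull_invalid_input"
  )
  hom <- g$homolog
  hom[1] <- 1L # not an involution across hemispheres
  expect_error(
    spatial_graph(
      g$weights, g$fiber_distances, g$coordinates, g$volumes,
      g$region_ids, g$hemisphere, g$division, hom
    ),
    class = "geonull_invalid_input"
  )
})
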