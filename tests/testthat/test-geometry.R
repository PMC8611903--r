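test_that("z-scoring log-weights standardizes the positive edges", {
  # two distinct weights: z = +/- 1 under the population convention
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[1, 3] <- w[3, 1] <- exp(2)
  z <- zscore_log_weights(w)
  expect_equal(sort(z[upper.tri(z)][!is.na(z[upper.tri(z)])]), c(-1, 1))
  b <- medium_benchmark()
  z <- zscore_log_weights(b$graph)
  vals <- z[upper.tri(z)]
  vals <- vals[!is.na(vals)]
  expect_equal(mean(vals), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(vals^2)), 1, tolerance = 1e-9)
  # invariance under weight rescaling
  z2 <- zscore_log_weights(17 * b$graph$weights)
  expect_equal(z, z2, tolerance = 1e-9)
  wc <- matrix(1, 3, 3)
  diag(wc) <- 0
  expect_error(zscore_log_weights(wc), class = "geonull_degenerate_input")
})

test_that("binned profiles match a loop-based oracle", {
  # forced two-bin case
  z <- matrix(NA_real_, 4, 4)
  z[1, 2] <- z[2, 1] <- -1
  z[3, 4] <- z[4, 3] <- -1
  z[1, 3] <- z[3, 1] <- 1
  z[2, 4] <- z[4, 2] <- 1
  f <- matrix(0, 4, 4)
  f[1, 2] <- f[2, 1] <- 0.5
  f[3, 4] <- f[4, 3] <- 0.6
  f[1, 3] <- f[3, 1] <- 1.5
  f[2, 4] <- f[4, 2] <- 1.7
  f[1, 4] <- f[4, 1] <- 5
  f[2, 3] <- f[3, 2] <- 5
  prof <- binned_weight_profile(z, f, width = 1)
  expect_equal(prof$mean, c(-1, 1))
  expect_equal(prof$sd, c(0, 0))
  expect_equal(prof$n, c(2L, 2L))

  b <- medium_benchmark()
  g <- b$graph
  zz <- zscore_log_weights(g)
  prof <- binned_weight_profile(zz, g$fiber_distances, width = 1)
  expect_equal(sum(prof$n), sum(!is.na(zz[upper.tri(zz)])))
  # loop oracle per bin
  iu <- which(upper.tri(zz), arr.ind = TRUE)
  for (r in sample(nrow(prof), 5)) {
    lo <- prof$bin_lo[r]
    hi <- prof$bin_hi[r]
    vals <- c()
    for (k in seq_len(nrow(iu))) {
      i <- iu[k, 1]
      j <- iu[k, 2]
      fd <- g$fiber_distances[i, j]
      if (!is.na(zz[i, j]) && fd >= lo && fd < hi) vals <- c(vals, zz[i, j])
    }
    expect_equal(prof$mean[r], mean(vals), tolerance = 1e-12)
    expect_equal(prof$n[r], length(vals))
  }
  # count-weighted bin means average to the global zero
  expect_equal(sum(prof$mean * prof$n) / sum(prof$n), 0, tolerance = 1e-9)
})

test_that("profile comparison flags shifted bins after correction", {
  b <- tiny_graph_fixture(n = 20, seed = 9)
  g <- b$graph
  ref <- binned_weight_profile(zscore_log_weights(g), g$fiber_distances)
  # replicates identical to the reference: nothing significant
  reps <- list(ref, ref, ref, ref, ref)
  cmp <- compare_profiles(reps, ref)
  expect_true(all(!cmp$significant))
  # shift one bin by 10 SDs in all replicates
  set.seed(2)
  shifted <- lapply(1:5, function(i) {
    p <- ref
    p$mean[3] <- p$mean[3] + 10
    p$mean <- p$mean + rnorm(length(p$mean), sd = 1e-3)
    p
  })
  cmp2 <- compare_profiles(shifted, ref)
  expect_true(cmp2$significant[3])
  # hand t-statistic for the shifted bin
  vals <- vapply(shifted, function(p) p$mean[3], numeric(1))
  tstat <- (mean(vals) - ref$mean[3]) / (sd(vals) / sqrt(5))
  expect_equal(cmp2$statistic[3], tstat, tolerance = 1e-12)
  # alpha = 0 flags nothing
  cmp3 <- compare_profiles(shifted, ref, alpha = 0)
  expect_true(all(!cmp3$significant))
  expect_error(compare_profiles(list(ref), ref),
    class = "geonull_insufficient_replicates"
  )
})

test_that("hub identification takes the top fraction with stable ties", {
  set.seed(3)
  v <- runif(20)
  h <- identify_hubs(v, 0.15)
  expect_length(h$indices, 3)
  expect_identical(h$indices, sort(order(-v)[1:3]))
  # all-equal centralities: first round(f*N) indices, with a warning
  expect_warning(ht <- identify_hubs(rep(1, 20), 0.15))
  expect_identical(ht$indices, 1:3)
  # full-sort oracle
  v2 <- rnorm(57)
  h2 <- identify_hubs(v2, 0.15)
  expect_identical(h2$indices, sort(sort.list(-v2)[seq_len(round(0.15 * 57))]))
})

test_that("center-of-mass distances use the volume-weighted centroid", {
  coords <- rbind(c(1, 0, 0), c(-1, 0, 0))
  expect_equal(com_distances(coords, c(1, 1)), c(1, 1))
  # a node sitting at the center of mass scores 0
  coords3 <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 0, 0))
  expect_equal(com_distances(coords3, c(1, 1, 2), subset = 3), 0)
  set.seed(5)
  coords30 <- matrix(rnorm(90), 30, 3)
  vols <- runif(30, 0.5, 3)
  d <- com_distances(coords30, vols)
  com <- c(0, 0, 0)
  for (i in 1:30) com <- com + vols[i] * coords30[i, ]
  com <- com / sum(vols)
  for (i in sample(30, 6)) {
    expect_equal(d[i], sqrt(sum((coords30[i, ] - com)^2)), tolerance = 1e-12)
  }
})

test_that("mean neighbor fiber distance is the weight-weighted average", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[1, 3] <- w[3, 1] <- 1
  f <- matrix(0, 3, 3)
  f[1, 2] <- f[2, 1] <- 2
  f[1, 3] <- f[3, 1] <- 4
  expect_equal(mean_neighbor_fiber_distance(w, f)[1], 3)
  w[1, 2] <- w[2, 1] <- 3
  expect_equal(mean_neighbor_fiber_distance(w, f)[1], 2.5)
  b <- medium_benchmark()
  g <- b$graph
  dn <- mean_neighbor_fiber_distance(g$weights, g$fiber_distances)
  for (i in sample(length(dn), 5)) {
    num <- 0
    den <- 0
    for (j in seq_along(dn)) {
      num <- num + g$weights[i, j] * g$fiber_distances[i, j]
      den <- den + g$weights[i, j]
    }
    expect_equal(dn[i], num / den, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("normalized metric ratios divide by the ensemble mean", {
  expect_equal(normalized_metric_ratio(2, c(2, 2, 2)), 1)
  expect_equal(normalized_metric_ratio(3, c(2, 2, 2)), 1.5)
  set.seed(7)
  ens <- rnorm(100, 5)
  expect_equal(normalized_metric_ratio(4, ens), 4 / mean(ens), tolerance = 1e-12)
  expect_error(normalized_metric_ratio(1, c(-1, 1)), class = "geonull_invalid_input")
})

test_that("hub strength percentages sum to 100 and match loop sums", {
  s <- c(3, 1, 2, 2)
  division <- c("a", "b", "a", "c")
  hubs <- identify_hubs(s, 0.75) # hubs {1, 3, 4}: strengths 3, 2, 2
  tab <- hub_strength_by_division(s, hubs, division)
  expect_equal(sum(tab$percent), 100, tolerance = 1e-9)
  expect_equal(tab$percent[tab$division == "a"], 100 * 5 / 7)
  expect_equal(tab$percent[tab$division == "c"], 100 * 2 / 7)
  # two hubs with strengths 3 and 1 in different divisions -> 75 / 25
  tab2 <- hub_strength_by_division(c(3, 1), structure(
    list(indices = 1:2, fraction = 1, measure = "strength", threshold_value = 1),
    class = "hub_set"
  ), c("x", "y"))
  expect_equal(tab2$percent, c(75, 25))
  set.seed(11)
  b <- medium_benchmark()
  g <- b$graph
  s <- rowSums(g$weights)
  hubs <- identify_hubs(s, 0.15)
  tab3 <- hub_strength_by_division(s, hubs, g$division)
  for (d in tab3$division) {
    acc <- 0
    for (i in hubs$indices) if (g$division[i] == d) acc <- acc + s[i]
    expect_equal(
      tab3$percent[tab3$division == d],
      as.numeric(100 * acc / sum(s[hubs$indices])),
      tolerance = 1e-9
    )
  }
})

test_that("correlations match definitional oracles", {
  x <- 1:10
  expect_equal(spearman_rho(x, x^3), 1)
  expect_equal(spearman_rho(x, rev(x)), -1)
  set.seed(13)
  a <- rnorm(20)
  bb <- rnorm(20)
  expect_equal(spearman_rho(a, bb), oracle_spearman(a, bb), tolerance = 1e-12)
  expect_equal(pearson_r(a, bb), oracle_pearson(a, bb), tolerance = 1e-12)
})

test_that("division-level weight agreement restricts to edge blocks", {
  b <- medium_benchmark()
  g <- b$graph
  n <- nrow(g$weights)
  set.seed(1)
  wb <- g$weights *
    exp(matrix(rnorm(n * n, sd = 0.2), n, n) |> (\(m) (m + t(m)) / 2)())
  diag(wb) <- 0
  tab <- division_weight_agreement(g$weights, wb, g$division, g$hemisphere)
  overall <- tab[tab$division_a == "all", ]
  iu <- upper.tri(g$weights)
  expect_equal(overall$rho, spearman_rho(g$weights[iu], wb[iu]), tolerance = 1e-12)
  # spot-check one division pair with a loop
  r <- tab[tab$division_a != "all" & !is.na(tab$rho) & tab$n_edges >= 3, ][1, ]
  xa <- c()
  xb <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      lo <- min(g$division[i], g$division[j])
      hi <- max(g$division[i], g$division[j])
      lat <- if (g$hemisphere[i] == g$hemisphere[j]) "ipsi" else "contra"
      if (lo == r$division_a && hi == r$division_b && lat == r$laterality) {
        xa <- c(xa, g$weights[i, j])
        xb <- c(xb, wb[i, j])
      }
    }
  }
  expect_equal(r$n_edges, length(xa))
  expect_equal(r$rho, oracle_spearman(xa, xb), tolerance = 1e-12)
})

test_that("tukey and permutation tests behave under null and separation", {
  set.seed(17)
  base_draw <- rnorm(15)
  tk <- tukey_range_test(list(a = base_draw, b = base_draw, c = base_draw))
  expect_true(all(tk$p_value > 0.99))
  same <- lapply(1:3, function(i) rnorm(15))
  far <- list(a = rnorm(10), b = rnorm(10) + 20)
  tk2 <- tukey_range_test(far)
  expect_lt(tk2$p_value[1], 1e-6)
  pt <- permutation_test(far$a, far$b, n_perm = 999, seed = 5)
  expect_equal(pt$p_value, 1 / 1000)
  pt2 <- permutation_test(far$a, far$b, n_perm = 999, seed = 5)
  expect_identical(pt, pt2)
  null_pt <- permutation_test(same[[1]], same[[2]], n_perm = 499, seed = 7)
  expect_gt(null_pt$p_value, 0.01)
  expect_error(permutation_test(1:3, 4:6, n_perm = 0), class = "geonull_invalid_input")
})
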