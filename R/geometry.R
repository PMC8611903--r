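# Geometry-aware analyses: z-scored weight-distance profiles, hubs,
# center-of-mass peripherality, neighbor fiber distances, surrogate
# normalisation, division summaries.

#' Z-score log-weights of a network
#'
#' Standardizes the natural-log weights of the positive upper-triangle
#' edges to zero mean and unit variance (population SD convention by
#' default), making weight-distance profiles comparable across modalities
#' whose weights live in different units. Invariant to uniform weight
#' rescaling.
#'
#' @param w Symmetric nonnegative weight matrix (or [spatial_graph()]).
#' @param convention "population" (divide by E) or "sample" (E - 1).
#' @return Symmetric z-score matrix; `NA` at zero pairs and the diagonal.
#' @export
zscore_log_weights <- function(w, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  if (inherits(w, "spatial_graph")) w <- w$weights
  check_symmetric(w, what = "weights")
  if (any(w < 0)) stop_invalid("weights must be nonnegative")
  pos <- w > 0
  diag(pos) <- FALSE
  vals <- log(w[upper.tri(w) & pos])
  if (length(vals) < 2) stop_invalid("need at least 2 positive edges to z-score")
  mu <- mean(vals)
  sigma <- if (convention == "population") {
    sqrt(mean((vals - mu)^2))
  } else {
    sd(vals)
  }
  if (sigma == 0) {
    abort("degenerate input: all positive log-weights identical",
      class = "geonull_degenerate_input"
    )
  }
  Z <- matrix(NA_real_, nrow(w), ncol(w), dimnames = dimnames(w))
  Z[pos] <- (log(w[pos]) - mu) / sigma
  Z
}

#' Binned weight-distance profile
#'
#' Mean and SD (population convention, matching the global z-scoring) of
#' z-scored log-weights within fiber-distance bins of fixed width
#' (1 mm by default). Bins with no edges are dropped; bins with one edge
#' have `NA` SD.
#'
#' @param z Z-score matrix from [zscore_log_weights()].
#' @param f Fiber-distance matrix, mm.
#' @param width Bin width, mm.
#' @return A tibble of class `binned_profile`: `bin`, `bin_lo`, `bin_hi`,
#'   `mean`, `sd`, `n`.
#' @export
binned_weight_profile <- function(z, f, width = 1) {
  if (!all(dim(z) == dim(f))) stop_invalid("z/f shape mismatch")
  if (width <= 0) stop_invalid("bin width must be positive")
  up <- upper.tri(z)
  use <- up & !is.na(z)
  zz <- z[use]
  ff <- f[use]
  bin <- floor(ff / width)
  prof <- tibble(bin = bin, z = zz, f = ff) |>
    group_by(.data$bin) |>
    summarise(
      mean = mean(.data$z),
      sd = if (n() >= 2) sqrt(mean((.data$z - mean(.data$z))^2)) else NA_real_,
      n = n(),
      .groups = "drop"
    ) |>
    arrange(.data$bin) |>
    mutate(
      bin_lo = .data$bin * width, bin_hi = (.data$bin + 1) * width,
      bin = .data$bin + 1L
    ) |>
    select("bin", "bin_lo", "bin_hi", "mean", "sd", "n")
  class(prof) <- c("binned_profile", class(prof))
  attr(prof, "width") <- width
  prof
}

#' Compare replicate profiles against a reference profile
#'
#' Per-bin one-sample t-test of the replicate bin means against the
#' reference bin mean, corrected for multiple comparisons across tested
#' bins (Bonferroni by default). Bins are tested only where the reference
#' is defined and at least two replicates contribute.
#'
#' @param profiles List of >= 2 replicate `binned_profile`s (e.g. one per
#'   dataset).
#' @param reference Reference `binned_profile`.
#' @param alpha Corrected significance level (default 0.01).
#' @param method Multiplicity correction passed to [stats::p.adjust()]
#'   ("bonferroni" default, "BH" available).
#' @param value Which profile curve to compare: bin means or bin SDs.
#' @return Tibble: `bin_lo`, `bin_hi`, `reference`, `replicate_mean`,
#'   `n_replicates`, `statistic`, `p_value`, `p_adjusted`, `significant`.
#' @export
compare_profiles <- function(profiles, reference, alpha = 0.01,
                             method = "bonferroni",
                             value = c("mean", "sd")) {
  value <- match.arg(value)
  if (length(profiles) < 2) {
    abort("need at least 2 replicate profiles",
      class = "geonull_insufficient_replicates"
    )
  }
  reps <- bind_rows(lapply(seq_along(profiles), function(i) {
    mutate(as_tibble(profiles[[i]]), replicate = i)
  }))
  ref <- as_tibble(reference) |>
    select("bin_lo", "bin_hi", reference = dplyr::all_of(value))
  tested <- reps |>
    rename(value = dplyr::all_of(value)) |>
    filter(!is.na(.data$value)) |>
    group_by(.data$bin_lo, .data$bin_hi) |>
    summarise(
      replicate_mean = mean(.data$value),
      replicate_sd = sd(.data$value),
      n_replicates = n(),
      .groups = "drop"
    ) |>
    filter(.data$n_replicates >= 2) |>
    left_join(ref, by = c("bin_lo", "bin_hi")) |>
    filter(!is.na(.data$reference))
  tested <- tested |>
    mutate(
      # zero replicate variance: statistic is 0 when the means agree,
      # +/- Inf otherwise (p of 1 resp. 0)
      statistic = dplyr::case_when(
        .data$replicate_sd > 0 ~ (.data$replicate_mean - .data$reference) /
          (.data$replicate_sd / sqrt(.data$n_replicates)),
        .data$replicate_mean == .data$reference ~ 0,
        TRUE ~ Inf * sign(.data$replicate_mean - .data$reference)
      ),
      p_value = 2 * stats::pt(-abs(.data$statistic), df = .data$n_replicates - 1),
      p_adjusted = p.adjust(.data$p_value, method = method),
      significant = .data$p_adjusted < alpha
    ) |>
    select(
      "bin_lo", "bin_hi", "reference", "replicate_mean", "n_replicates",
      "statistic", "p_value", "p_adjusted", "significant"
    )
  tested
}

#' Identify hub nodes from a centrality vector
#'
#' Hubs are the `round(fraction * N)` nodes with the largest centrality
#' (top 15% by default); the remaining nodes are "feeders". Ties at the
#' threshold resolve by index order, with a warning.
#'
#' @param centrality Numeric centrality vector (strength, eigenvector, ...).
#' @param fraction Hub fraction of nodes, default 0.15.
#' @param measure Optional label recording which centrality was used.
#' @return A `hub_set`: list with `indices`, `fraction`, `measure`,
#'   `threshold_value`.
#' @export
identify_hubs <- function(centrality, fraction = 0.15, measure = "strength") {
  if (fraction < 0 || fraction > 1) stop_invalid("fraction must be in [0, 1]")
  n <- length(centrality)
  k <- round(fraction * n)
  ord <- order(-centrality, seq_len(n))
  idx <- sort(ord[seq_len(k)])
  thr <- if (k > 0) centrality[ord[k]] else Inf
  if (k > 0 && k < n && centrality[ord[k + 1]] == thr) {
    warn("centrality ties at the hub threshold; resolved by index order")
  }
  structure(
    list(
      indices = idx, fraction = fraction, measure = measure,
      threshold_value = thr
    ),
    class = "hub_set"
  )
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf(
    "<hub_set> %d hubs (top %.0f%% by %s, threshold %.4g)\n",
    length(x$indices), 100 * x$fraction, x$measure, x$threshold_value
  ))
  invisible(x)
}

#' Distances from nodes to the brain center of mass
#'
#' Euclidean distance from each selected node to the volume-weighted mean
#' of all node coordinates (set `weighted = FALSE` for the unweighted
#' centroid).
#'
#' @param coords N x 3 coordinate matrix, mm.
#' @param volumes Node volumes used as center-of-mass weights.
#' @param subset Node indices to measure (or a `hub_set`); default all.
#' @param weighted Volume-weight the center of mass (default `TRUE`).
#' @return Numeric vector of distances, mm, one per subset node.
#' @export
com_distances <- function(coords, volumes, subset = NULL, weighted = TRUE) {
  coords <- as.matrix(coords)
  if (inherits(subset, "hub_set")) subset <- subset$indices
  if (is.null(subset)) subset <- seq_len(nrow(coords))
  if (length(subset) == 0) stop_invalid("subset must be nonempty")
  wts <- if (weighted) volumes else rep(1, nrow(coords))
  com <- colSums(coords * wts) / sum(wts)
  sqrt(colSums((t(coords[subset, , drop = FALSE]) - com)^2))
}

#' Mean fiber distance to each node's neighbors
#'
#' Weight-weighted average fiber distance,
#' `<D>_i = sum_j w_ij f_ij / sum_j w_ij`. Low values mark geometrically
#' central nodes. For near-fully-connected graphs the weighting is
#' essential (an unweighted mean over neighbors is almost constant);
#' `weighted = FALSE` gives the plain mean over positive-weight neighbors.
#'
#' @param w Symmetric nonnegative weight matrix (or [spatial_graph()]).
#' @param f Fiber-distance matrix, mm.
#' @param weighted Weight-average (default) or plain mean over neighbors.
#' @return Numeric vector, mm; `NA` for zero-strength nodes.
#' @export
mean_neighbor_fiber_distance <- function(w, f = NULL, weighted = TRUE) {
  if (inherits(w, "spatial_graph")) {
    f <- w$fiber_distances
    w <- w$weights
  }
  check_symmetric(w, what = "weights")
  if (!all(dim(w) == dim(f))) stop_invalid("weight/distance shape mismatch")
  s <- rowSums(w)
  out <- if (weighted) {
    rowSums(w * f) / s
  } else {
    rowSums((w > 0) * f) / rowSums(w > 0)
  }
  out[s == 0] <- NA_real_
  out
}

#' Normalize an empirical metric by a surrogate ensemble
#'
#' The ratio `empirical / mean(ensemble)`: 1 indicates the metric is fully
#' explained by what the ensemble preserves (for geometric surrogates,
#' spatial embedding alone).
#'
#' @param empirical Scalar empirical metric value.
#' @param ensemble_values Numeric vector of surrogate metric values.
#' @return Scalar ratio.
#' @export
normalized_metric_ratio <- function(empirical, ensemble_values) {
  m <- mean(ensemble_values)
  if (!is.finite(m) || m == 0) stop_invalid("ensemble mean must be nonzero")
  empirical / m
}

#' Percent of total hub strength per brain division
#'
#' For each division label, the percent of summed hub-node strength it
#' contains; percentages sum to 100 over all divisions.
#'
#' @param strengths Node strength vector.
#' @param hubs A `hub_set` (or integer node indices).
#' @param division Per-node division labels.
#' @return Tibble: `division`, `hub_strength`, `percent`, sorted by
#'   decreasing percent.
#' @export
hub_strength_by_division <- function(strengths, hubs, division) {
  idx <- if (inherits(hubs, "hub_set")) hubs$indices else as.integer(hubs)
  if (length(idx) == 0) stop_invalid("hub set is empty")
  tot <- sum(strengths[idx])
  tibble(division = division[idx], strength = unname(strengths[idx])) |>
    group_by(.data$division) |>
    summarise(hub_strength = sum(.data$strength), .groups = "drop") |>
    mutate(percent = 100 * .data$hub_strength / tot) |>
    arrange(desc(.data$percent))
}
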