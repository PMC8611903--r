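# Statistical machinery: rank/linear correlations (overall and by brain
# division), Tukey's range test, permutation test.

#' Spearman rank correlation
#'
#' Average-rank handling of ties; pairs with missing values are dropped.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Scalar rho.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  cor(x[ok], y[ok], method = "spearman")
}

#' Pearson product-moment correlation
#'
#' @inheritParams spearman_rho
#' @return Scalar r.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  cor(x[ok], y[ok], method = "pearson")
}

#' Edge-weight agreement between two graphs, by division pair
#'
#' Spearman correlation of edge weights restricted to edges whose
#' endpoints lie in a given pair of major brain divisions, separated into
#' ipsilateral and contralateral edges; plus the overall correlation.
#' Edges positive in either graph contribute.
#'
#' @param wa,wb Weight matrices over the same parcellation.
#' @param division Per-node division labels.
#' @param hemisphere Per-node "L"/"R" labels.
#' @return Tibble: `division_a`, `division_b`, `laterality`, `rho`,
#'   `n_edges`; the overall correlation appears as division pair
#'   `"all"/"all"`.
#' @export
division_weight_agreement <- function(wa, wb, division, hemisphere) {
  check_symmetric(wa, what = "weights A")
  check_symmetric(wb, what = "weights B")
  if (!all(dim(wa) == dim(wb))) stop_invalid("weight matrices differ in size")
  iu <- which(upper.tri(wa), arr.ind = TRUE)
  keep <- wa[iu] > 0 | wb[iu] > 0
  iu <- iu[keep, , drop = FALSE]
  da <- division[iu[, 1]]
  db <- division[iu[, 2]]
  lo <- pmin(da, db)
  hi <- pmax(da, db)
  lat <- ifelse(hemisphere[iu[, 1]] == hemisphere[iu[, 2]], "ipsi", "contra")
  xa <- wa[iu]
  xb <- wb[iu]
  per_div <- tibble(
    division_a = lo, division_b = hi, laterality = lat,
    xa = xa, xb = xb
  ) |>
    group_by(.data$division_a, .data$division_b, .data$laterality) |>
    summarise(
      rho = if (n() >= 3) spearman_rho(.data$xa, .data$xb) else NA_real_,
      n_edges = n(),
      .groups = "drop"
    )
  overall <- tibble(
    division_a = "all", division_b = "all", laterality = "both",
    rho = spearman_rho(xa, xb), n_edges = length(xa)
  )
  bind_rows(overall, per_div)
}

#' Tukey's range test across groups
#'
#' Pairwise comparisons of group means via the studentized range
#' distribution (Tukey HSD on a one-way layout).
#'
#' @param groups Named list of numeric vectors, one per group.
#' @return Tibble: `comparison`, `estimate` (difference of means),
#'   `conf_low`, `conf_high`, `p_value`.
#' @export
tukey_range_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop_invalid("need a list of at least 2 groups")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  dat <- dat[is.finite(dat$value), ]
  fit <- aov(value ~ group, data = dat)
  tk <- TukeyHSD(fit)$group
  tibble(
    comparison = rownames(tk),
    estimate = tk[, "diff"],
    conf_low = tk[, "lwr"],
    conf_high = tk[, "upr"],
    p_value = tk[, "p adj"]
  )
}

#' Two-sample permutation test
#'
#' Permutes group labels `n_perm` times and compares the absolute observed
#' statistic (difference of means by default) with the permutation
#' distribution: `p = (1 + #{|t*| >= |t|}) / (1 + n_perm)`. Deterministic
#' per seed.
#'
#' @param a,b Numeric samples.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param statistic Function of two samples returning a scalar.
#' @return One-row tibble: `statistic`, `p_value`, `n_perm`.
#' @export
permutation_test <- function(a, b, n_perm = 999, seed = 1L,
                             statistic = function(x, y) mean(x) - mean(y)) {
  if (length(a) == 0 || length(b) == 0) stop_invalid("samples must be nonempty")
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")
  obs <- statistic(a, b)
  pooled <- c(a, b)
  na <- length(a)
  exceed <- with_seed(as.integer(seed), {
    sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), na)
      abs(statistic(pooled[idx], pooled[-idx])) >= abs(obs)
    }, logical(1)))
  })
  tibble(
    statistic = obs,
    p_value = (1 + exceed) / (1 + n_perm),
    n_perm = as.integer(n_perm)
  )
}
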