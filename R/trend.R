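#' Fit the low-order weight-distance trend of a connectome
#'
#' Fits the natural-log edge weights of the upper-triangle positive edges to
#' a cubic polynomial in fiber distance, `log w ~ g(f)`, and then a parabola
#' `h(f)` to the absolute residuals, modelling the heteroscedastic spread of
#' log-weights around the trend. `g` and `h` are the two transformations
#' used to detrend weights before shuffling when building geometric
#' surrogates. Zero-weight pairs are excluded (their count is recorded).
#'
#' The spread curve is floored at `spread_floor` = 1e-6 of the median fitted
#' spread so that detrending never divides by a vanishing or negative value.
#'
#' @param w Symmetric nonnegative weight matrix (or a [spatial_graph()]).
#' @param f Symmetric fiber-distance matrix, mm. Ignored when `w` is a
#'   spatial graph.
#' @return A `trend_model`: cubic coefficients of `g` (increasing powers of
#'   distance), parabola coefficients of `h`, spread floor, edge counts and
#'   fit summaries.
#' @export
fit_trend <- function(w, f = NULL) {
  if (inherits(w, "spatial_graph")) {
    f <- w$fiber_distances
    w <- w$weights
  }
  check_symmetric(w, what = "weights")
  check_symmetric(f, what = "fiber_distances")
  if (any(w < 0)) stop_invalid("weights must be nonnegative")
  up <- upper.tri(w)
  pos <- up & w > 0
  n_pos <- sum(pos)
  n_zero <- sum(up) - n_pos
  if (n_pos < 10) {
    abort(
      sprintf("need at least 10 positive edges to fit the trend, have %d", n_pos),
      class = "geonull_insufficient_data"
    )
  }
  lw <- log(w[pos])
  fd <- f[pos]
  g_fit <- lm(lw ~ fd + I(fd^2) + I(fd^3))
  res <- lw - predict(g_fit)
  h_fit <- lm(abs(res) ~ fd + I(fd^2))
  spread_hat <- predict(h_fit)
  structure(
    list(
      cubic_coeffs = unname(coef(g_fit)),
      spread_coeffs = unname(coef(h_fit)),
      # relative floor, plus an absolute one: a spread below 1e-6 log-units
      # is numerically meaningless and would blow up detrended residuals
      spread_floor = max(1e-6 * median(spread_hat), 1e-6),
      n_edges_fit = n_pos,
      excluded_zero_edges = n_zero,
      distance_range = range(fd),
      residual_mean = mean(res),
      residual_sd = sd(res)
    ),
    class = "trend_model"
  )
}

eval_poly <- function(coeffs, x) {
  out <- 0
  for (k in rev(seq_along(coeffs))) out <- out * x + coeffs[k]
  out
}

#' Evaluate the fitted log-weight trend g(f)
#' @param model A `trend_model`.
#' @param f Fiber distances, mm.
#' @return Predicted mean log-weight at each distance.
#' @export
predict_trend <- function(model, f) {
  stopifnot(inherits(model, "trend_model"))
  eval_poly(model$cubic_coeffs, f)
}

#' Evaluate the fitted residual-spread curve h(f), floored
#' @inheritParams predict_trend
#' @return Predicted spread, never below the model's floor.
#' @export
predict_spread <- function(model, f) {
  stopifnot(inherits(model, "trend_model"))
  pmax(eval_poly(model$spread_coeffs, f), model$spread_floor)
}

#' @export
print.trend_model <- function(x, ...) {
  cat(sprintf(
    "<trend_model> cubic g over %d edges (%d zero pairs excluded)\n",
    x$n_edges_fit, x$excluded_zero_edges
  ))
  cat(
    "  g coeffs:", format(x$cubic_coeffs, digits = 4),
    "\n  h coeffs:", format(x$spread_coeffs, digits = 4), "\n"
  )
  invisible(x)
}

#' @method tidy trend_model
#' @export
tidy.trend_model <- function(x, ...) {
  tibble(
    curve = c(rep("trend", 4), rep("spread", 3)),
    term = c(paste0("f^", 0:3), paste0("f^", 0:2)),
    estimate = c(x$cubic_coeffs, x$spread_coeffs)
  )
}

#' @method glance trend_model
#' @export
glance.trend_model <- function(x, ...) {
  tibble(
    n_edges_fit = x$n_edges_fit,
    excluded_zero_edges = x$excluded_zero_edges,
    residual_mean = x$residual_mean,
    residual_sd = x$residual_sd,
    distance_min = x$distance_range[1],
    distance_max = x$distance_range[2]
  )
}

#' Remove the fitted weight-distance trend from a weight matrix
#'
#' Transforms each positive edge to
#' `r_ij = (log w_ij - g(f_ij)) / max(h(f_ij), floor)`: the normalized residual once the
#' cubic trend and the heteroscedastic spread have been divided out. The
#' residuals carry essentially zero rank or linear correlation with distance
#' and are the quantity shuffled when building geometric surrogates.
#'
#' @inheritParams fit_trend
#' @param model A `trend_model` from [fit_trend()].
#' @return Symmetric residual matrix; zero-weight pairs and the diagonal are
#'   `NA` (missing marker).
#' @export
detrend_weights <- function(w, f, model) {
  if (inherits(w, "spatial_graph")) {
    f <- w$fiber_distances
    w <- w$weights
  }
  stopifnot(inherits(model, "trend_model"))
  check_symmetric(w, what = "weights")
  if (any(w < 0)) stop_invalid("weights must be nonnegative")
  if (!all(dim(w) == dim(f))) stop_invalid("weight/distance shape mismatch")
  R <- matrix(NA_real_, nrow(w), ncol(w), dimnames = dimnames(w))
  pos <- w > 0
  diag(pos) <- FALSE
  R[pos] <- (log(w[pos]) - predict_trend(model, f[pos])) /
    predict_spread(model, f[pos])
  R
}

#' Reimpose the weight-distance trend on detrended residuals
#'
#' Exact algebraic inverse of [detrend_weights()] on positive edges:
#' `log w = g(f) + max(h(f), floor) * r`.
#'
#' @param r Residual matrix from [detrend_weights()] (NA marks zero pairs).
#' @param f Fiber-distance matrix, mm.
#' @param model The `trend_model` used to detrend.
#' @return Log-weight matrix; `-Inf` at zero-weight pairs and the diagonal.
#' @export
retrend_weights <- function(r, f, model) {
  stopifnot(inherits(model, "trend_model"))
  if (!all(dim(r) == dim(f))) stop_invalid("residual/distance shape mismatch")
  lw <- matrix(-Inf, nrow(r), ncol(r), dimnames = dimnames(r))
  pos <- !is.na(r)
  diag(pos) <- FALSE
  lw[pos] <- predict_trend(model, f[pos]) + predict_spread(model, f[pos]) * r[pos]
  lw
}
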