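# Geometric and random surrogate construction.
#
# A geometric surrogate preserves (i) the empirical weight multiset mapped
# through rank order onto distance-respecting positions and (ii) the node
# strength sequence, while destroying all other topology. A random
# surrogate preserves the strength sequence only.

#' Restore a target node-strength sequence by symmetric scaling sweeps
#'
#' Iteratively rescales a symmetric nonnegative matrix so that each row/
#' column sum approaches its target: per sweep,
#' `w[i,j] <- w[i,j] * sqrt((t_i/s_i) * (t_j/s_j))` where `s` are the current
#' strengths. The geometric-mean update preserves symmetry and
#' nonnegativity by construction. Convergence is declared when the largest
#' relative strength deviation drops to `tol`; otherwise the result is
#' flagged (never silently truncated).
#'
#' With `match = "nodewise"` (the default here) each node is driven to its
#' own target strength. With `match = "distribution"` (how surrogate
#' graphs are restored by default) the sorted targets are first assigned
#' to nodes by the rank of their current strength — the strength
#' distribution is restored, but which node carries which strength remains
#' the matrix's own (geometry-driven) outcome, so hub identities can move.
#'
#' @param w Symmetric nonnegative matrix with zero diagonal.
#' @param target_strengths Strictly positive length-N vector.
#' @param tol Relative strength tolerance (default 1e-3).
#' @param max_iter Maximum sweeps (default 1000).
#' @param match Drive each node to its own target ("nodewise", default)
#'   or assign the sorted targets by current strength rank
#'   ("distribution").
#' @return The rescaled matrix with attributes `iterations`,
#'   `strength_error` (final max relative deviation) and `converged`.
#' @export
restore_strength_sequence <- function(w, target_strengths, tol = 1e-3,
                                      max_iter = 1000,
                                      match = c("nodewise", "distribution")) {
  match <- match.arg(match)
  check_symmetric(w, what = "weights")
  if (any(w < 0)) stop_invalid("weights must be nonnegative")
  n <- nrow(w)
  if (length(target_strengths) != n || any(target_strengths <= 0)) {
    stop_invalid("target_strengths must be strictly positive, one per node")
  }
  if (match == "distribution") {
    target_strengths <- sort(target_strengths)[rank(rowSums(w), ties.method = "first")]
  }
  err_of <- function(m) max(abs(rowSums(m) - target_strengths) / target_strengths)
  iter <- 0L
  err <- err_of(w)
  while (err > tol && iter < max_iter) {
    s <- rowSums(w)
    if (any(s == 0)) break # isolated node with positive target: cannot converge
    ratio <- sqrt(target_strengths / s)
    w <- w * outer(ratio, ratio)
    diag(w) <- 0
    iter <- iter + 1L
    err <- err_of(w)
  }
  structure(w,
    iterations = iter, strength_error = err, converged = err <= tol
  )
}

surrogate_core <- function(w, positions, values, target_strengths, tol,
                           max_iter, seed, restore_strengths,
                           strength_match = "distribution") {
  n <- nrow(w)
  out <- matrix(0, n, n, dimnames = dimnames(w))
  out[positions] <- values
  out <- out + t(out)
  if (restore_strengths) {
    out <- restore_strength_sequence(out, target_strengths,
      tol = tol, max_iter = max_iter, match = strength_match
    )
  } else {
    out <- structure(out, iterations = 0L, strength_error = NA_real_, converged = NA)
  }
  attr(out, "seed") <- seed
  out
}

#' Build one geometric surrogate graph
#'
#' Pipeline: detrend the log-weights with the fitted cubic trend `g` and
#' spread curve `h`; shuffle the normalized residuals uniformly at random
#' over the positive upper-triangle positions (then mirror); retrend;
#' replace the surrogate weights by the original weight multiset mapped
#' through rank order (largest original weight onto the largest surrogate
#' position); finally restore the empirical node-strength sequence. The
#' result preserves the empirical low-order weight-distance relationship
#' and strength sequence but is otherwise random. Zero-weight pairs stay
#' zero.
#'
#' @param w Symmetric nonnegative weight matrix (or [spatial_graph()]).
#' @param f Fiber-distance matrix (ignored when `w` is a spatial graph).
#' @param seed Integer seed; the surrogate is a pure function of
#'   (inputs, seed).
#' @param tol,max_iter Strength-restoration controls
#'   (see [restore_strength_sequence()]).
#' @param model Optional pre-fitted `trend_model` (refit otherwise).
#' @param restore_strengths Set `FALSE` to return the pre-restoration
#'   surrogate, whose weight multiset is exactly the empirical one.
#' @param strength_match Restore the sorted strength distribution by
#'   surrogate rank ("distribution", default; hub identities stay free) or
#'   drive each node to its own empirical strength ("nodewise"). See
#'   [restore_strength_sequence()].
#' @return Surrogate weight matrix with attributes `seed`, `iterations`,
#'   `strength_error`, `converged`.
#' @export
geometric_surrogate <- function(w, f = NULL, seed = 1L, tol = 1e-3,
                                max_iter = 1000, model = NULL,
                                restore_strengths = TRUE,
                                strength_match = c("distribution", "nodewise")) {
  strength_match <- match.arg(strength_match)
  if (inherits(w, "spatial_graph")) {
    f <- w$fiber_distances
    w <- w$weights
  }
  check_symmetric(w, what = "weights")
  pos <- which(upper.tri(w) & w > 0)
  if (length(pos) < 2) {
    return(structure(w,
      seed = seed, iterations = 0L, strength_error = 0, converged = TRUE
    ))
  }
  if (is.null(model)) model <- fit_trend(w, f)
  R <- detrend_weights(w, f, model)
  resid_vals <- R[pos]
  perm <- with_seed(as.integer(seed), sample.int(length(pos)))
  Rs <- matrix(NA_real_, nrow(w), ncol(w))
  Rs[pos] <- resid_vals[perm]
  Rs[lower.tri(Rs)] <- t(Rs)[lower.tri(Rs)]
  lw <- retrend_weights(Rs, f, model)
  surr_vals <- lw[pos]
  # rank-map the original weight multiset onto the surrogate rank order
  mapped <- numeric(length(pos))
  mapped[order(surr_vals)] <- sort(w[pos])
  surrogate_core(w, pos, mapped, rowSums(w), tol, max_iter, seed,
    restore_strengths, strength_match
  )
}

#' Build one random (strength-preserving) surrogate graph
#'
#' Shuffles the empirical weights uniformly at random over the positive
#' upper-triangle positions and restores the empirical node-strength
#' sequence. No distance structure is imposed: only the strength sequence
#' (and node locations) survive.
#'
#' @inheritParams geometric_surrogate
#' @return Surrogate weight matrix with diagnostics attributes.
#' @export
random_surrogate <- function(w, seed = 1L, tol = 1e-3, max_iter = 1000,
                             restore_strengths = TRUE,
                             strength_match = c("distribution", "nodewise")) {
  strength_match <- match.arg(strength_match)
  if (inherits(w, "spatial_graph")) w <- w$weights
  check_symmetric(w, what = "weights")
  pos <- which(upper.tri(w) & w > 0)
  if (length(pos) < 2) {
    return(structure(w,
      seed = seed, iterations = 0L, strength_error = 0, converged = TRUE
    ))
  }
  perm <- with_seed(as.integer(seed), sample.int(length(pos)))
  surrogate_core(w, pos, w[pos][perm], rowSums(w), tol, max_iter, seed,
    restore_strengths, strength_match
  )
}

#' Build a surrogate ensemble
#'
#' Generates `n` geometric or random surrogates with per-surrogate seeds
#' `base_seed, base_seed + 1, ...`, recording convergence diagnostics. For
#' geometric ensembles the trend model is fitted once and shared.
#'
#' @inheritParams geometric_surrogate
#' @param n Ensemble size (>= 1); 100 is the conventional choice.
#' @param kind "geometric" or "random".
#' @param base_seed First surrogate seed.
#' @return A `surrogate_ensemble`: list with `kind`, `matrices`, `seeds`,
#'   `strength_error`, `iterations_used`, `converged`, and the shared
#'   `model` (geometric only). Non-convergence is flagged per surrogate,
#'   never raised as an error.
#' @export
build_ensemble <- function(w, f = NULL, n = 100, kind = c("geometric", "random"),
                           base_seed = 1L, tol = 1e-3, max_iter = 1000,
                           model = NULL,
                           strength_match = c("distribution", "nodewise")) {
  kind <- match.arg(kind)
  strength_match <- match.arg(strength_match)
  if (inherits(w, "spatial_graph")) {
    f <- w$fiber_distances
    w <- w$weights
  }
  if (!is.numeric(n) || n < 1) stop_invalid("ensemble size n must be >= 1")
  n <- as.integer(n)
  if (kind == "geometric" && is.null(model)) model <- fit_trend(w, f)
  seeds <- as.integer(base_seed) + seq_len(n) - 1L
  mats <- lapply(seeds, function(s) {
    if (kind == "geometric") {
      geometric_surrogate(w, f,
        seed = s, tol = tol, max_iter = max_iter,
        model = model, strength_match = strength_match
      )
    } else {
      random_surrogate(w,
        seed = s, tol = tol, max_iter = max_iter,
        strength_match = strength_match
      )
    }
  })
  structure(
    list(
      kind = kind,
      matrices = lapply(mats, function(m) {
        attributes(m)[c("seed", "iterations", "strength_error", "converged")] <- NULL
        m
      }),
      seeds = seeds,
      strength_error = map_dbl(mats, ~ attr(.x, "strength_error")),
      iterations_used = map_int(mats, ~ attr(.x, "iterations")),
      converged = map_lgl(mats, ~ isTRUE(attr(.x, "converged"))),
      tol = tol,
      model = model
    ),
    class = "surrogate_ensemble"
  )
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf(
    "<surrogate_ensemble> %d %s surrogates (%d x %d), %d converged at tol %g\n",
    length(x$matrices), x$kind, nrow(x$matrices[[1]]), ncol(x$matrices[[1]]),
    sum(x$converged), x$tol
  ))
  invisible(x)
}

#' @method tidy surrogate_ensemble
#' @export
tidy.surrogate_ensemble <- function(x, ...) {
  tibble(
    surrogate = seq_along(x$seeds),
    kind = x$kind,
    seed = x$seeds,
    iterations = x$iterations_used,
    strength_error = x$strength_error,
    converged = x$converged
  )
}

#' @method glance surrogate_ensemble
#' @export
glance.surrogate_ensemble <- function(x, ...) {
  tibble(
    kind = x$kind,
    n = length(x$matrices),
    n_converged = sum(x$converged),
    max_strength_error = max(x$strength_error),
    mean_iterations = mean(x$iterations_used)
  )
}

#' Summarise an ensemble with a metric function
#'
#' @param ensemble A `surrogate_ensemble`.
#' @param metric Function taking a weight matrix and returning a scalar.
#' @return Numeric vector of per-surrogate metric values.
#' @export
ensemble_metric <- function(ensemble, metric) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  map_dbl(ensemble$matrices, metric)
}
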