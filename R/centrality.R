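# Node centralities: strength, eigenvector, participation.

#' Node strengths
#'
#' Sum of edge weights incident to each node (the weighted degree).
#'
#' @param w Symmetric nonnegative weight matrix (or [spatial_graph()]).
#' @return Named numeric vector of strengths.
#' @export
node_strengths <- function(w) {
  if (inherits(w, "spatial_graph")) w <- w$weights
  check_symmetric(w, what = "weights")
  rowSums(w)
}

#' Eigenvector centrality
#'
#' Elements of the leading eigenvector of the weight matrix, computed by
#' power iteration to a relative tolerance of 1e-10, sign-fixed positive
#' and normalized to unit Euclidean norm. If the positive support is
#' disconnected, the largest connected component is scored (others get 0)
#' with a warning. Invariant under uniform weight rescaling.
#'
#' @param w Symmetric nonnegative weight matrix (or [spatial_graph()]).
#' @param tol Power-iteration convergence tolerance.
#' @param max_iter Iteration cap.
#' @return Named numeric vector, nonnegative, unit norm.
#' @export
eigenvector_centrality <- function(w, tol = 1e-10, max_iter = 100000) {
  if (inherits(w, "spatial_graph")) w <- w$weights
  check_symmetric(w, what = "weights")
  if (all(w == 0)) {
    abort("eigenvector centrality undefined for an all-zero matrix",
      class = "geonull_undefined_metric"
    )
  }
  n <- nrow(w)
  g <- graph_from_adjacency_matrix(w > 0, mode = "undirected", diag = FALSE)
  comp <- components(g)
  keep <- seq_len(n)
  if (comp$no > 1) {
    # isolated or minor-component nodes cannot carry centrality mass
    main <- which.max(comp$csize)
    keep <- which(comp$membership == main)
    warn(sprintf(
      "positive support is disconnected; scoring the largest component (%d of %d nodes)",
      length(keep), n
    ))
  }
  ws <- w[keep, keep, drop = FALSE]
  v <- rep(1 / sqrt(length(keep)), length(keep))
  # spectral shift keeps the Perron eigenvalue strictly dominant in
  # magnitude (bipartite supports otherwise make the iteration oscillate)
  mu <- max(rowSums(ws))
  for (i in seq_len(max_iter)) {
    nv <- as.vector(ws %*% v) + mu * v
    nrm <- sqrt(sum(nv^2))
    nv <- nv / nrm
    if (max(abs(nv - v)) < tol) {
      v <- nv
      break
    }
    v <- nv
  }
  out <- numeric(n)
  out[keep] <- abs(v)
  out <- out / sqrt(sum(out^2))
  names(out) <- rownames(w)
  out
}

#' Participation coefficients
#'
#' Diversity of a node's intermodular connectivity for a given module
#' partition: `P_i = 1 - sum_m (k_im / k_i)^2` where `k_im` is the weight
#' from node `i` to module `m` and `k_i` its strength. 0 means all weight
#' stays within the node's own module; a node spreading weight uniformly
#' over all `M` modules approaches `1 - 1/M`. Zero-strength nodes score 0
#' (their count is attached as attribute `n_zero_strength`).
#'
#' @param w Symmetric nonnegative weight matrix.
#' @param partition `module_partition` or membership vector.
#' @return Named numeric vector in \[0, 1); attribute `n_zero_strength`.
#' @export
participation_coefficients <- function(w, partition) {
  if (inherits(w, "spatial_graph")) w <- w$weights
  check_symmetric(w, what = "weights")
  memb <- as_membership_vec(partition, nrow(w))
  s <- rowSums(w)
  mods <- sort(unique(memb))
  km <- vapply(mods, function(m) {
    rowSums(w[, memb == m, drop = FALSE])
  }, numeric(nrow(w)))
  p <- numeric(nrow(w))
  okay <- s > 0
  p[okay] <- 1 - rowSums((km[okay, , drop = FALSE] / s[okay])^2)
  n_zero <- sum(!okay)
  if (n_zero > 0) {
    warn(sprintf("%d zero-strength node(s) assigned participation 0", n_zero))
  }
  names(p) <- rownames(w)
  structure(p, n_zero_strength = n_zero)
}

#' Tidy per-node centrality table
#'
#' Gathers strength, eigenvector centrality and (given a partition)
#' participation coefficient into one tibble, the hub-analysis input.
#'
#' @param graph A [spatial_graph()] or weight matrix.
#' @param partition Optional partition for participation coefficients.
#' @return Tibble: node, region_id (if available), strength, eigenvector,
#'   participation.
#' @export
node_centralities <- function(graph, partition = NULL) {
  w <- if (inherits(graph, "spatial_graph")) graph$weights else graph
  out <- tibble(
    node = seq_len(nrow(w)),
    region_id = rownames(w) %||% as.character(seq_len(nrow(w))),
    strength = unname(node_strengths(w)),
    eigenvector = unname(eigenvector_centrality(w))
  )
  if (!is.null(partition)) {
    out$participation <- unname(as.numeric(participation_coefficients(w, partition)))
  }
  out
}
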