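#' Spatially embedded weighted network
#'
#' Container for a weighted symmetric connectome together with its spatial
#' embedding: per-node coordinates (mm, RAS convention), region volumes
#' (mm^3), hemisphere and major-division labels, homologous-region pairing,
#' and a pairwise fiber-distance matrix (mm).
#'
#' Invariants enforced at construction: `weights` symmetric with zero
#' diagonal; `fiber_distances` symmetric, zero diagonal, strictly positive
#' off-diagonal wherever a weight is positive, and never more than `1e-6`
#' below the Euclidean inter-node distance; `homolog` an involution mapping
#' left to right hemisphere regions; all components of matching length.
#'
#' @param weights N x N nonnegative symmetric matrix. Units are
#'   modality-specific (normalized connection density or volume-normalized
#'   streamline count); only ratios and ranks of weights matter downstream.
#' @param fiber_distances N x N symmetric matrix of fiber (pathway) lengths
#'   in mm.
#' @param coordinates N x 3 matrix of region center-of-mass coordinates, mm.
#' @param volumes length-N positive vector of region volumes, mm^3.
#' @param region_ids length-N character vector of unique region identifiers.
#' @param hemisphere length-N vector of "L"/"R" labels.
#' @param division length-N character vector of major brain division labels.
#' @param homolog length-N integer vector pairing each region with its
#'   mirror-hemisphere homolog.
#' @return An object of class `spatial_graph`.
#' @export
spatial_graph <- function(weights, fiber_distances, coordinates, volumes,
                          region_ids, hemisphere, division, homolog) {
  check_symmetric(weights, what = "weights")
  check_symmetric(fiber_distances, what = "fiber_distances")
  n <- nrow(weights)
  if (any(weights < 0)) stop_invalid("weights must be nonnegative")
  if (any(diag(weights) != 0)) stop_invalid("weights must have a zero diagonal")
  if (any(diag(fiber_distances) != 0)) {
    stop_invalid("fiber_distances must have a zero diagonal")
  }
  if (nrow(fiber_distances) != n) stop_invalid("fiber_distances dimension mismatch")
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) != n || ncol(coordinates) != 3) {
    stop_invalid("coordinates must be an N x 3 matrix")
  }
  if (length(volumes) != n || any(volumes <= 0)) {
    stop_invalid("volumes must be length N and strictly positive")
  }
  if (length(region_ids) != n || anyDuplicated(region_ids)) {
    stop_invalid("region_ids must be length N and unique")
  }
  if (length(hemisphere) != n || !all(hemisphere %in% c("L", "R"))) {
    stop_invalid("hemisphere labels must be 'L' or 'R'")
  }
  if (length(division) != n) stop_invalid("division labels must be length N")
  check_involution(homolog, n)
  if (any(hemisphere[homolog] == hemisphere)) {
    stop_invalid("homolog must pair regions across hemispheres")
  }
  off <- upper.tri(weights)
  bad <- off & weights > 0 & fiber_distances <= 0
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop_invalid(sprintf(
      "positive weight at (%d,%d) but non-positive fiber distance", ij[1], ij[2]
    ))
  }
  eu <- as.matrix(dist(coordinates))
  if (any(fiber_distances < eu - 1e-6)) {
    stop_invalid("fiber_distances fall below Euclidean inter-node distances")
  }
  dimnames(weights) <- dimnames(fiber_distances) <- list(region_ids, region_ids)
  dimnames(coordinates) <- list(region_ids, c("x_mm", "y_mm", "z_mm"))
  structure(
    list(
      weights = weights, fiber_distances = fiber_distances,
      coordinates = coordinates, volumes = as.numeric(volumes),
      region_ids = as.character(region_ids),
      hemisphere = as.character(hemisphere),
      division = as.character(division), homolog = as.integer(homolog)
    ),
    class = "spatial_graph"
  )
}

#' @export
print.spatial_graph <- function(x, ...) {
  n <- length(x$region_ids)
  pos <- sum(x$weights[upper.tri(x$weights)] > 0)
  tot <- n * (n - 1) / 2
  cat(sprintf(
    "<spatial_graph> %d regions (%d L / %d R), %d divisions\n", n,
    sum(x$hemisphere == "L"), sum(x$hemisphere == "R"),
    length(unique(x$division))
  ))
  cat(sprintf(
    "  %d / %d node pairs connected (density %.1f%%), fiber distances %.2f-%.2f mm\n",
    pos, tot, 100 * pos / tot,
    min(x$fiber_distances[upper.tri(x$fiber_distances)]),
    max(x$fiber_distances)
  ))
  invisible(x)
}

#' Node table of a spatial graph
#'
#' @param graph A [spatial_graph()].
#' @return A tibble with one row per region: id, hemisphere, division,
#'   coordinates, volume, strength.
#' @export
node_table <- function(graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  tibble(
    region_id = graph$region_ids,
    hemisphere = graph$hemisphere,
    division = graph$division,
    x_mm = graph$coordinates[, 1],
    y_mm = graph$coordinates[, 2],
    z_mm = graph$coordinates[, 3],
    volume_mm3 = graph$volumes,
    strength = rowSums(graph$weights)
  )
}

#' Edge table of a spatial graph
#'
#' Long-format view of the upper triangle, the natural input to tidyverse
#' summaries of the weight-distance relationship.
#'
#' @param graph A [spatial_graph()].
#' @param positive_only Drop zero-weight pairs (default `TRUE`).
#' @return A tibble with columns `from`, `to`, `weight`, `fiber_distance_mm`,
#'   `division_from`, `division_to`, `laterality` ("ipsi"/"contra").
#' @export
edge_table <- function(graph, positive_only = TRUE) {
  stopifnot(inherits(graph, "spatial_graph"))
  n <- length(graph$region_ids)
  iu <- which(upper.tri(graph$weights), arr.ind = TRUE)
  out <- tibble(
    from = graph$region_ids[iu[, 1]],
    to = graph$region_ids[iu[, 2]],
    weight = graph$weights[iu],
    fiber_distance_mm = graph$fiber_distances[iu],
    division_from = graph$division[iu[, 1]],
    division_to = graph$division[iu[, 2]],
    laterality = ifelse(graph$hemisphere[iu[, 1]] == graph$hemisphere[iu[, 2]],
      "ipsi", "contra"
    )
  )
  if (positive_only) out <- filter(out, .data$weight > 0)
  out
}

#' Symmetrize a directed connectivity matrix
#'
#' Collapses a directed matrix (e.g. anterograde tracer projections) to an
#' undirected one by summing the two directed weights of every node pair,
#' for comparability with inherently undirected diffusion tractography.
#'
#' @param w_dir Square nonnegative matrix of directed weights.
#' @return Symmetric matrix with zero diagonal;
#'   `out[i,j] = w_dir[i,j] + w_dir[j,i]`.
#' @export
symmetrize_directed <- function(w_dir) {
  check_square(w_dir, "directed weight matrix")
  if (any(w_dir < 0)) stop_invalid("directed weights must be nonnegative")
  out <- w_dir + t(w_dir)
  diag(out) <- 0
  out
}

#' Enforce hemispheric mirror symmetry
#'
#' Makes `w[i,j] == w[h(i),h(j)]` exact for the homolog involution `h`, as
#' done when building square connectivity matrices from single-hemisphere
#' injections. The default averages each entry with its mirrored
#' counterpart: the unique symmetric, idempotent, total-weight-conserving
#' rule. `method = "sum"` adds them instead (not idempotent).
#'
#' @param w Symmetric weight matrix.
#' @param homolog Involution pairing mirror regions.
#' @param method "average" (default) or "sum".
#' @return Symmetric matrix satisfying the mirror identity exactly.
#' @export
enforce_hemispheric_symmetry <- function(w, homolog, method = c("average", "sum")) {
  method <- match.arg(method)
  check_symmetric(w, what = "weights")
  check_involution(homolog, nrow(w))
  mirrored <- w[homolog, homolog]
  out <- if (method == "average") (w + mirrored) / 2 else w + mirrored
  diag(out) <- 0
  out
}

#' Normalize connection counts by node-volume products
#'
#' Converts raw streamline or projection counts into the normalized
#' connection density metric: `counts[i,j] / (volumes[i] * volumes[j])`.
#'
#' @param counts Square nonnegative matrix of raw counts.
#' @param volumes Strictly positive node volumes (mm^3).
#' @return Matrix of normalized connection densities.
#' @export
normalize_connection_density <- function(counts, volumes) {
  check_square(counts, "count matrix")
  if (any(counts < 0)) stop_invalid("counts must be nonnegative")
  if (length(volumes) != nrow(counts) || any(volumes <= 0)) {
    stop_invalid("volumes must be strictly positive, one per node")
  }
  counts / outer(volumes, volumes)
}

#' Threshold a weighted graph to a target edge density
#'
#' Retains the `ceiling(d * N * (N-1) / 2)` largest-weight node pairs as
#' binary edges. Ties are broken by lexicographic (row, column) index order
#' so that density sweeps are deterministic and nested.
#'
#' @param w Symmetric weight matrix, zero diagonal.
#' @param density Fraction of node pairs to keep, in \[0, 1\].
#' @return Binary symmetric adjacency matrix.
#' @export
threshold_to_density <- function(w, density) {
  check_symmetric(w, what = "weights")
  if (!is.numeric(density) || length(density) != 1 || is.na(density) ||
    density < 0 || density > 1) {
    stop_invalid("density must be a single value in [0, 1]")
  }
  n <- nrow(w)
  iu <- which(upper.tri(w), arr.ind = TRUE)
  keep <- ceiling(density * nrow(iu))
  A <- matrix(0, n, n)
  if (keep > 0) {
    ord <- order(-w[upper.tri(w)], iu[, 1], iu[, 2])
    sel <- iu[ord[seq_len(keep)], , drop = FALSE]
    A[sel] <- 1
    A <- A + t(A)
  }
  dimnames(A) <- dimnames(w)
  A
}
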