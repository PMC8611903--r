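# Binary integration measures: global/local efficiency, clustering, path
# length. Disconnected pairs contribute 0 to efficiencies and are excluded
# from the mean path length (their count is reported).

binary_adjacency <- function(a) {
  check_symmetric(a, what = "adjacency")
  if (!all(a %in% c(0, 1))) stop_invalid("adjacency must be binary")
  if (any(diag(a) != 0)) stop_invalid("adjacency must have a zero diagonal")
  a
}

bfs_distances <- function(a) {
  g <- graph_from_adjacency_matrix(a, mode = "undirected", diag = FALSE)
  distances(g, algorithm = "unweighted")
}

#' Global efficiency of a binary graph
#'
#' Mean inverse shortest-path length over ordered node pairs, with
#' `1/Inf = 0` for disconnected pairs. Lies in \[0, 1\]; 1 for a complete
#' graph; monotone nondecreasing under edge addition.
#'
#' @param a Binary symmetric adjacency, zero diagonal, N >= 2.
#' @return Scalar efficiency.
#' @export
global_efficiency <- function(a) {
  a <- binary_adjacency(a)
  n <- nrow(a)
  if (n < 2) {
    abort("global efficiency undefined for fewer than 2 nodes",
      class = "geonull_undefined_metric"
    )
  }
  d <- bfs_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency per node
#'
#' For each node, the global efficiency of the subgraph induced on its
#' neighbors (the Latora-Marchiori neighborhood reading of "average inverse
#' shortest path length between a node and all of its neighbors"); nodes
#' with fewer than 2 neighbors score 0.
#'
#' @param a Binary symmetric adjacency, zero diagonal.
#' @return Named numeric vector in \[0, 1\].
#' @export
local_efficiency <- function(a) {
  a <- binary_adjacency(a)
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    if (length(nb) >= 2) {
      out[i] <- global_efficiency(a[nb, nb, drop = FALSE])
    }
  }
  names(out) <- rownames(a)
  out
}

#' Binary clustering coefficient and characteristic path length
#'
#' Standard binary clustering coefficient (triangle density of each node's
#' neighborhood; nodes of degree < 2 score 0) averaged over nodes, and the
#' mean shortest-path length over connected node pairs. Disconnected pairs
#' are excluded from the path-length mean and counted separately.
#'
#' @param a Binary symmetric adjacency, zero diagonal.
#' @return One-row tibble: `clustering`, `path_length`,
#'   `disconnected_pairs`.
#' @export
clustering_and_path_length <- function(a) {
  a <- binary_adjacency(a)
  n <- nrow(a)
  deg <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2 # triangles through each node
  cc <- ifelse(deg >= 2, tri / (deg * (deg - 1) / 2), 0)
  d <- bfs_distances(a)
  up <- upper.tri(d)
  finite <- up & is.finite(d) & d > 0
  pl <- if (any(finite)) mean(d[finite]) else NA_real_
  tibble(
    clustering = mean(cc),
    path_length = pl,
    disconnected_pairs = sum(up & is.infinite(d))
  )
}
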