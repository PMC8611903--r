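# Modularity, Louvain optimization, label alignment, consensus.

as_membership_vec <- function(partition, n = NULL) {
  m <- if (inherits(partition, "module_partition")) partition$assignment else partition
  m <- as.integer(m)
  if (!is.null(n) && length(m) != n) stop_invalid("partition length mismatch")
  if (any(is.na(m)) || any(m < 1)) stop_invalid("module labels must be positive integers")
  m
}

new_module_partition <- function(assignment, Q = NA_real_, seed = NA_integer_) {
  assignment <- as.integer(assignment)
  # relabel to contiguous 1..k in order of first appearance
  assignment <- match(assignment, unique(assignment[order(assignment)]))
  structure(
    list(
      assignment = assignment,
      n_modules = length(unique(assignment)),
      Q = Q,
      source_seed = seed
    ),
    class = "module_partition"
  )
}

#' Construct a module partition object
#'
#' @param assignment Positive-integer module label per node (relabelled to
#'   contiguous `1..n_modules`).
#' @param Q Optional modularity of the assignment on its source graph.
#' @param seed Optional seed that produced the assignment.
#' @return A `module_partition`.
#' @export
module_partition <- function(assignment, Q = NA_real_, seed = NA_integer_) {
  new_module_partition(as_membership_vec(assignment), Q = Q, seed = seed)
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf(
    "<module_partition> %d nodes in %d modules (Q = %s)\n",
    length(x$assignment), x$n_modules,
    ifelse(is.na(x$Q), "NA", format(x$Q, digits = 4))
  ))
  invisible(x)
}

#' @method tidy module_partition
#' @export
tidy.module_partition <- function(x, ...) {
  tibble(node = seq_along(x$assignment), module = x$assignment)
}

#' Newman-Girvan modularity of a weighted partition
#'
#' `Q = (1/2m) * sum_ij (w_ij - s_i s_j / 2m) * delta(c_i, c_j)` with `m`
#' the total edge weight and `s` the node strengths. Invariant under module
#' relabelling and uniform weight rescaling.
#'
#' @param w Symmetric nonnegative weight matrix.
#' @param partition `module_partition` or integer membership vector.
#' @return Scalar modularity Q.
#' @export
modularity_score <- function(w, partition) {
  check_symmetric(w, what = "weights")
  memb <- as_membership_vec(partition, nrow(w))
  m2 <- sum(w)
  if (m2 <= 0) {
    abort("modularity undefined: total edge weight is zero",
      class = "geonull_undefined_metric"
    )
  }
  s <- rowSums(w)
  q <- 0
  for (c in unique(memb)) {
    idx <- memb == c
    q <- q + sum(w[idx, idx]) / m2 - (sum(s[idx]) / m2)^2
  }
  q
}

#' Louvain community detection with restarts
#'
#' Optimizes modularity with the Louvain heuristic; the best of
#' `n_restarts` randomized runs is kept. Deterministic given `seed`.
#'
#' @param w Symmetric nonnegative weight matrix.
#' @param seed Integer seed.
#' @param resolution Resolution parameter (1 = classic modularity).
#' @param n_restarts Randomized restarts; the partition with the highest
#'   modularity is returned.
#' @return A `module_partition` with its Q on `w`.
#' @export
louvain_partition <- function(w, seed = 1L, resolution = 1, n_restarts = 100) {
  check_symmetric(w, what = "weights")
  if (sum(w) <= 0) {
    abort("Louvain undefined: total edge weight is zero",
      class = "geonull_undefined_metric"
    )
  }
  g <- graph_from_adjacency_matrix(w, mode = "undirected", weighted = TRUE)
  wts <- E(g)$weight
  with_seed(as.integer(seed), {
    best <- NULL
    best_q <- -Inf
    for (r in seq_len(n_restarts)) {
      cl <- cluster_louvain(g, resolution = resolution)
      q <- modularity(g, membership(cl), weights = wts, resolution = resolution)
      if (q > best_q) {
        best_q <- q
        best <- as.integer(membership(cl))
      }
    }
    new_module_partition(best, Q = modularity_score(w, best), seed = as.integer(seed))
  })
}

# maximum-agreement injective label mapping from partition modules onto
# reference modules, via exact subset-DP assignment on the contingency
# table (small module counts) or a greedy fallback.
assignment_mapping <- function(contingency) {
  kp <- nrow(contingency)
  kr <- ncol(contingency)
  if (kr <= 16) {
    n_states <- bitwShiftL(1L, kr)
    # dp over rows; state = set of used reference labels
    dp <- matrix(-Inf, kp + 1L, n_states)
    choice <- array(NA_integer_, c(kp, n_states))
    dp[1L, 1L] <- 0
    for (i in seq_len(kp)) {
      for (st in which(dp[i, ] > -Inf) - 1L) {
        # skip: leave row i unmatched (gets a fresh label)
        if (dp[i, st + 1L] > dp[i + 1L, st + 1L]) {
          dp[i + 1L, st + 1L] <- dp[i, st + 1L]
          choice[i, st + 1L] <- 0L
        }
        for (j in seq_len(kr)) {
          bit <- bitwShiftL(1L, j - 1L)
          if (bitwAnd(st, bit) == 0L) {
            v <- dp[i, st + 1L] + contingency[i, j]
            if (v > dp[i + 1L, bitwOr(st, bit) + 1L]) {
              dp[i + 1L, bitwOr(st, bit) + 1L] <- v
              choice[i, bitwOr(st, bit) + 1L] <- j
            }
          }
        }
      }
    }
    end_state <- which.max(dp[kp + 1L, ]) - 1L
    mapping <- integer(kp)
    st <- end_state
    for (i in rev(seq_len(kp))) {
      j <- choice[i, st + 1L]
      mapping[i] <- j
      if (!is.na(j) && j > 0L) st <- bitwAnd(st, bitwNot(bitwShiftL(1L, j - 1L)))
    }
    mapping
  } else {
    # greedy: repeatedly take the largest remaining overlap
    mapping <- integer(kp)
    ct <- contingency
    repeat {
      if (all(ct < 0)) break
      ij <- which(ct == max(ct), arr.ind = TRUE)[1, ]
      if (ct[ij[1], ij[2]] < 0) break
      mapping[ij[1]] <- ij[2]
      ct[ij[1], ] <- -1
      ct[, ij[2]] <- -1
    }
    mapping
  }
}

#' Align module labels to a reference partition
#'
#' Relabels the modules of `partition` so that per-node label agreement
#' with `reference` is maximized, via an optimal injective assignment on
#' the module-overlap contingency table. The grouping itself is unchanged;
#' only labels move. Modules that match no reference module receive fresh
#' labels above the reference's range.
#'
#' @param partition,reference `module_partition`s (or membership vectors)
#'   over the same nodes.
#' @return A `module_partition` with relabelled assignment.
#' @export
align_labels <- function(partition, reference) {
  p <- as_membership_vec(partition)
  r <- as_membership_vec(reference, length(p))
  kp <- max(p)
  kr <- max(r)
  ct <- matrix(0, kp, kr)
  for (i in seq_along(p)) ct[p[i], r[i]] <- ct[p[i], r[i]] + 1
  mapping <- assignment_mapping(ct)
  unmatched <- which(is.na(mapping) | mapping == 0L)
  if (length(unmatched)) mapping[unmatched] <- kr + seq_along(unmatched)
  out <- mapping[p]
  q <- if (inherits(partition, "module_partition")) partition$Q else NA_real_
  sd <- if (inherits(partition, "module_partition")) partition$source_seed else NA_integer_
  structure(
    list(
      assignment = as.integer(out),
      n_modules = length(unique(out)),
      Q = q, source_seed = sd
    ),
    class = "module_partition"
  )
}

#' Consensus partition across aligned partitions
#'
#' Each partition is aligned to `reference`, then every node takes the
#' label most frequently assigned to it; ties break to the lowest label ID.
#'
#' @param partitions Non-empty list of `module_partition`s or membership
#'   vectors.
#' @param reference Reference partition for label alignment.
#' @param w Optional weight matrix on which to evaluate the consensus Q.
#' @return A `module_partition` in the aligned label space.
#' @export
consensus_partition <- function(partitions, reference, w = NULL) {
  if (length(partitions) == 0) stop_invalid("need at least one partition")
  aligned <- lapply(partitions, function(p) align_labels(p, reference)$assignment)
  labels_mat <- do.call(rbind, aligned)
  cons <- apply(labels_mat, 2, function(v) {
    which.max(tabulate(v)) # ties break to the lowest label ID
  })
  q <- if (!is.null(w)) modularity_score(w, cons) else NA_real_
  structure(
    list(
      assignment = as.integer(cons),
      n_modules = length(unique(cons)),
      Q = q, source_seed = NA_integer_
    ),
    class = "module_partition"
  )
}

#' Percent node-label agreement of two partitions
#'
#' `p1` is assumed already aligned to `p2` (see [align_labels()]).
#'
#' @param p1,p2 `module_partition`s or membership vectors, same nodes.
#' @return Percent of nodes with identical labels (0-100).
#' @export
partition_agreement <- function(p1, p2) {
  a <- as_membership_vec(p1)
  b <- as_membership_vec(p2, length(a))
  100 * mean(a == b)
}
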