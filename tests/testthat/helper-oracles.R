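# Independent brute-force oracles. Deliberately written as plain loops /
# generic numerics so they share no code path with the package.

oracle_modularity <- function(w, memb) {
  m2 <- sum(w)
  n <- nrow(w)
  s <- rowSums(w)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) {
        q <- q + (w[i, j] - s[i] * s[j] / m2) / m2
      }
    }
  }
  q
}

# all set partitions of 1..n (Bell number growth; fine for n <= 8)
all_partitions <- function(n) {
  if (n == 1) {
    return(list(list(1L)))
  }
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1]] <- q
    }
    p[[length(p) + 1]] <- n
    out[[length(out) + 1]] <- p
  }
  out
}

oracle_best_partition <- function(w) {
  best_q <- -Inf
  best <- NULL
  for (p in all_partitions(nrow(w))) {
    memb <- integer(nrow(w))
    for (k in seq_along(p)) memb[p[[k]]] <- k
    q <- oracle_modularity(w, memb)
    if (q > best_q) {
      best_q <- q
      best <- memb
    }
  }
  list(memb = best, q = best_q)
}

oracle_participation <- function(w, memb) {
  n <- nrow(w)
  p <- numeric(n)
  for (i in seq_len(n)) {
    ki <- sum(w[i, ])
    if (ki == 0) next
    acc <- 0
    for (m in unique(memb)) {
      kim <- sum(w[i, memb == m])
      acc <- acc + (kim / ki)^2
    }
    p[i] <- 1 - acc
  }
  p
}

oracle_eigenvector <- function(w) {
  e <- eigen(w, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- abs(v)
  v / sqrt(sum(v^2))
}

oracle_bfs <- function(a, start) {
  n <- nrow(a)
  d <- rep(Inf, n)
  d[start] <- 0
  frontier <- start
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in which(a[u, ] > 0)) {
        if (is.infinite(d[v])) {
          d[v] <- d[u] + 1
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  d
}

oracle_global_efficiency <- function(a) {
  n <- nrow(a)
  tot <- 0
  for (i in seq_len(n)) {
    d <- oracle_bfs(a, i)
    for (j in seq_len(n)) {
      if (j != i && is.finite(d[j])) tot <- tot + 1 / d[j]
    }
  }
  tot / (n * (n - 1))
}

oracle_local_efficiency <- function(a) {
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    if (length(nb) >= 2) {
      out[i] <- oracle_global_efficiency(a[nb, nb, drop = FALSE])
    }
  }
  out
}

oracle_clustering_path <- function(a) {
  n <- nrow(a)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k >= 2) {
      links <- 0
      for (u in nb) for (v in nb) if (u < v && a[u, v] > 0) links <- links + 1
      cc[i] <- links / (k * (k - 1) / 2)
    }
  }
  dsum <- 0
  cnt <- 0
  for (i in seq_len(n)) {
    d <- oracle_bfs(a, i)
    for (j in seq_len(n)) {
      if (j > i && is.finite(d[j]) && d[j] > 0) {
        dsum <- dsum + d[j]
        cnt <- cnt + 1
      }
    }
  }
  list(clustering = mean(cc), path_length = if (cnt) dsum / cnt else NA_real_)
}

oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- mean(rx)
  my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

oracle_pearson <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random symmetric weighted test graph (possibly sparse)
random_weighted_graph <- function(n, p_edge = 0.6) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p_edge) w[i, j] <- w[j, i] <- runif(1, 0.1, 5)
    }
  }
  w
}

random_binary_graph <- function(n, p_edge = 0.4) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p_edge) a[i, j] <- a[j, i] <- 1
    }
  }
  a
}
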