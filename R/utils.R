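# internal validators shared across modules

stop_invalid <- function(...) abort(paste0(...), class = "geonull_invalid_input")

check_square <- function(M, what = "matrix") {
  if (!is.matrix(M) || !is.numeric(M) || nrow(M) != ncol(M)) {
    stop_invalid(what, " must be a square numeric matrix")
  }
  if (any(!is.finite(M))) stop_invalid(what, " contains non-finite values")
  invisible(M)
}

check_symmetric <- function(M, tol = 1e-9, what = "matrix") {
  check_square(M, what)
  dev <- abs(M - t(M))
  if (max(dev) > tol) {
    ij <- which(dev == max(dev), arr.ind = TRUE)[1, ]
    stop_invalid(what, sprintf(
      " is asymmetric beyond %g: entry (%d,%d) differs from (%d,%d) by %g",
      tol, ij[1], ij[2], ij[2], ij[1], max(dev)
    ))
  }
  invisible(M)
}

check_involution <- function(homolog, n) {
  if (length(homolog) != n || !all(homolog %in% seq_len(n))) {
    stop_invalid("homolog must index all ", n, " nodes")
  }
  if (any(homolog[homolog] != seq_len(n)) || any(homolog == seq_len(n))) {
    stop_invalid("homolog must be a fixed-point-free involution (h(h(i)) = i, h(i) != i)")
  }
  invisible(homolog)
}

upper_idx <- function(n) which(upper.tri(matrix(0, n, n)))

# rebuild a symmetric matrix from values on the upper triangle
sym_from_upper <- function(values, n) {
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- values
  M + t(M)
}
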