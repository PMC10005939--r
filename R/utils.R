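# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Half-vectorization of a symmetric matrix
#'
#' Stacks the lower triangle (including the diagonal) of a symmetric matrix
#' column by column, the ordering used throughout for the genetic covariance
#' matrix and its sampling covariance.
#'
#' @param m A symmetric numeric matrix.
#' @return Numeric vector of length `k(k+1)/2`.
#' @export
vech <- function(m) m[lower.tri(m, diag = TRUE)]

# index pairs (i >= j) in vech order for a k x k matrix
vech_index <- function(k) {
  idx <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}

# inverse of vech: rebuild the symmetric matrix
unvech <- function(v, k) {
  m <- matrix(0, k, k)
  m[lower.tri(m, diag = TRUE)] <- v
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

# deterministic sub-stream seeds so one top-level seed drives every stage;
# kept strictly below 2^31 - 1
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 11 * offset) %% 2147483629L)
}

# contiguous jackknife block assignment; shrinks the block count (with a
# warning) when there are fewer variants than requested blocks
block_assign <- function(m, n_blocks) {
  if (m < 2L) stop("need at least 2 variants for jackknife blocks")
  if (n_blocks > m) {
    warning(sprintf("reducing jackknife blocks from %d to %d (only %d variants)",
                    n_blocks, m, m))
    n_blocks <- m
  }
  sort(rep_len(seq_len(n_blocks), m))
}

# delete-one-block jackknife covariance of a B x p matrix of delete-block
# estimates; returns list(est_se or cov)
jackknife_cov <- function(theta_del) {
  b <- nrow(theta_del)
  centred <- sweep(theta_del, 2L, colMeans(theta_del))
  crossprod(centred) * (b - 1) / b
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
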