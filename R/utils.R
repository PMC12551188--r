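#' Standardize a numeric vector
#'
#' Centers to mean zero and scales to unit sample standard deviation
#' (denominator \eqn{n-1}).
#'
#' @param v numeric vector with positive variance.
#' @return numeric vector with mean 0 and sample SD 1.
#' @export
#' @examples
#' standardize(c(1, 2, 3))
standardize <- function(v) {
  if (!is.numeric(v)) stop("`v` must be numeric")
  s <- stats::sd(v)
  if (!is.finite(s) || s <= 0) {
    stop("cannot standardize a constant (zero-variance) vector")
  }
  (v - mean(v)) / s
}

#' Ridge-stabilize a relationship matrix
#'
#' Adds `eps * mean(diag(K))` to the diagonal.  Relationship matrices built
#' from fewer markers/transcripts than animals (e.g. \eqn{T = WW^T/k} with
#' `k < n`) are singular; this small ridge makes them invertible without
#' materially changing the model.
#'
#' @param K symmetric matrix.
#' @param eps relative ridge size (default `1e-6`).
#' @return `K` with the ridge added; the ridge actually used is stored in
#'   attribute `"ridge"`.
#' @export
ridge_stabilize <- function(K, eps = 1e-6) {
  r <- eps * mean(diag(K))
  out <- K + diag(r, nrow(K))
  attr(out, "ridge") <- r
  out
}

## force exact symmetry after chains of matrix products
symmetrize <- function(M) (M + t(M)) / 2

## local RNG: set a seed without clobbering the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## drop aliased (linearly dependent) columns of a design matrix
drop_aliased <- function(X, warn = TRUE) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- colnames(X)[-keep]
    if (warn) {
      warning("dropping aliased design column(s): ",
              paste(dropped, collapse = ", "))
    }
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}
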