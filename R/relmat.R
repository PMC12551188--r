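#' Genomic relationship matrix (VanRaden method 1)
#'
#' \deqn{G = \frac{ZZ^T}{\sum_j 2 p_j (1 - p_j)}}
#' with \eqn{Z} the centered dosage matrix (polymorphic SNPs only; monomorphic
#' SNPs contribute zero to both numerator and denominator).
#'
#' @param geno a [genotype_data] object.
#' @return symmetric \eqn{n \times n} matrix with animal ids as dimnames and
#'   attribute `kind = "G"`.
#' @export
vanraden_g <- function(geno) {
  stopifnot(inherits(geno, "genotype_data"))
  G <- tcrossprod(geno$Z) / geno$m_tilde
  G <- symmetrize(G)
  dimnames(G) <- list(geno$ids, geno$ids)
  attr(G, "kind") <- "G"
  G
}

#' Transcriptomic relationship matrix
#'
#' \deqn{T = \frac{WW^T}{k}} with \eqn{W} the pre-corrected standardized
#' transcript matrix and \eqn{k} the number of transcripts.
#'
#' @param W numeric matrix (animals x transcripts).
#' @param k number of transcripts; must equal `ncol(W)`.
#' @return symmetric positive semidefinite \eqn{n \times n} matrix with
#'   attribute `kind = "T"`.
#' @export
transcript_t <- function(W, k = ncol(W)) {
  W <- as.matrix(W)
  if (ncol(W) == 0L || k == 0L) stop("`W` must have at least one transcript column")
  if (k != ncol(W)) stop("`k` must equal the number of columns of `W`")
  Tm <- symmetrize(tcrossprod(W) / k)
  dimnames(Tm) <- list(rownames(W), rownames(W))
  attr(Tm, "kind") <- "T"
  Tm
}

#' Ridge parameter from the heritability of transcript-level effects
#'
#' \deqn{\lambda = \tilde m \left(\frac{1}{\tilde h_t^2} - 1\right)}
#'
#' @param h2_t heritability of transcript-level effects, in (0, 1).
#' @param m_tilde VanRaden scaling constant \eqn{\sum_j 2 p_j(1-p_j)}.
#' @return positive scalar \eqn{\lambda}.
#' @export
#' @examples
#' lambda_from_h2(0.25, 1)  # 3
lambda_from_h2 <- function(h2_t, m_tilde) {
  if (!is.numeric(h2_t) || length(h2_t) != 1L || h2_t <= 0 || h2_t >= 1) {
    stop("`h2_t` must be a single value strictly inside (0, 1)")
  }
  if (m_tilde <= 0) stop("`m_tilde` must be positive")
  m_tilde * (1 / h2_t - 1)
}

#' Condition transcript abundances on genotypes (direct route)
#'
#' \deqn{W_c = \left(I_n - Z (Z^T Z + I_m \lambda)^{-1} Z^T\right) W,}
#' i.e. \eqn{W_c = (I - S_\lambda) W} with the ridge-regression smoother
#' \eqn{S_\lambda}.  The \eqn{m \times m} inversion makes this the route of
#' choice when animals outnumber SNPs.
#'
#' @param W transcript matrix (animals x transcripts), rows aligned with the
#'   genotype rows.
#' @param geno a [genotype_data] object supplying the centered `Z`.
#' @param lambda positive ridge parameter (see [lambda_from_h2()]).
#' @return object of class `"conditioning"`: list with `W_c`, `lambda`,
#'   `route = "direct"`.
#' @export
condition_w_direct <- function(W, geno, lambda) {
  stopifnot(inherits(geno, "genotype_data"))
  W <- as.matrix(W)
  Z <- geno$Z
  if (nrow(W) != nrow(Z)) stop("`W` and genotype rows must be aligned")
  if (lambda <= 0) stop("`lambda` must be positive")
  A <- crossprod(Z)
  diag(A) <- diag(A) + lambda
  W_c <- W - Z %*% solve(A, crossprod(Z, W))
  dimnames(W_c) <- dimnames(W)
  structure(list(W_c = W_c, lambda = lambda, route = "direct"),
            class = "conditioning")
}

#' Condition transcript abundances on genotypes (Woodbury route)
#'
#' Equivalent to [condition_w_direct()] but written via the Woodbury matrix
#' identity in terms of the \eqn{n \times n} genomic relationship matrix:
#' \deqn{W_c = \left(I_n - G^* + G^* (I_n + G^*)^{-1} G^*\right) W,
#'       \qquad G^* = G\, \tilde m / \lambda.}
#' The route of choice when SNPs outnumber animals.
#'
#' @param W transcript matrix (animals x transcripts).
#' @param G genomic relationship matrix built from the same `Z` ([vanraden_g()]).
#' @param m_tilde VanRaden scaling constant used in `G`.
#' @param lambda positive ridge parameter.
#' @return object of class `"conditioning"`: list with `W_c`, `lambda`,
#'   `route = "woodbury"`.
#' @export
condition_w_woodbury <- function(W, G, m_tilde, lambda) {
  W <- as.matrix(W)
  G <- as.matrix(G)
  if (nrow(W) != nrow(G)) stop("`W` and `G` rows must be aligned")
  if (lambda <= 0) stop("`lambda` must be positive")
  if (m_tilde <= 0) stop("`m_tilde` must be positive")
  Gs <- G * (m_tilde / lambda)
  B <- Gs
  diag(B) <- diag(B) + 1       # I + G*
  GsW <- Gs %*% W
  W_c <- W - GsW + Gs %*% solve(B, GsW)
  dimnames(W_c) <- dimnames(W)
  structure(list(W_c = W_c, lambda = lambda, route = "woodbury"),
            class = "conditioning")
}

#' Conditioned transcriptomic relationship matrix
#'
#' \deqn{T_c = \frac{W_c W_c^T}{k}.}
#'
#' @param W_c conditioned transcript matrix (a matrix, or a `"conditioning"`
#'   object from [condition_w_direct()] / [condition_w_woodbury()]).
#' @param k number of transcripts.
#' @return symmetric PSD matrix with attribute `kind = "T_c"`.
#' @export
conditioned_t <- function(W_c, k = NULL) {
  if (inherits(W_c, "conditioning")) W_c <- W_c$W_c
  if (is.null(k)) k <- ncol(W_c)
  Tc <- transcript_t(W_c, k)
  attr(Tc, "kind") <- "T_c"
  Tc
}

#' Choose the cheaper conditioning route
#'
#' Direct (one \eqn{m \times m} inversion) when animals outnumber SNPs;
#' Woodbury (one \eqn{n \times n} inversion) when SNPs outnumber animals.
#' A tie goes to the direct route.
#'
#' @param n number of animals.
#' @param m number of SNPs.
#' @return `"direct"` or `"woodbury"`.
#' @export
#' @examples
#' choose_route(480, 4000)  # "woodbury"
choose_route <- function(n, m) {
  if (n >= m) "direct" else "woodbury"
}

#' Condition transcripts on genotypes, picking the route automatically
#'
#' @inheritParams condition_w_direct
#' @param G optional precomputed [vanraden_g()] matrix (avoids recomputation
#'   inside grid searches).
#' @return a `"conditioning"` object.
#' @export
condition_w <- function(W, geno, lambda, G = NULL) {
  route <- choose_route(nrow(as.matrix(W)), geno$m)
  if (route == "direct") {
    condition_w_direct(W, geno, lambda)
  } else {
    if (is.null(G)) G <- vanraden_g(geno)
    condition_w_woodbury(W, G, geno$m_tilde, lambda)
  }
}
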