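#' Back-solve transcript effects from TBLUP animal effects
#'
#' \deqn{\hat u = \frac{1}{k} W^T T^{-1} \hat t,}
#' where \eqn{\hat t} is the vector of estimated animal transcriptomic
#' effects.  When \eqn{T} is exactly invertible the consistency identity
#' \eqn{W \hat u = \hat t} holds.  \eqn{T} with fewer transcripts than
#' animals is singular, so a small ridge ([ridge_stabilize()]) is applied
#' before inversion; the ridge used is recorded in attribute `"ridge"`.
#'
#' @param W pre-corrected standardized transcript matrix (n x k).
#' @param T_mat transcriptomic relationship matrix \eqn{WW^T/k}.
#' @param t_hat BLUP vector of animal transcriptomic effects (length n).
#' @param k number of transcripts.
#' @param ridge_eps relative ridge for the inversion of `T_mat`.
#' @return vector \eqn{\hat u} of length `k`.
#' @export
backsolve_effects <- function(W, T_mat, t_hat, k = ncol(W), ridge_eps = 1e-6) {
  W <- as.matrix(W)
  if (length(t_hat) != nrow(W)) stop("`t_hat` must have one entry per animal")
  if (k != ncol(W)) stop("`k` must equal ncol(W)")
  Tr <- ridge_stabilize(as.matrix(T_mat), ridge_eps)
  u <- drop(crossprod(W, solve(Tr, t_hat))) / k
  names(u) <- colnames(W)
  attr(u, "ridge") <- attr(Tr, "ridge")
  u
}

#' Prediction-error variance matrix of the animal transcriptomic effects
#'
#' The PEV of \eqn{\hat t} from the TBLUP model with one record per animal
#' (incidence matrix = identity) is the random-effect block of the inverse
#' mixed-model-equation coefficient matrix:
#' \deqn{C^{tt} = \sigma^2_e\left(I - X (X^T X)^{-1} X^T +
#'   T^{-1}\lambda\right)^{-1}, \qquad \lambda = \sigma^2_e / \sigma^2_t.}
#'
#' @param X fixed-effect design matrix (full column rank).
#' @param T_mat transcriptomic relationship matrix.
#' @param sigma2_e,sigma2_t residual and transcriptomic variance components.
#' @param ridge_eps relative ridge for the inversion of `T_mat`.
#' @return symmetric n x n matrix.
#' @export
ctt_matrix <- function(X, T_mat, sigma2_e, sigma2_t, ridge_eps = 1e-6) {
  X <- as.matrix(X)
  T_mat <- as.matrix(T_mat)
  n <- nrow(T_mat)
  if (nrow(X) != n) stop("`X` rows must match `T_mat`")
  if (sigma2_e <= 0 || sigma2_t <= 0) stop("variance components must be positive")
  if (qr(X)$rank < ncol(X)) stop("`X` must have full column rank")
  lam <- sigma2_e / sigma2_t
  Tr <- ridge_stabilize(T_mat, ridge_eps)
  M <- diag(n) - X %*% solve(crossprod(X), t(X))
  inner <- M + solve(Tr) * lam
  cn <- rcond(inner)
  if (cn < 1e-14) {
    stop(sprintf("C^tt inner matrix is numerically singular (rcond = %.2e)", cn))
  }
  symmetrize(sigma2_e * solve(inner))
}

#' Variance of back-solved transcript effects
#'
#' \deqn{\mathrm{Var}(\hat u) = \frac{1}{k^2} W^T T^{-1}
#'   (T \sigma^2_t - C^{tt}) T^{-1} W.}
#' Returns the diagonal.  Small negative diagonal entries (within numerical
#' error) are clipped to zero; entries below `-1e-10` times the matrix scale
#' signal an inconsistent PEV and raise an error.
#'
#' @param W transcript matrix.
#' @param T_mat transcriptomic relationship matrix.
#' @param Ctt PEV matrix from [ctt_matrix()].
#' @param sigma2_t transcriptomic variance component.
#' @param k number of transcripts.
#' @param ridge_eps relative ridge for inversions of `T_mat`.
#' @return vector of `Var(u_hat_j)`, length `k`.
#' @export
effect_variance <- function(W, T_mat, Ctt, sigma2_t, k = ncol(W),
                            ridge_eps = 1e-6) {
  W <- as.matrix(W)
  Tr <- ridge_stabilize(as.matrix(T_mat), ridge_eps)
  TiW <- solve(Tr, W)
  ## the same stabilized T must be used here and inside C^tt: the difference
  ## T*sigma2_t - C^tt is second order in sigma2_t and a ridge mismatch
  ## would otherwise dominate it near the boundary
  mid <- Tr * sigma2_t - Ctt
  v <- colSums(TiW * (mid %*% TiW)) / k^2
  scale <- max(abs(v), 1)
  if (any(v < -1e-10 * scale)) {
    stop("negative estimated Var(u_hat): prediction-error variance is inconsistent ",
         "with the fitted variance components")
  }
  pmax(v, 0)
}

#' Standard-normal association test of transcript effects
#'
#' \eqn{RNA_j = \hat u_j / \sqrt{\mathrm{Var}(\hat u_j)}} with two-sided
#' p-values \eqn{2(1 - \Phi(|RNA_j|))}.  Both the nominal 0.05 level and the
#' Bonferroni threshold `0.05 / n_tests` are reported.
#'
#' @param u_hat back-solved transcript effects.
#' @param var_u their variances (nonnegative).
#' @param n_tests number of tests for the Bonferroni threshold (default:
#'   number of transcripts).
#' @param alpha nominal significance level (default 0.05).
#' @return object of class `"transcript_effects"`: data.frame `table`
#'   (`transcript`, `u_hat`, `var_u`, `rna`, `p`), `bonferroni_alpha`,
#'   `alpha`.
#' @export
rna_test <- function(u_hat, var_u, n_tests = length(u_hat), alpha = 0.05) {
  if (length(u_hat) != length(var_u)) stop("`u_hat` and `var_u` must be parallel")
  if (any(var_u < 0)) stop("`var_u` must be nonnegative")
  rna <- ifelse(var_u > 0, u_hat / sqrt(var_u), ifelse(u_hat == 0, 0, Inf * sign(u_hat)))
  if (any(var_u == 0 & u_hat != 0)) {
    warning("zero variance with nonzero effect: p-value set to 0")
  }
  p <- 2 * stats::pnorm(abs(rna), lower.tail = FALSE)
  nm <- names(u_hat)
  if (is.null(nm)) nm <- sprintf("tr%d", seq_along(u_hat))
  structure(list(table = data.frame(transcript = nm, u_hat = as.numeric(u_hat),
                                    var_u = var_u, rna = rna, p = p),
                 bonferroni_alpha = alpha / n_tests, alpha = alpha,
                 n_tests = n_tests),
            class = "transcript_effects")
}

#' Transcript-effect back-solving and testing from a fitted TBLUP model
#'
#' Full pipeline: extract \eqn{\hat t}, \eqn{\sigma^2_t}, \eqn{\sigma^2_e}
#' and the fixed design from the fit, back-solve \eqn{\hat u}
#' ([backsolve_effects()]), form \eqn{C^{tt}} ([ctt_matrix()]) and
#' \eqn{\mathrm{Var}(\hat u)} ([effect_variance()]), and test each effect
#' ([rna_test()]).  Requires one phenotype record per animal.
#'
#' @param fit a `"blup_fit"` with a single transcript term (default name
#'   `"t"`).
#' @param W the transcript matrix the fit's \eqn{T} was built from.
#' @param term name of the transcript term in the fit.
#' @param ridge_eps relative ridge for inversions of `T`.
#' @param alpha nominal significance level.
#' @return a `"transcript_effects"` object (see [rna_test()]).
#' @export
transcript_effects <- function(fit, W, term = "t", ridge_eps = 1e-6,
                               alpha = 0.05) {
  stopifnot(inherits(fit, "blup_fit"))
  if (!term %in% fit$term_names) stop("fit has no term named '", term, "'")
  W <- as.matrix(W)
  if (nrow(W) != fit$n) stop("`W` must have one row per fitted animal")
  Tm <- transcript_t(W)
  s2t <- fit$variance_components[[term]]
  s2e <- fit$variance_components[["residual"]]
  t_hat <- fit$blups[[term]]
  u_hat <- backsolve_effects(W, Tm, t_hat, ridge_eps = ridge_eps)
  Ctt <- ctt_matrix(fit$X, Tm, s2e, s2t, ridge_eps = ridge_eps)
  var_u <- effect_variance(W, Tm, Ctt, s2t, ridge_eps = ridge_eps)
  out <- rna_test(u_hat, var_u, alpha = alpha)
  out$ridge <- attr(u_hat, "ridge")
  out
}

#' @export
print.transcript_effects <- function(x, ...) {
  cat(sprintf("Transcript-effect tests: %d transcripts\n", nrow(x$table)))
  cat(sprintf("  nominal alpha %.3g: %d significant; Bonferroni %.3g: %d significant\n",
              x$alpha, sum(x$table$p < x$alpha),
              x$bonferroni_alpha, sum(x$table$p < x$bonferroni_alpha)))
  print(head(x$table[order(x$table$p), ], 5L))
  invisible(x)
}

#' Manhattan-style plot of transcript-effect p-values
#'
#' \eqn{-\log_{10} p} per transcript with the nominal and
#' Bonferroni-corrected significance lines.
#'
#' @param x a `"transcript_effects"` object.
#' @param ... passed to `plot()`.
#' @export
plot.transcript_effects <- function(x, ...) {
  lp <- -log10(pmax(x$table$p, 1e-300))
  plot(seq_along(lp), lp, pch = 19, xlab = "transcript",
       ylab = expression(-log[10](p)), xaxt = "n", ...)
  axis(1, at = seq_along(lp), labels = x$table$transcript, las = 2,
       cex.axis = 0.6)
  abline(h = -log10(x$alpha), col = "salmon")
  abline(h = -log10(x$bonferroni_alpha), col = "darkred")
  invisible(x)
}
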