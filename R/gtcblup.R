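#' Fit the GTCBLUPi model (grid search over transcript-level heritability)
#'
#' The model is \eqn{y = Xb + g + t_c + e} with
#' \eqn{g \sim N(0, G\sigma^2_g)} and
#' \eqn{t_c \sim N(0, T_c \sigma^2_{t_c})}, where
#' \eqn{T_c = W_c W_c^T / k} and \eqn{W_c = (I - S_\lambda) W} is the
#' transcript matrix conditioned on the genotypes through the ridge smoother
#' \eqn{S_\lambda = Z (Z^T Z + \lambda I)^{-1} Z^T}.  The ridge is tied to the
#' heritability of transcript-level effects by
#' \eqn{\lambda = \tilde m (1/\tilde h_t^2 - 1)}.
#'
#' \eqn{\tilde h_t^2} cannot be estimated jointly with the other variance
#' components (it enters through \eqn{W_c} itself), so it is profiled: for
#' each grid value the model is refitted by REML and the value maximizing the
#' restricted log-likelihood is selected.  Ties are broken toward the smaller
#' \eqn{\tilde h_t^2} (the more conservative removal of genetic signal).
#' REML at each grid point is warm-started from the previous point's variance
#' components.  Grid points that fail to converge are recorded and skipped.
#'
#' @param y response vector (standardized).
#' @param X fixed-effect design (`NULL` = intercept only).
#' @param geno a [genotype_data] object.
#' @param W pre-corrected standardized transcript matrix.
#' @param grid_step step of the \eqn{\tilde h_t^2} grid (default 0.01; grid =
#'   `seq(grid_step, 1 - grid_step, by = grid_step)`).
#' @param grid optional explicit grid of \eqn{\tilde h_t^2} values in (0, 1).
#' @param G optional precomputed [vanraden_g()] matrix.
#' @param ... further arguments to [blup_fit()].
#' @return object of class `"gtcblupi_fit"`: list with `h2_t_hat`,
#'   `lambda_hat`, `profile` (data.frame `h2_t`, `lambda`, `loglik`,
#'   `converged`), `fit` (the best `"blup_fit"`, terms `g` and `tc`), `route`,
#'   `W_c` (at the optimum).
#' @export
fit_gtcblupi <- function(y, X = NULL, geno, W, grid_step = 0.01, grid = NULL,
                         G = NULL, ...) {
  stopifnot(inherits(geno, "genotype_data"))
  W <- as.matrix(W)
  n <- length(y)
  if (nrow(W) != n) stop("`W` rows must match `y`")
  if (is.null(grid)) {
    if (grid_step <= 0 || grid_step >= 0.5) stop("`grid_step` must be in (0, 0.5)")
    grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  }
  if (any(grid <= 0 | grid >= 1)) stop("grid values must lie strictly inside (0, 1)")
  grid <- sort(grid)
  if (is.null(G)) G <- vanraden_g(geno)
  route <- choose_route(n, geno$m)
  k <- ncol(W)

  prof <- data.frame(h2_t = grid, lambda = NA_real_, loglik = NA_real_,
                     converged = FALSE)
  best <- NULL
  best_h2 <- NA_real_
  best_Wc <- NULL
  init <- NULL
  for (i in seq_along(grid)) {
    lam <- lambda_from_h2(grid[i], geno$m_tilde)
    cnd <- if (route == "direct") {
      condition_w_direct(W, geno, lam)
    } else {
      condition_w_woodbury(W, G, geno$m_tilde, lam)
    }
    Tc <- conditioned_t(cnd$W_c, k)
    fit <- tryCatch(
      blup_fit(y, X, K = list(g = G, tc = Tc), init = init, ...),
      error = function(e) NULL)
    prof$lambda[i] <- lam
    if (is.null(fit) || !fit$converged) {
      if (!is.null(fit)) prof$loglik[i] <- fit$loglik
      next
    }
    prof$loglik[i] <- fit$loglik
    prof$converged[i] <- TRUE
    init <- fit$variance_components
    if (is.null(best) || fit$loglik > best$loglik) {   # strict: ties keep smaller h2_t
      best <- fit
      best_h2 <- grid[i]
      best_Wc <- cnd$W_c
    }
  }
  if (is.null(best)) stop("no grid point converged; GTCBLUPi fit failed")
  best$model <- "GTCBLUPi"
  structure(list(h2_t_hat = best_h2,
                 lambda_hat = lambda_from_h2(best_h2, geno$m_tilde),
                 profile = prof, fit = best, route = route, W_c = best_Wc,
                 grid_step = if (length(grid) > 1L) diff(grid)[1L] else NA_real_),
            class = "gtcblupi_fit")
}

#' @export
print.gtcblupi_fit <- function(x, ...) {
  cat(sprintf("GTCBLUPi fit: h2_t = %.3f (lambda = %.2f, %s route, %d grid points)\n",
              x$h2_t_hat, x$lambda_hat, x$route, nrow(x$profile)))
  print(x$fit)
  invisible(x)
}

#' @export
logLik.gtcblupi_fit <- function(object, ...) logLik(object$fit)

#' Plot the GTCBLUPi profile likelihood
#'
#' Restricted log-likelihood of the conditioned model as a function of the
#' transcript-level heritability grid, with the selected value marked.
#'
#' @param x a `"gtcblupi_fit"` object.
#' @param ... passed to `plot()`.
#' @export
plot.gtcblupi_fit <- function(x, ...) {
  ok <- x$profile$converged
  plot(x$profile$h2_t[ok], x$profile$loglik[ok], type = "l",
       xlab = expression(tilde(h)[t]^2), ylab = "REML log-likelihood", ...)
  abline(v = x$h2_t_hat, lty = 2, col = "grey40")
  points(x$h2_t_hat, max(x$profile$loglik[ok]), pch = 19)
  invisible(x)
}

#' Fit the GTCBLUP model (trait-heritability ridge)
#'
#' Same conditioned model as [fit_gtcblupi()], but with the ridge computed
#' from the trait's GBLUP heritability instead of a grid search:
#' \eqn{\lambda = m (1/h^2 - 1)} with \eqn{m} the SNP count (or
#' \eqn{\tilde m} when `use_m_tilde = TRUE`).
#'
#' @inheritParams fit_gtcblupi
#' @param h2 trait heritability; taken from `gblup_fit` when `NULL`.
#' @param gblup_fit a fitted GBLUP model of the same trait (source of `h2`).
#' @param use_m_tilde use \eqn{\tilde m = \sum 2p(1-p)} instead of the SNP
#'   count as the multiplier.
#' @return a `"blup_fit"` object (terms `g`, `tc`) with `$model = "GTCBLUP"`,
#'   `$lambda` and `$h2_source` recorded.
#' @export
fit_gtcblup <- function(y, X = NULL, geno, W, h2 = NULL, gblup_fit = NULL,
                        use_m_tilde = FALSE, G = NULL, ...) {
  stopifnot(inherits(geno, "genotype_data"))
  if (is.null(h2)) {
    if (is.null(gblup_fit)) stop("supply either `h2` or a fitted GBLUP model")
    vp <- variance_proportions(gblup_fit)
    h2 <- vp$proportion[match("g", vp$term)]
    if (is.na(h2)) stop("`gblup_fit` has no term named 'g'")
  }
  if (h2 <= 0) {
    stop("trait heritability is at the zero boundary; lambda = m(1/h2 - 1) is ",
         "undefined. Fit GTBLUP instead, or supply `h2` explicitly.")
  }
  if (h2 >= 1) stop("`h2` must be below 1")
  mult <- if (use_m_tilde) geno$m_tilde else geno$m
  lam <- mult * (1 / h2 - 1)
  if (is.null(G)) G <- vanraden_g(geno)
  route <- choose_route(length(y), geno$m)
  cnd <- if (route == "direct") {
    condition_w_direct(W, geno, lam)
  } else {
    condition_w_woodbury(W, G, geno$m_tilde, lam)
  }
  Tc <- conditioned_t(cnd$W_c, ncol(W))
  fit <- blup_fit(y, X, K = list(g = G, tc = Tc), ...)
  fit$model <- "GTCBLUP"
  fit$lambda <- lam
  fit$h2_source <- h2
  fit
}
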