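#' REML log-likelihood of a multi-kernel mixed model
#'
#' For the model \eqn{y = X b + \sum_i u_i + e} with
#' \eqn{u_i \sim N(0, K_i \sigma^2_i)} and \eqn{e \sim N(0, I \sigma^2_e)},
#' evaluates the restricted log-likelihood
#' \deqn{\ell_R = -\tfrac12\left[(n-p)\log 2\pi + \log|V| +
#'   \log|X^T V^{-1} X| + y^T P y\right]}
#' with \eqn{V = \sum_i K_i \sigma^2_i + I\sigma^2_e} and
#' \eqn{P = V^{-1} - V^{-1} X (X^T V^{-1} X)^{-1} X^T V^{-1}}.
#' The value is exact up to an additive constant (\eqn{+\tfrac12\log|X^TX|},
#' constant across all fits sharing the same `X`).
#'
#' @param y response vector (typically standardized).
#' @param X fixed-effect design matrix of full column rank.
#' @param K list of \eqn{n \times n} covariance kernels.
#' @param sigma2 vector of variance components, one per kernel.
#' @param sigma2_e residual variance.
#' @return scalar restricted log-likelihood.
#' @export
reml_loglik <- function(y, X, K, sigma2, sigma2_e) {
  if (is.matrix(K)) K <- list(K)
  if (length(sigma2) != length(K)) stop("one variance component per kernel required")
  n <- length(y)
  V <- diag(sigma2_e, n)
  for (i in seq_along(K)) V <- V + sigma2[i] * K[[i]]
  .reml_core(y, as.matrix(X), V)$loglik
}

## shared dense REML machinery: loglik, P, Py at a given V
.reml_core <- function(y, X, V) {
  n <- length(y); p <- ncol(X)
  R <- tryCatch(chol(V), error = function(e) {
    stop("V is not positive definite for the given variance components")
  })
  Vi <- chol2inv(R)
  XtVi <- crossprod(X, Vi)              # p x n
  XtViX <- XtVi %*% X
  cX <- tryCatch(chol(symmetrize(XtViX)), error = function(e) {
    stop("X'V^{-1}X is singular; remove aliased fixed-effect columns")
  })
  B <- forwardsolve(t(cX), XtVi)        # p x n
  P <- Vi - crossprod(B)
  Py <- drop(P %*% y)
  yPy <- sum(y * Py)
  loglik <- -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(R))) +
                      2 * sum(log(diag(cX))) + yPy)
  beta <- drop(backsolve(cX, forwardsolve(t(cX), drop(XtVi %*% y))))
  list(loglik = loglik, P = P, Py = Py, Vi = Vi, beta = beta, cX = cX)
}

#' Fit a BLUP mixed model by REML
#'
#' Average-information (AI) REML for \eqn{y = Xb + \sum_i u_i + e} with any
#' number of dense covariance kernels, with safeguarded step-halving, a
#' multiplicative EM-style fallback when the AI update fails, and a floor of
#' `floor_frac * var(y)` on every variance component.  Models with a single
#' kernel use an exact eigendecomposition fast path (the profile likelihood in
#' the variance ratio is maximized by Brent search).
#'
#' BLUPs of the random effects are \eqn{\hat u_i = \sigma^2_i K_i P y}, fixed
#' effects are GLS estimates at the optimum, and standard errors of the
#' variance components come from the inverse AI matrix.
#'
#' @param y response vector (typically Box-Cox transformed and standardized).
#' @param X fixed-effect design matrix; `NULL` means intercept only.  Aliased
#'   columns are dropped with a warning.
#' @param K named list of \eqn{n \times n} covariance kernels (e.g.
#'   `list(g = G, t = T)`).  Residual `I` is always included and need not be
#'   listed.
#' @param ids animal identifiers (default: `names(y)`, then rownames of the
#'   first kernel).
#' @param method `"auto"` (eigen path for one kernel, AI otherwise), `"ai"`
#'   (force the generic dense path) or `"eigen"` (single kernel only).
#' @param init optional starting values, length `length(K) + 1` (residual
#'   last).
#' @param max_iter,tol_loglik,tol_par convergence controls: stop when the
#'   log-likelihood changes by less than `tol_loglik` and every parameter by
#'   less than `tol_par` (relative), or after `max_iter` iterations.
#' @param floor_frac lower bound on each component, as a fraction of `var(y)`.
#' @param verbose print the iteration trace.
#' @return object of class `"blup_fit"`: list with `variance_components`
#'   (named, residual last), `std_errors`, `beta`, `blups` (list of BLUP
#'   vectors per term), `loglik`, `aic`, `converged`, `identifiable`,
#'   `n_iter`, `mean_diag`, `n`, `ids`, `y`, `X`, `trace`.
#' @seealso [gblup()], [tblup()], [gtblup()], [variance_proportions()],
#'   [lrt()]
#' @export
blup_fit <- function(y, X = NULL, K, ids = NULL,
                     method = c("auto", "ai", "eigen"),
                     init = NULL, max_iter = 200L,
                     tol_loglik = 1e-8, tol_par = 1e-6,
                     floor_frac = 1e-8, verbose = FALSE) {
  method <- match.arg(method)
  y <- as.numeric(y)
  n <- length(y)
  if (is.matrix(K)) K <- list(K)
  if (!length(K)) stop("at least one covariance kernel is required")
  K <- lapply(K, as.matrix)
  if (is.null(names(K)) || any(names(K) == "")) {
    names(K) <- sprintf("u%d", seq_along(K))
  }
  if (any(names(K) == "residual")) stop('"residual" is a reserved term name')
  for (nm in names(K)) {
    if (!all(dim(K[[nm]]) == n)) stop(sprintf("kernel '%s' is not %d x %d", nm, n, n))
  }
  if (is.null(ids)) {
    ids <- names(y)
    if (is.null(ids)) ids <- rownames(K[[1L]])
    if (is.null(ids)) ids <- sprintf("id%d", seq_len(n))
  }
  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("`X` must have one row per observation")
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  X <- drop_aliased(X)
  q <- length(K)
  if (method == "eigen" && q != 1L) stop("the eigen path handles exactly one kernel")
  use_eigen <- (method == "eigen") || (method == "auto" && q == 1L)

  fit <- if (use_eigen) {
    .fit_eigen(y, X, K, init = init, floor_frac = floor_frac)
  } else {
    .fit_ai(y, X, K, init = init, max_iter = max_iter,
            tol_loglik = tol_loglik, tol_par = tol_par,
            floor_frac = floor_frac, verbose = verbose)
  }

  theta <- fit$theta
  names(theta) <- c(names(K), "residual")
  ## final quantities at the optimum
  V <- diag(theta[q + 1L], n)
  for (i in seq_len(q)) V <- V + theta[i] * K[[i]]
  core <- .reml_core(y, X, V)
  blups <- lapply(seq_len(q), function(i) {
    u <- drop(theta[i] * (K[[i]] %*% core$Py))
    names(u) <- ids
    u
  })
  names(blups) <- names(K)
  ai <- .ai_matrix(core$P, core$Py, K)
  identifiable <- TRUE
  se <- rep(NA_real_, q + 1L)
  cov_theta <- NULL
  ok <- tryCatch({
    cov_theta <- solve(ai)
    TRUE
  }, error = function(e) FALSE)
  if (ok && all(diag(cov_theta) >= 0)) se <- sqrt(diag(cov_theta))
  if (!ok || rcond(ai) < 1e-12) {
    identifiable <- FALSE
    warning("variance components are not separately identifiable ",
            "(singular average-information matrix); the total variance is still valid")
  }
  names(se) <- names(theta)
  aic <- -2 * core$loglik + 2 * (q + 1L)
  structure(list(variance_components = theta, std_errors = se,
                 beta = structure(core$beta, names = colnames(X)),
                 blups = blups, loglik = core$loglik, aic = aic,
                 converged = fit$converged, identifiable = identifiable,
                 n_iter = fit$n_iter, trace = fit$trace,
                 mean_diag = c(vapply(K, function(k) mean(diag(k)), numeric(1)),
                               residual = 1),
                 n = n, n_fixed = ncol(X), ids = ids, y = y, X = X,
                 term_names = names(K), model = NULL, call = match.call()),
            class = "blup_fit")
}

## AI matrix: AI_ij = 0.5 * y'P K_i P K_j P y, residual kernel last
.ai_matrix <- function(P, Py, K) {
  q <- length(K)
  Q <- matrix(0, length(Py), q + 1L)
  for (i in seq_len(q)) Q[, i] <- K[[i]] %*% Py
  Q[, q + 1L] <- Py
  symmetrize(0.5 * crossprod(Q, P %*% Q))
}

## generic dense AI-REML with EM-style fallback
.fit_ai <- function(y, X, K, init, max_iter, tol_loglik, tol_par,
                    floor_frac, verbose) {
  n <- length(y)
  q <- length(K)
  vy <- stats::var(y)
  floorv <- floor_frac * vy
  theta <- if (!is.null(init)) pmax(as.numeric(init), floorv) else rep(vy / (q + 1L), q + 1L)
  if (length(theta) != q + 1L) stop("`init` must have length(K) + 1 entries")

  eval_core <- function(th) {
    V <- diag(th[q + 1L], n)
    for (i in seq_len(q)) V <- V + th[i] * K[[i]]
    .reml_core(y, X, V)
  }

  core <- eval_core(theta)
  trace <- data.frame(iter = 0L, loglik = core$loglik)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    ## scores and AI at current theta
    trPK <- numeric(q + 1L)
    yPKPy <- numeric(q + 1L)
    for (i in seq_len(q)) {
      trPK[i] <- sum(core$P * K[[i]])
      yPKPy[i] <- sum(core$Py * (K[[i]] %*% core$Py))
    }
    trPK[q + 1L] <- sum(diag(core$P))
    yPKPy[q + 1L] <- sum(core$Py^2)
    score <- -0.5 * (trPK - yPKPy)
    ai <- .ai_matrix(core$P, core$Py, K)

    step_ok <- FALSE
    delta <- tryCatch(solve(ai, score), error = function(e) NULL)
    if (!is.null(delta) && all(is.finite(delta))) {
      step <- 1
      for (h in 1:12) {
        prop <- pmax(theta + step * delta, floorv)
        new_core <- tryCatch(eval_core(prop), error = function(e) NULL)
        if (!is.null(new_core) && is.finite(new_core$loglik) &&
            new_core$loglik >= core$loglik - 1e-10) {
          step_ok <- TRUE
          break
        }
        step <- step / 2
      }
    }
    if (!step_ok) {
      ## multiplicative EM-style fixed-point step (always positive):
      ## sigma_i^2 <- sigma_i^2 * sqrt(y'PK_iPy / tr(PK_i))
      ratio <- sqrt(pmax(yPKPy, 1e-300) / pmax(trPK, 1e-300))
      ratio <- pmin(pmax(ratio, 0.1), 10)
      prop <- pmax(theta * ratio, floorv)
      new_core <- tryCatch(eval_core(prop), error = function(e) NULL)
      if (is.null(new_core) || !is.finite(new_core$loglik)) break
    }
    dll <- new_core$loglik - core$loglik
    dpar <- max(abs(prop - theta) / pmax(theta, floorv))
    theta <- prop
    core <- new_core
    trace <- rbind(trace, data.frame(iter = it, loglik = core$loglik))
    if (verbose) {
      message(sprintf("iter %3d  logL = %.8f  dlogL = %.2e  dpar = %.2e",
                      it, core$loglik, dll, dpar))
    }
    if (abs(dll) < tol_loglik && dpar < tol_par) {
      converged <- TRUE
      break
    }
  }
  if (!converged && max_iter > 0L) {
    ## a boundary solution with a stalled likelihood still counts as converged
    if (nrow(trace) >= 2L &&
        abs(diff(tail(trace$loglik, 2L))) < sqrt(tol_loglik)) converged <- TRUE
  }
  list(theta = theta, converged = converged, n_iter = it, trace = trace)
}

## exact single-kernel path: rotate by the eigenvectors of K, profile out
## sigma2_e, Brent-search the variance ratio
.fit_eigen <- function(y, X, K, init, floor_frac) {
  n <- length(y)
  p <- ncol(X)
  vy <- stats::var(y)
  floorv <- floor_frac * vy
  eg <- eigen(symmetrize(K[[1L]]), symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  ## profile REML loglik in log-ratio r = sigma2_u / sigma2_e
  prof <- function(logr) {
    r <- exp(logr)
    v <- r * d + 1
    w <- 1 / v
    XtWX <- crossprod(Xt * w, Xt)
    cX <- tryCatch(chol(symmetrize(XtWX)), error = function(e) NULL)
    if (is.null(cX)) return(-Inf)
    XtWy <- drop(crossprod(Xt, w * yt))
    bet <- backsolve(cX, forwardsolve(t(cX), XtWy))
    quad <- sum(w * yt^2) - sum(XtWy * bet)
    if (quad <= 0) return(-Inf)
    s2e <- quad / (n - p)
    -0.5 * ((n - p) * (log(2 * pi) + 1 + log(s2e)) + sum(log(v)) +
              2 * sum(log(diag(cX))))
  }
  lo <- log(floorv / vy)      # ratio floor
  hi <- log(1e8)
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-10)
  logr <- opt$maximum
  ## guard the boundaries
  if (prof(lo) >= opt$objective) logr <- lo
  r <- exp(logr)
  v <- r * d + 1
  w <- 1 / v
  XtWX <- crossprod(Xt * w, Xt)
  cX <- chol(symmetrize(XtWX))
  XtWy <- drop(crossprod(Xt, w * yt))
  bet <- backsolve(cX, forwardsolve(t(cX), XtWy))
  quad <- sum(w * yt^2) - sum(XtWy * bet)
  s2e <- quad / (n - p)
  theta <- pmax(c(r * s2e, s2e), floorv)
  list(theta = theta, converged = TRUE, n_iter = NA_integer_,
       trace = data.frame(iter = 0L, loglik = prof(logr)))
}

# ---- convenience model wrappers ---------------------------------------------

#' Fit the GBLUP, TBLUP or GTBLUP model
#'
#' Thin wrappers around [blup_fit()] that build the relationship matrices and
#' label the model:
#' `gblup()` fits \eqn{y = Xb + g + e}, \eqn{g \sim N(0, G\sigma^2_g)};
#' `tblup()` fits \eqn{y = Xb + t + e}, \eqn{t \sim N(0, T\sigma^2_t)};
#' `gtblup()` fits \eqn{y = Xb + g + t + e} with both terms independent.
#'
#' @param y response vector.
#' @param X fixed-effect design (`NULL` = intercept only).
#' @param geno a [genotype_data] object (for `gblup`/`gtblup`).
#' @param W pre-corrected standardized transcript matrix (for
#'   `tblup`/`gtblup`).
#' @param ... passed to [blup_fit()].
#' @return a `"blup_fit"` object with `$model` set.
#' @export
gblup <- function(y, X = NULL, geno, ...) {
  fit <- blup_fit(y, X, K = list(g = vanraden_g(geno)), ...)
  fit$model <- "GBLUP"
  fit
}

#' @rdname gblup
#' @export
tblup <- function(y, X = NULL, W, ...) {
  fit <- blup_fit(y, X, K = list(t = transcript_t(W)), ...)
  fit$model <- "TBLUP"
  fit
}

#' @rdname gblup
#' @export
gtblup <- function(y, X = NULL, geno, W, ...) {
  fit <- blup_fit(y, X, K = list(g = vanraden_g(geno), t = transcript_t(W)), ...)
  fit$model <- "GTBLUP"
  fit
}

# ---- methods ----------------------------------------------------------------

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf("%s mixed model fit by REML (n = %d)\n",
              if (is.null(x$model)) "BLUP" else x$model, x$n))
  vc <- data.frame(sigma2 = x$variance_components, SE = x$std_errors)
  print(round(vc, 4))
  cat(sprintf("REML log-likelihood: %.4f   AIC: %.4f   converged: %s\n",
              x$loglik, x$aic, x$converged))
  invisible(x)
}

#' @export
summary.blup_fit <- function(object, ...) {
  vp <- variance_proportions(object)
  out <- list(fit = object, proportions = vp)
  class(out) <- "summary.blup_fit"
  out
}

#' @export
print.summary.blup_fit <- function(x, ...) {
  print(x$fit)
  cat("\nVariance proportions (mean-diagonal scaled):\n")
  print(x$proportions)
  cat("\nFixed effects:\n")
  print(round(x$fit$beta, 4))
  invisible(x)
}

#' @export
coef.blup_fit <- function(object, ...) object$beta

#' @export
logLik.blup_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$variance_components),
            nobs = object$n, class = "logLik")
}

#' @export
fitted.blup_fit <- function(object, ...) {
  drop(object$X %*% object$beta) + Reduce(`+`, object$blups)
}

#' @export
residuals.blup_fit <- function(object, ...) object$y - fitted(object)

#' Extract BLUPs of the random animal effects
#'
#' @param object a `"blup_fit"` object.
#' @param term term name (default: all terms as a list).
#' @return named vector (one term) or list of named vectors.
#' @export
ranef <- function(object, term = NULL) {
  stopifnot(inherits(object, "blup_fit"))
  if (is.null(term)) return(object$blups)
  if (!term %in% names(object$blups)) stop("unknown term: ", term)
  object$blups[[term]]
}

#' Variance proportions from a fitted BLUP model
#'
#' Each component's contribution to the phenotypic variance is
#' \eqn{\sigma^2_i \cdot \mathrm{mean}(\mathrm{diag}(K_i))}; the mean-diagonal
#' scaling is applied uniformly (it is a no-op for matrices with unit mean
#' diagonal such as \eqn{G}, and yields
#' \eqn{\tilde\sigma^2_{t_c} = \sigma^2_{t_c}\,\mathrm{mean}(\mathrm{diag}(T_c))}
#' for conditioned transcripts).  Proportions sum to one.
#'
#' @param fit a `"blup_fit"` object.
#' @return data.frame with `term`, `sigma2`, `mean_diag`, `scaled_sigma2`,
#'   `proportion`; attribute `scaled_by_mean_diag = TRUE`.
#' @export
variance_proportions <- function(fit) {
  stopifnot(inherits(fit, "blup_fit"))
  sc <- fit$variance_components * fit$mean_diag
  out <- data.frame(term = names(fit$variance_components),
                    sigma2 = unname(fit$variance_components),
                    mean_diag = unname(fit$mean_diag),
                    scaled_sigma2 = unname(sc),
                    proportion = unname(sc / sum(sc)))
  attr(out, "scaled_by_mean_diag") <- TRUE
  out
}

#' Likelihood-ratio test between nested REML fits
#'
#' \deqn{D = 2[\log L_{\mathrm{full}} - \log L_{\mathrm{reduced}}]}
#' compared against a chi-squared distribution with degrees of freedom equal
#' to the difference in the number of variance parameters.  Both fits must
#' share the same response and fixed-effect design.  Because the tested
#' component sits on the boundary of its parameter space under the null, the
#' plain chi-squared p-value is conservative; for a one-parameter test the
#' 50:50 mixture p-value is also reported (attribute `"p_mixture"`).
#'
#' @param full,reduced `"blup_fit"` objects, `reduced` nested in `full`.
#' @return list with `D`, `df`, `p`; attribute `p_mixture` when `df == 1`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "blup_fit"), inherits(reduced, "blup_fit"))
  if (full$n != reduced$n) stop("fits are not on the same data")
  df <- length(full$variance_components) - length(reduced$variance_components)
  if (df < 0L) stop("`full` has fewer variance parameters than `reduced`")
  D <- 2 * (full$loglik - reduced$loglik)
  if (D < -1e-6) {
    stop("negative deviance (D = ", format(D),
         "): models are not nested or a fit did not converge")
  }
  D <- max(D, 0)
  p <- if (df == 0L) 1 else stats::pchisq(D, df, lower.tail = FALSE)
  out <- list(D = D, df = df, p = p)
  if (df == 1L) {
    attr(out, "p_mixture") <- if (D == 0) 1 else 0.5 * stats::pchisq(D, 1, lower.tail = FALSE)
  }
  out
}
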