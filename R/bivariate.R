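#' Bivariate TBLUP for transcriptomic trait correlations
#'
#' Fits the two-trait model
#' \deqn{\begin{pmatrix} y_1 \\ y_2 \end{pmatrix} = (I_2 \otimes X) b +
#'   t + e, \qquad t \sim N(0, \Sigma_t \otimes T), \quad
#'   e \sim N(0, \Sigma_e \otimes I)}
#' by direct maximization of the bivariate REML log-likelihood.  The 2x2
#' transcriptomic and residual covariance matrices are parameterized by their
#' Cholesky factors (log-diagonal), which guarantees positive
#' semidefiniteness; the transcriptomic correlation
#' \eqn{r_t = \Sigma_t[1,2]/\sqrt{\Sigma_t[1,1]\Sigma_t[2,2]}} is read off
#' afterwards, with a delta-method standard error from the numerical
#' information matrix.
#'
#' Computationally, \eqn{T} is eigendecomposed once; rotating both traits by
#' the eigenvectors turns the \eqn{2n \times 2n} covariance into \eqn{n}
#' independent 2x2 blocks, so each likelihood evaluation is \eqn{O(np^2)}.
#' The optimizer is multi-started from the univariate TBLUP fits with
#' starting correlations 0 and \eqn{\pm 0.8}.
#'
#' The residual cross-trait covariance is estimated by default (the same
#' animals are measured for both traits; forcing it to zero would confound
#' the transcriptomic correlation) and can be fixed at zero with
#' `fix_re_zero = TRUE`.
#'
#' @param y1,y2 phenotype vectors for the two traits (same animals, same
#'   order).
#' @param X fixed-effect design (shared by both traits; `NULL` = intercept).
#' @param T_mat transcriptomic relationship matrix.
#' @param fix_rt_zero constrain the transcriptomic correlation to zero
#'   (the null model of [correlation_lrt()]).
#' @param fix_re_zero constrain the residual correlation to zero.
#' @param starts correlation starting values for multi-start.
#' @return object of class `"bivariate_fit"`: `Sigma_t`, `Sigma_e`, `r_t`,
#'   `r_e`, `se_r_t`, `loglik`, `converged`, `n`.
#' @export
fit_bivariate_tblup <- function(y1, y2, X = NULL, T_mat,
                                fix_rt_zero = FALSE, fix_re_zero = FALSE,
                                starts = c(0, 0.8, -0.8)) {
  n <- length(y1)
  if (length(y2) != n) stop("`y1` and `y2` must cover the same animals")
  T_mat <- as.matrix(T_mat)
  if (!all(dim(T_mat) == n)) stop("`T_mat` must be n x n")
  if (is.null(X)) X <- matrix(1, n, 1L)
  X <- drop_aliased(as.matrix(X), warn = FALSE)
  p <- ncol(X)

  eg <- eigen(symmetrize(T_mat), symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  z1 <- drop(crossprod(U, y1))
  z2 <- drop(crossprod(U, y2))
  Xt <- crossprod(U, X)

  ## free parameters: Cholesky factors of Sigma_t then Sigma_e;
  ## off-diagonals dropped when fixed at zero
  build <- function(th) {
    i <- 0L
    lt11 <- exp(th[i <- i + 1L])
    lt21 <- if (fix_rt_zero) 0 else th[i <- i + 1L]
    lt22 <- exp(th[i <- i + 1L])
    le11 <- exp(th[i <- i + 1L])
    le21 <- if (fix_re_zero) 0 else th[i <- i + 1L]
    le22 <- exp(th[i <- i + 1L])
    St <- matrix(c(lt11^2, lt11 * lt21, lt11 * lt21, lt21^2 + lt22^2), 2L)
    Se <- matrix(c(le11^2, le11 * le21, le11 * le21, le21^2 + le22^2), 2L)
    list(St = St, Se = Se)
  }

  negll <- function(th) {
    S <- build(th)
    v11 <- S$St[1, 1] * d + S$Se[1, 1]
    v12 <- S$St[1, 2] * d + S$Se[1, 2]
    v22 <- S$St[2, 2] * d + S$Se[2, 2]
    det <- v11 * v22 - v12^2
    if (any(det <= 0) || any(v11 <= 0)) return(1e10)
    w11 <- v22 / det
    w12 <- -v12 / det
    w22 <- v11 / det
    A11 <- crossprod(Xt * w11, Xt)
    A12 <- crossprod(Xt * w12, Xt)
    A22 <- crossprod(Xt * w22, Xt)
    A <- rbind(cbind(A11, A12), cbind(A12, A22))
    cA <- tryCatch(chol(symmetrize(A)), error = function(e) NULL)
    if (is.null(cA)) return(1e10)
    c1 <- drop(crossprod(Xt, w11 * z1 + w12 * z2))
    c2 <- drop(crossprod(Xt, w12 * z1 + w22 * z2))
    cc <- c(c1, c2)
    s <- sum(w11 * z1^2 + 2 * w12 * z1 * z2 + w22 * z2^2)
    bb <- backsolve(cA, forwardsolve(t(cA), cc))
    yPy <- s - sum(cc * bb)
    ll <- -0.5 * ((2 * n - 2 * p) * log(2 * pi) + sum(log(det)) +
                    2 * sum(log(diag(cA))) + yPy)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  ## univariate starting variances
  uni <- function(z) {
    .fit_eigen(as.numeric(z), X, list(T_mat), init = NULL, floor_frac = 1e-8)$theta
  }
  th1 <- uni(y1)
  th2 <- uni(y2)
  mk_start <- function(rt) {
    s_t <- c(th1[1L], th2[1L])
    s_e <- c(th1[2L], th2[2L])
    lt11 <- sqrt(s_t[1L])
    lt21 <- if (fix_rt_zero) NULL else rt * sqrt(s_t[2L])
    lt22 <- sqrt(s_t[2L] * max(1 - rt^2, 1e-4))
    le11 <- sqrt(s_e[1L])
    le21 <- if (fix_re_zero) NULL else 0
    le22 <- sqrt(s_e[2L])
    c(log(lt11), lt21, log(lt22), log(le11), le21, log(le22))
  }
  n_par <- 6L - fix_rt_zero - fix_re_zero
  is_diag_log <- rep(FALSE, n_par)
  i <- 0L
  is_diag_log[i <- i + 1L] <- TRUE
  if (!fix_rt_zero) i <- i + 1L
  is_diag_log[i <- i + 1L] <- TRUE
  is_diag_log[i <- i + 1L] <- TRUE
  if (!fix_re_zero) i <- i + 1L
  is_diag_log[i <- i + 1L] <- TRUE
  lower <- ifelse(is_diag_log, -8, -20)
  upper <- ifelse(is_diag_log, 4, 20)

  best <- NULL
  for (rt in (if (fix_rt_zero) 0 else starts)) {
    st <- pmin(pmax(mk_start(rt), lower), upper)
    opt <- tryCatch(
      stats::optim(st, negll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500L, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("bivariate REML optimization failed from every start")
  th <- best$par
  S <- build(th)
  r_t <- S$St[1, 2] / sqrt(S$St[1, 1] * S$St[2, 2])
  r_e <- S$Se[1, 2] / sqrt(S$Se[1, 1] * S$Se[2, 2])

  ## delta-method SE of r_t from the numerical information matrix
  se_r_t <- NA_real_
  if (!fix_rt_zero) {
    H <- tryCatch(stats::optimHess(th, negll), error = function(e) NULL)
    if (!is.null(H)) {
      covp <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(covp)) {
        gr <- numeric(length(th))
        h <- 1e-5
        for (j in seq_along(th)) {
          tp <- th; tm <- th
          tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
          rp <- with(build(tp), St[1, 2] / sqrt(St[1, 1] * St[2, 2]))
          rm <- with(build(tm), St[1, 2] / sqrt(St[1, 1] * St[2, 2]))
          gr[j] <- (rp - rm) / (2 * h)
        }
        v <- drop(crossprod(gr, covp %*% gr))
        if (is.finite(v) && v >= 0) se_r_t <- sqrt(v)
      }
    }
  }
  structure(list(Sigma_t = S$St, Sigma_e = S$Se, r_t = r_t, r_e = r_e,
                 se_r_t = se_r_t, loglik = -best$value,
                 converged = best$convergence == 0, n = n,
                 fix_rt_zero = fix_rt_zero, fix_re_zero = fix_re_zero),
            class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf("Bivariate TBLUP (n = %d): r_t = %.3f (SE %.3f), r_e = %.3f\n",
              x$n, x$r_t, x$se_r_t, x$r_e))
  cat(sprintf("  REML log-likelihood %.4f, converged: %s\n", x$loglik, x$converged))
  invisible(x)
}

#' @export
logLik.bivariate_fit <- function(object, ...) {
  structure(object$loglik,
            df = 6L - object$fix_rt_zero - object$fix_re_zero,
            class = "logLik")
}

#' Likelihood-ratio test of zero transcriptomic correlation
#'
#' Refits the bivariate model with the transcriptomic correlation constrained
#' to zero (diagonal \eqn{\Sigma_t}) and compares
#' \eqn{D = 2[\log L_{full} - \log L_0]} with \eqn{\chi^2_1}.
#'
#' @param full a converged full `"bivariate_fit"`.
#' @param y1,y2,X,T_mat the data the full model was fitted to.
#' @param ... passed to [fit_bivariate_tblup()] for the constrained fit.
#' @return list with `D`, `p`, `constrained` (the null fit).
#' @export
correlation_lrt <- function(full, y1, y2, X = NULL, T_mat, ...) {
  stopifnot(inherits(full, "bivariate_fit"))
  if (!full$converged) stop("the full bivariate fit did not converge")
  null_fit <- fit_bivariate_tblup(y1, y2, X, T_mat, fix_rt_zero = TRUE,
                                  fix_re_zero = full$fix_re_zero, ...)
  D <- 2 * (full$loglik - null_fit$loglik)
  if (D < -1e-6) {
    stop("negative deviance in correlation LRT; the full fit is not at its optimum")
  }
  D <- max(D, 0)
  list(D = D, p = stats::pchisq(D, df = 1L, lower.tail = FALSE),
       constrained = null_fit)
}
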