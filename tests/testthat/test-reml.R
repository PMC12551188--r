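test_that("reml_loglik matches the closed form for the iid intercept model", {
  set.seed(51)
  n <- 40
  y <- rnorm(n, 2, 1.3)
  X <- matrix(1, n, 1)
  s2 <- 0.7; s2e <- 0.5           # K = I: total variance s2 + s2e
  sig <- s2 + s2e
  SS <- sum((y - mean(y))^2)
  closed <- -0.5 * ((n - 1) * (log(2 * pi) + log(sig)) + log(n) + SS / sig)
  expect_equal(reml_loglik(y, X, list(diag(n)), s2, s2e), closed, tolerance = 1e-10)
})

test_that("scaling the response shifts the REML log-likelihood analytically", {
  set.seed(52)
  n <- 30
  K <- tcrossprod(matrix(rnorm(n * 5), n, 5)) / 5
  y <- rnorm(n)
  X <- cbind(1, rnorm(n))
  c0 <- 3
  l1 <- reml_loglik(y, X, list(K), 0.4, 0.6)
  l2 <- reml_loglik(c0 * y, X, list(K), c0^2 * 0.4, c0^2 * 0.6)
  expect_equal(l2, l1 - (n - 2) * log(c0), tolerance = 1e-8)
})

test_that("reml_loglik agrees with the naive explicit-inversion oracle", {
  set.seed(53)
  n <- 50
  K1 <- tcrossprod(matrix(rnorm(n * 20), n, 20)) / 20
  K2 <- tcrossprod(matrix(rnorm(n * 8), n, 8)) / 8
  y <- rnorm(n)
  X <- cbind(1, rbinom(n, 1, 0.5))
  for (s in list(c(0.5, 0.2, 0.8), c(1.2, 0.01, 0.3))) {
    expect_equal(reml_loglik(y, X, list(K1, K2), s[1:2], s[3]),
                 naive_reml_loglik(y, X, list(K1, K2), s[1:2], s[3]),
                 tolerance = 1e-8)
  }
  expect_error(reml_loglik(y, X, list(K1), -2, 0.001), "positive definite")
})

test_that("blup_fit recovers simulated variance components (GBLUP)", {
  geno <- iid_genotypes(500, 600, seed = 54)
  set.seed(55)
  g <- drop(geno$Z %*% rnorm(600, sd = sqrt(0.3 / geno$m_tilde)))
  y <- g + rnorm(500, sd = sqrt(0.7))
  fit <- gblup(y, NULL, geno)
  expect_true(fit$converged)
  expect_lt(abs(fit$variance_components[["g"]] - 0.3),
            3 * fit$std_errors[["g"]])
  ## heritability proportion near 0.3
  vp <- variance_proportions(fit)
  expect_lt(abs(vp$proportion[1] - 0.3), 0.15)
})

test_that("a null component is estimated at the boundary", {
  set.seed(56)
  sim <- small_dataset(seed = 57)
  y <- rnorm(length(sim$pheno$y))          # noise only: both components null
  f <- suppressWarnings(gtblup(y, NULL, sim$geno, sim$transcripts$W))
  expect_lt(f$variance_components[["t"]], 0.05)
})

test_that("the eigen fast path agrees with the generic dense AI path", {
  sim <- small_dataset(seed = 58)
  y <- sim$pheno$y; X <- sim$pheno$X
  G <- vanraden_g(sim$geno)
  fe <- blup_fit(y, X, list(g = G), method = "eigen")
  fa <- blup_fit(y, X, list(g = G), method = "ai")
  expect_lt(abs(fe$loglik - fa$loglik), 1e-6)
  expect_lt(max(abs(fe$variance_components - fa$variance_components)), 1e-4)
})

test_that("the fit is a local REML maximum and satisfies the MME identity", {
  sim <- small_dataset(seed = 59)
  y <- sim$pheno$y; X <- sim$pheno$X
  G <- vanraden_g(sim$geno)
  Tm <- transcript_t(sim$transcripts$W)
  fit <- blup_fit(y, X, list(g = G, t = Tm))
  th <- fit$variance_components
  l0 <- reml_loglik(y, fit$X, list(G, Tm), th[1:2], th[3])
  expect_equal(l0, fit$loglik, tolerance = 1e-8)
  for (i in 1:3) {
    for (f in c(0.99, 1.01)) {
      th2 <- th; th2[i] <- th2[i] * f
      expect_lte(reml_loglik(y, fit$X, list(G, Tm), th2[1:2], th2[3]),
                 l0 + 1e-6)
    }
  }
  ## MME identity: y = X beta + sum(u_i) + sigma2_e * Py
  V <- th[1] * G + th[2] * Tm + diag(th[3], fit$n)
  Vi <- solve(V)
  P <- Vi - Vi %*% fit$X %*% solve(t(fit$X) %*% Vi %*% fit$X, t(fit$X) %*% Vi)
  res <- y - drop(fit$X %*% fit$beta) - Reduce(`+`, fit$blups) -
    th[3] * drop(P %*% y)
  expect_lt(max(abs(res)), 1e-8 * max(abs(y)))
})

test_that("an unidentifiable variance split is flagged", {
  set.seed(60)
  y <- rnorm(80, sd = 2)
  expect_warning(fit <- blup_fit(y, NULL, list(dup = diag(80)), method = "ai"),
                 "identifiable")
  total <- sum(fit$variance_components)
  expect_lt(abs(total - var(y)) / var(y), 0.2)
})

test_that("AIC counts variance parameters only and lrt follows the chi-square", {
  sim <- small_dataset(seed = 61)
  y <- sim$pheno$y; X <- sim$pheno$X
  G <- vanraden_g(sim$geno)
  Tm <- transcript_t(sim$transcripts$W)
  f1 <- blup_fit(y, X, list(g = G))
  f2 <- blup_fit(y, X, list(g = G, t = Tm))
  expect_equal(f1$aic, -2 * f1$loglik + 2 * 2)
  expect_equal(AIC(f1), f1$aic)
  expect_equal(AIC(f2) - AIC(f1), -2 * (f2$loglik - f1$loglik) + 2)

  out <- lrt(f2, f1)
  expect_equal(out$D, 2 * (f2$loglik - f1$loglik))
  expect_equal(out$p, pchisq(out$D, 1, lower.tail = FALSE))
  expect_equal(attr(out, "p_mixture"), out$p / 2)
  same <- lrt(f1, f1)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
})

test_that("variance proportions apply mean-diagonal scaling and sum to one", {
  fit <- structure(list(variance_components = c(g = 1, tc = 1, residual = 2),
                        mean_diag = c(g = 1, tc = 0.8, residual = 1)),
                   class = "blup_fit")
  vp <- variance_proportions(fit)
  expect_equal(vp$scaled_sigma2, c(1, 0.8, 2))
  expect_equal(sum(vp$proportion), 1)
  expect_equal(vp$proportion, c(1, 0.8, 2) / 3.8)
  expect_true(attr(vp, "scaled_by_mean_diag"))
})
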