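test_that("vanraden_g matches the hand-computed two-animal example", {
  ## dosages (0, 2) at one SNP, p = 0.5: Z = (-1, 1), m_tilde = 0.5
  geno <- genotype_data(matrix(c(0, 2), 2, 1), ids = c("a", "b"))
  G <- vanraden_g(geno)
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE)
})

test_that("G is symmetric with near-unit mean diagonal on F2 data", {
  sim <- small_dataset(seed = 21)
  G <- vanraden_g(sim$geno)
  expect_lt(max(abs(G - t(G))), 1e-10)
  expect_gt(mean(diag(G)), 0.8)
  expect_lt(mean(diag(G)), 1.2)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
})

test_that("monomorphic SNPs are excluded from Z and m_tilde", {
  dos <- cbind(fixed = c(2, 2, 2), seg = c(0, 1, 2))
  geno <- genotype_data(dos)
  expect_equal(geno$m, 1L)
  expect_equal(geno$m_tilde, 2 * 0.5 * 0.5)
  expect_error(genotype_data(matrix(2, 3, 2)), "monomorphic")
})

test_that("transcript_t satisfies its defining properties", {
  set.seed(31)
  ## a full orthogonal basis scaled by sqrt(k) gives T = I (k = n)
  k <- 40
  Q <- qr.Q(qr(matrix(rnorm(40 * k), 40, k))) * sqrt(k)
  expect_equal(unname(transcript_t(Q)), diag(40), tolerance = 1e-10,
               ignore_attr = TRUE)
  ## duplicated animal rows give identical rows/cols of T
  W <- iid_W(20, 8, seed = 32)
  W[2, ] <- W[1, ]
  Tm <- transcript_t(W)
  expect_equal(Tm[1, ], Tm[2, ], ignore_attr = TRUE)
  ## PSD with rank bounded by k
  W2 <- matrix(rnorm(50 * 77), 50, 77)
  ev <- eigen(transcript_t(W2), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
  expect_error(transcript_t(matrix(numeric(0), 5, 0)), "at least one")
})

test_that("lambda_from_h2 implements m_tilde * (1/h2 - 1)", {
  expect_equal(lambda_from_h2(0.25, 1), 3)
  expect_equal(lambda_from_h2(0.5, 2), 2)
  expect_lt(lambda_from_h2(1 - 1e-9, 1), 1e-6)    # h2 -> 1: lambda -> 0
  expect_gt(lambda_from_h2(1e-9, 1), 1e8)         # h2 -> 0: lambda -> infinity
  expect_error(lambda_from_h2(0, 1), "inside")
  expect_error(lambda_from_h2(1, 1), "inside")
})

test_that("conditioning limits: lambda -> infinity and Z = 0 leave W unchanged", {
  set.seed(41)
  geno <- iid_genotypes(25, 40, seed = 41)
  W <- iid_W(25, 6, seed = 42)
  out <- condition_w_direct(W, geno, 1e12)
  expect_lt(max(abs(out$W_c - W)), 1e-4 * max(abs(W)))
  G <- vanraden_g(geno)
  outw <- condition_w_woodbury(W, G, geno$m_tilde, 1e12)
  expect_lt(max(abs(outw$W_c - W)), 1e-4 * max(abs(W)))
  expect_lt(max(abs(condition_w_woodbury(W, G * 0, geno$m_tilde, 5)$W_c - W)), 1e-12)
})

test_that("lambda -> 0 with full-rank Z projects W off the genotype space", {
  geno <- iid_genotypes(30, 10, seed = 43)   # n > m, Z full column rank
  W <- iid_W(30, 5, seed = 44)
  out <- condition_w_direct(W, geno, 1e-8)
  expect_lt(max(abs(crossprod(geno$Z, out$W_c))), 1e-5)
})

test_that("direct and Woodbury conditioning agree across n>m, n<m, n=m", {
  set.seed(45)
  cfgs <- expand.grid(n = c(20, 40), m = c(20, 40, 120), lam_scale = c(0.3, 3))
  for (i in seq_len(nrow(cfgs))) {
    n <- cfgs$n[i]; m <- cfgs$m[i]
    geno <- iid_genotypes(n, m, seed = 100 + i)
    W <- iid_W(n, 7, seed = 200 + i)
    lam <- cfgs$lam_scale[i] * geno$m_tilde
    d <- condition_w_direct(W, geno, lam)
    w <- condition_w_woodbury(W, vanraden_g(geno), geno$m_tilde, lam)
    expect_lt(rel_frob(w$W_c, d$W_c), 1e-8)
  }
})

test_that("the smoother is a shrinker: eigenvalues in [0, 1), T_c diag shrinks", {
  geno <- iid_genotypes(20, 30, seed = 46)
  Z <- geno$Z
  lam <- 2
  S <- Z %*% solve(crossprod(Z) + diag(lam, ncol(Z)), t(Z))
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
  expect_lt(max(ev), 1)
  W <- iid_W(20, 6, seed = 47)
  Tm <- transcript_t(W)
  for (h2 in c(0.9, 0.5, 0.05)) {
    Tc <- conditioned_t(condition_w_direct(W, geno, lambda_from_h2(h2, geno$m_tilde)))
    expect_lte(mean(diag(Tc)), mean(diag(Tm)) + 1e-10)
  }
  ## continuity: tiny h2 (huge lambda) keeps T_c close to T
  Tc <- conditioned_t(condition_w_direct(W, geno, lambda_from_h2(0.002, geno$m_tilde)))
  expect_lt(rel_frob(Tc, Tm), 0.05)
})

test_that("choose_route follows the animals-versus-SNPs rule with direct ties", {
  expect_equal(choose_route(480, 4000), "woodbury")
  expect_equal(choose_route(4000, 480), "direct")
  expect_equal(choose_route(100, 100), "direct")
})
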