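test_that("random folds have exact 80/20 sizes and are reproducible", {
  ids <- sprintf("a%03d", 1:480)
  fp <- make_folds(ids, "random", 0.2, n_reps = 20, seed = 1)
  expect_length(fp$folds, 20L)
  expect_true(all(vapply(fp$folds, function(f) length(f$validation), integer(1)) == 96L))
  expect_true(all(vapply(fp$folds, function(f) length(f$reference), integer(1)) == 384L))
  for (f in fp$folds) {
    expect_length(intersect(f$reference, f$validation), 0L)
    expect_setequal(c(f$reference, f$validation), ids)
  }
  expect_identical(make_folds(ids, "random", 0.2, n_reps = 20, seed = 1), fp)
})

test_that("family folds enumerate all group combinations", {
  ids <- sprintf("q%03d", 1:100)
  groups <- rep(sprintf("fam%d", 1:10), each = 10)
  fp <- make_folds(ids, "family", 0.2, groups = groups)
  expect_length(fp$folds, choose(10, 2))
  for (f in fp$folds) {
    vg <- unique(groups[match(f$validation, ids)])
    rg <- unique(groups[match(f$reference, ids)])
    expect_length(vg, 2L)
    expect_length(rg, 8L)
    expect_length(intersect(vg, rg), 0L)
  }
  ## every animal validated at least once across folds
  val_all <- unique(unlist(lapply(fp$folds, `[[`, "validation")))
  expect_setequal(val_all, ids)
  expect_error(make_folds(ids, "family", 0.2), "requires")
  expect_error(make_folds(ids[1:10], "random", 0.02), "empty")
})

test_that("validation prediction interpolates duplicated animals exactly", {
  set.seed(81)
  n <- 40
  W <- iid_W(n, 12, seed = 81)
  K <- transcript_t(W)
  ids <- rownames(W)
  ## make validation animal identical (in K) to reference animal 1
  K[n, ] <- K[1, ]; K[, n] <- K[, 1]; K[n, n] <- K[1, 1]
  y <- rnorm(n)
  ref <- ids[1:(n - 1)]
  fit <- blup_fit(y[1:(n - 1)], NULL, list(t = K[ref, ref]), ids = ref)
  pred <- predict_validation(fit, list(t = K), ids[n])
  expect_lt(abs(pred - fit$blups$t[1]), 1e-4 * max(abs(fit$blups$t)))
  ## zero cross-block gives zero predictions
  K0 <- K; K0[n, 1:(n - 1)] <- 0; K0[1:(n - 1), n] <- 0
  expect_equal(unname(predict_validation(fit, list(t = K0), ids[n])), 0)
})

test_that("conditional-expectation prediction matches the MME-masking oracle", {
  sim <- small_dataset(seed = 82)
  y <- sim$pheno$y; X <- sim$pheno$X
  G <- vanraden_g(sim$geno)
  ids <- names(y)
  fp <- make_folds(ids, "random", 0.2, n_reps = 2, seed = 3)
  ycorr <- qr.resid(qr(X), y); names(ycorr) <- ids
  for (f in fp$folds) {
    fit <- blup_fit(y[f$reference], X[f$reference, , drop = FALSE],
                    list(g = G[f$reference, f$reference]), ids = f$reference)
    pred <- predict_validation(fit, list(g = G), f$validation)
    ## oracle: Henderson MME over all animals, validation records masked
    s2g <- fit$variance_components[["g"]]
    s2e <- fit$variance_components[["residual"]]
    Zinc <- matrix(0, length(f$reference), length(ids))
    Zinc[cbind(seq_along(f$reference), match(f$reference, ids))] <- 1
    Xr <- X[f$reference, , drop = FALSE]
    Ginv <- solve(G + diag(1e-6 * mean(diag(G)), nrow(G)))
    C <- rbind(cbind(crossprod(Xr), crossprod(Xr, Zinc)),
               cbind(crossprod(Zinc, Xr), crossprod(Zinc) + Ginv * (s2e / s2g)))
    sol <- solve(C, c(crossprod(Xr, y[f$reference]),
                      crossprod(Zinc, y[f$reference])))
    u_all <- sol[-seq_len(ncol(X))]
    names(u_all) <- ids
    a1 <- accuracy(pred, ycorr[f$validation])
    a2 <- accuracy(u_all[f$validation], ycorr[f$validation])
    expect_lt(abs(a1 - a2), 0.005)
  }
})

test_that("accuracy behaves as a correlation with pre-correction", {
  set.seed(83)
  n <- 60
  X <- model.matrix(~factor(rep(1:3, each = n / 3)))
  y <- rnorm(n) + rep(c(0, 1, -1), each = n / 3)
  yc <- qr.resid(qr(X), y)
  expect_equal(accuracy(yc, y, X), 1)
  expect_equal(accuracy(-yc, y, X), -1)
  ## invariance to location/positive scale of predictions
  p <- rnorm(n)
  expect_equal(accuracy(p, y, X), accuracy(5 + 2 * p, y, X))
  expect_warning(a <- accuracy(rep(1, n), y, X), "zero variance")
  expect_true(is.na(a))
  ## null distribution: mean near 0, sd near 1/sqrt(n-1)
  rs <- replicate(400, accuracy(rnorm(96), rnorm(96)))
  expect_lt(abs(mean(rs)), 0.02)
  expect_lt(abs(sd(rs) - 1 / sqrt(95)), 0.02)
})

test_that("Fisher z machinery is exact and round-trips", {
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  r <- seq(-0.99, 0.99, by = 0.03)
  expect_lt(max(abs(fisher_z_inv(fisher_z(r)) - r)), 1e-12)
  ci <- fisher_ci(c(0, 0, 0))
  expect_equal(unlist(ci[c("mean_r", "lo", "hi")]),
               c(mean_r = 0, lo = 0, hi = 0))
  expect_warning(fisher_ci(c(0.5, 1)), "clipped")
})

test_that("paired comparisons flag constant differences and identical models", {
  acc <- cbind(A = c(0.3, 0.4, 0.35, 0.25), B = c(0.3, 0.4, 0.35, 0.25))
  cv <- structure(list(accuracy = acc, n_folds = 4,
                       folds = structure(list(scheme = "random"),
                                         class = "fold_plan")),
                  class = "cv_result")
  cmp <- compare_models(cv, "A", "B")
  expect_equal(cmp$mean_diff, 0)
  expect_false(cmp$significant)
  acc2 <- cbind(A = c(0.3, 0.4, 0.35), B = c(0.2, 0.3, 0.25))
  cv2 <- structure(list(accuracy = acc2), class = "cv_result")
  cmp2 <- compare_models(cv2, "A", "B")
  expect_equal(cmp2$mean_diff, 0.1)
  expect_true(cmp2$significant)
  expect_error(compare_models(cv2, "A", "Z"), "not in CV result")
})

test_that("the CV loop is reproducible and models share folds", {
  sim <- small_dataset(n_f1_sires = 4, f2_per_mating = 10, n_snps = 200,
                       k = 20, seed = 84)
  y <- sim$pheno$y; X <- sim$pheno$X
  kern <- list(GBLUP = list(g = vanraden_g(sim$geno)),
               TBLUP = list(t = transcript_t(sim$transcripts$W)))
  fp <- make_folds(names(y), "random", 0.2, n_reps = 4, seed = 9)
  cv1 <- cross_validate(y, X, kern, fp)
  cv2 <- cross_validate(y, X, kern, fp)
  expect_identical(cv1$accuracy, cv2$accuracy)
  expect_equal(cv1$n_folds, 4L)
  expect_true(all(is.finite(cv1$accuracy)))
  cmp <- compare_models(cv1, "TBLUP", "GBLUP")
  expect_length(cmp$per_fold_diff, 4L)
})
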