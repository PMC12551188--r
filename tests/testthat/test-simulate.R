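test_that("simulate_pedigree reproduces the requested F2 design", {
  ped <- simulate_pedigree(12, 10, 20, 24, seed = 1)
  f2 <- ped[ped$generation == "F2", ]
  expect_equal(nrow(f2), 480L)
  expect_equal(length(unique(f2$family_group)), 10L)
  expect_true(all(f2$family_group == f2$sire_id))
  ## every F2 has exactly one F1 sire and one F1 dam
  f1 <- ped$animal_id[ped$generation == "F1"]
  expect_true(all(f2$sire_id %in% f1) && all(f2$dam_id %in% f1))
  ## parents precede offspring
  pos <- match(ped$animal_id, ped$animal_id)
  expect_true(all(is.na(ped$sire_id) |
                    match(ped$sire_id, ped$animal_id) < seq_len(nrow(ped))))

  tiny <- simulate_pedigree(2, 1, 2, 1, seed = 1)
  expect_equal(sum(tiny$generation == "F2"), 2L)
  expect_equal(length(unique(tiny$family_group[tiny$generation == "F2"])), 1L)

  expect_identical(simulate_pedigree(12, 5, 10, 10, seed = 7),
                   simulate_pedigree(12, 5, 10, 10, seed = 7))
  expect_error(simulate_pedigree(12, 5, 12, 10), "1:2")
  expect_error(simulate_pedigree(0, 5, 10, 10), "positive")
})

test_that("gene dropping conserves parental alleles at every locus", {
  ped <- simulate_pedigree(4, 2, 4, 3, seed = 2)
  geno <- simulate_genotypes(ped, n_snps = 50, seed = 3)
  H <- attr(geno, "haplotypes")
  for (i in which(ped$generation != "founder")) {
    s <- match(ped$sire_id[i], ped$animal_id)
    d <- match(ped$dam_id[i], ped$animal_id)
    expect_true(all(H$H1[i, ] == H$H1[s, ] | H$H1[i, ] == H$H2[s, ]))
    expect_true(all(H$H2[i, ] == H$H1[d, ] | H$H2[i, ] == H$H2[d, ]))
  }
  ## determinism
  geno2 <- simulate_genotypes(ped, n_snps = 50, seed = 3)
  expect_identical(geno$dosages, geno2$dosages)
})

test_that("offspring of two dosage-0 parents are dosage 0 (Mendelian certainty)", {
  ped <- simulate_pedigree(2, 1, 2, 4, seed = 4)
  geno <- simulate_genotypes(ped, n_snps = 20, seed = 5)
  dos <- geno$dosages
  f2 <- ped[ped$generation == "F2", ]
  for (i in seq_len(nrow(f2))) {
    s <- dos[f2$sire_id[i], ]
    d <- dos[f2$dam_id[i], ]
    o <- dos[f2$animal_id[i], ]
    expect_true(all(o[s == 0 & d == 0] == 0))
    expect_true(all(o[s == 2 & d == 2] == 2))
  }
})

test_that("F2 allele frequencies track the founder mean", {
  devs <- replicate(15, {
    ped <- simulate_pedigree(8, 4, 8, 10, seed = NULL)
    geno <- simulate_genotypes(ped, n_snps = 200)
    f2 <- ped$animal_id[ped$generation == "F2"]
    founders <- ped$animal_id[ped$generation == "founder"]
    mean(colMeans(geno$dosages[f2, ]) / 2) -
      mean(colMeans(geno$dosages[founders, ]) / 2)
  })
  ## drift through 12 F1 parents: mean deviation should be near zero
  expect_lt(abs(mean(devs)), 0.02)
})

test_that("paternal half-sibs match the tabular pedigree relationship oracle", {
  ped <- simulate_pedigree(6, 3, 6, 8, seed = 6)
  A <- tabular_A(ped)
  f2 <- ped[ped$generation == "F2", ]
  half_sibs <- A[f2$animal_id, f2$animal_id]
  same_sire <- outer(f2$sire_id, f2$sire_id, "==")
  diag(same_sire) <- FALSE
  expect_true(all(half_sibs[same_sire] >= 0.25))
  ## genomic relationships should correlate with pedigree ones
  geno <- simulate_genotypes(ped, n_snps = 500, seed = 7)
  G <- vanraden_g(subset_genotypes(geno, f2$animal_id))
  off <- upper.tri(G)
  expect_gt(cor(G[off], half_sibs[off]), 0.6)
})

test_that("transcript columns carry the requested heritable fraction", {
  geno <- iid_genotypes(300, 400, seed = 8)
  st <- simulate_transcripts(geno, k = 40, h2_transcript = 0.25, seed = 9)
  gv <- st$truth$genetic_values
  r2 <- vapply(seq_len(40), function(j) {
    summary(lm(st$transcripts$W[, j] ~ gv[, j]))$r.squared
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.25), 0.05)
  sl <- vapply(seq_len(40), function(j) {
    coef(lm(st$transcripts$W[, j] ~ gv[, j]))[2]
  }, numeric(1))
  expect_lt(abs(mean(sl) - 1), 0.15)

  ## null case: no association with genotypes
  st0 <- simulate_transcripts(geno, k = 20, h2_transcript = 0, seed = 10)
  r20 <- vapply(seq_len(20), function(j) {
    g <- drop(geno$Z[, 1:10] %*% rnorm(10))
    summary(lm(st0$transcripts$W[, j] ~ g))$r.squared
  }, numeric(1))
  expect_lt(mean(r20), 0.05)

  ## near-unit heritability: T approaches the genotype-predictable subspace
  st99 <- simulate_transcripts(geno, k = 20, h2_transcript = 0.99, seed = 11)
  r299 <- vapply(seq_len(20), function(j) {
    summary(lm(st99$transcripts$W[, j] ~ st99$truth$genetic_values[, j]))$r.squared
  }, numeric(1))
  expect_gt(mean(r299), 0.95)
  expect_error(simulate_transcripts(geno, k = 0), "at least 1")
})

test_that("phenotype components realize their target variances", {
  sim <- simulate_dataset(n_f1_sires = 10, f2_per_mating = 20, n_snps = 800,
                          k = 60, seed = 12)  # 10 sires x 2 dams x 20 = 400 F2
  tr <- sim$pheno$truth
  expect_lt(abs(var(tr$g) - 0.25) / 0.25, 0.45)
  expect_lt(abs(var(tr$t) - 0.35) / 0.35, 0.45)
  expect_lt(abs(var(tr$e) - 0.40) / 0.40, 0.45)
  ## balanced test days
  expect_lte(diff(range(table(sim$pheno$testday))), 1)
  ## pure-noise phenotypes are independent of genotypes and transcripts
  ph0 <- simulate_phenotypes(sim$geno, sim$transcripts,
                             list(sigma2_g = 0, sigma2_t = 0, sigma2_e = 1),
                             n_testdays = 1, seed = 13)
  expect_lt(abs(cor(ph0$y, tr$g)), 0.15)
  expect_lt(abs(cor(ph0$y, tr$t)), 0.15)
  ## determinism
  ph1 <- simulate_phenotypes(sim$geno, sim$transcripts,
                             list(sigma2_g = 0.2, sigma2_t = 0.3, sigma2_e = 0.5),
                             seed = 14)
  ph2 <- simulate_phenotypes(sim$geno, sim$transcripts,
                             list(sigma2_g = 0.2, sigma2_t = 0.3, sigma2_e = 0.5),
                             seed = 14)
  expect_identical(ph1$y, ph2$y)
})

test_that("realized component variances converge at larger n", {
  sim <- simulate_dataset(n_f1_sires = 50, f2_per_mating = 20, n_snps = 600,
                          k = 40, seed = 15)   # 50 half-sib groups, 2000 F2 animals
  tr <- sim$pheno$truth
  expect_lt(abs(var(tr$g) - 0.25) / 0.25, 0.10)
  expect_lt(abs(var(tr$t) - 0.35) / 0.35, 0.10)
  expect_lt(abs(var(tr$e) - 0.40) / 0.40, 0.10)
})
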