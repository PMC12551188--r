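# Independent oracles and small fixture builders used across the test files.

# Pedigree numerator relationship matrix by the standard tabular method.
# Used as the oracle for the family structure produced by the gene-dropping
# simulator (independent of the genotype-based G).
tabular_A <- function(ped) {
  n <- nrow(ped)
  ids <- ped$animal_id
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    si <- if (is.na(ped$sire_id[i])) NA_integer_ else match(ped$sire_id[i], ids)
    di <- if (is.na(ped$dam_id[i])) NA_integer_ else match(ped$dam_id[i], ids)
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        a <- 0
        if (!is.na(si)) a <- a + 0.5 * A[j, si]
        if (!is.na(di)) a <- a + 0.5 * A[j, di]
        A[i, j] <- A[j, i] <- a
      }
    }
    A[i, i] <- 1 + (if (!is.na(si) && !is.na(di)) 0.5 * A[si, di] else 0)
  }
  A
}

# Naive dense REML log-likelihood with explicit inversions (brute-force
# oracle for the package's Cholesky-based implementation).
naive_reml_loglik <- function(y, X, K, sigma2, sigma2_e) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(sigma2_e, n)
  for (i in seq_along(K)) V <- V + sigma2[i] * K[[i]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * ((n - p) * log(2 * pi) +
            as.numeric(determinant(V, logarithm = TRUE)$modulus) +
            as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) +
            drop(t(y) %*% P %*% y))
}

# Unstructured population: iid binomial dosages (no pedigree relationships).
iid_genotypes <- function(n, m, seed, freq = c(0.1, 0.9)) {
  set.seed(seed)
  p <- runif(m, freq[1], freq[2])
  dos <- vapply(p, function(pp) rbinom(n, 2L, pp), integer(n))
  rownames(dos) <- sprintf("id%03d", seq_len(n))
  genotype_data(dos)
}

# Small standardized transcript matrix with no genetic component.
iid_W <- function(n, k, seed) {
  set.seed(seed)
  W <- apply(matrix(rnorm(n * k), n, k), 2L, standardize)
  rownames(W) <- sprintf("id%03d", seq_len(n))
  colnames(W) <- sprintf("tr%d", seq_len(k))
  W
}

# Compact F2 dataset for tests that need family structure but not study scale.
small_dataset <- function(n_f1_sires = 5L, f2_per_mating = 12L, n_snps = 400L,
                          k = 30L, h2_transcript = 0.25, seed = 1L) {
  simulate_dataset(n_f1_sires = n_f1_sires, f2_per_mating = f2_per_mating,
                   n_snps = n_snps, k = k, h2_transcript = h2_transcript,
                   seed = seed)
}

rel_frob <- function(A, B) norm(A - B, "F") / norm(B, "F")
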