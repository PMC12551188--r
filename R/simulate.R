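#' Simulate an F2-cross pedigree
#'
#' Two founder lines are crossed to create an F1 generation, from which
#' `n_f1_sires` males and `n_f1_dams` females are mated in a 1:2 ratio (each
#' sire with two dams, without rotation); every mating contributes
#' `f2_per_mating` F2 offspring.  The paternal half-sib structure of the F2
#' generation defines the family groups used by family-blocked
#' cross-validation (`family_group` equals the F2 animal's sire id).
#'
#' The defaults reproduce the design of a quail F2 resource population:
#' 10 F1 sires x 20 F1 dams and 24 offspring per mating give 480 F2 animals
#' in 10 paternal half-sib groups.
#'
#' @param n_founder_per_line founders per line (half of each sex).
#' @param n_f1_sires number of F1 males used for breeding.
#' @param n_f1_dams number of F1 females; must equal `2 * n_f1_sires`.
#' @param f2_per_mating F2 offspring per sire-dam mating.
#' @param seed integer seed (optional; identical seeds give identical
#'   pedigrees).
#' @return object of class `"pedigree"` (a data.frame): `animal_id`,
#'   `sire_id`, `dam_id`, `generation` (founder/F1/F2), `sex`, `family_group`,
#'   `line` (founders only).
#' @export
simulate_pedigree <- function(n_founder_per_line = 12L, n_f1_sires = 10L,
                              n_f1_dams = 20L, f2_per_mating = 24L,
                              seed = NULL) {
  counts <- c(n_founder_per_line, n_f1_sires, n_f1_dams, f2_per_mating)
  if (any(counts < 1L) || any(counts != round(counts))) {
    stop("all counts must be positive integers")
  }
  if (n_f1_dams != 2L * n_f1_sires) {
    stop("the 1:2 mating design requires n_f1_dams = 2 * n_f1_sires")
  }
  with_seed(seed, {
    founders <- data.frame(
      animal_id = c(sprintf("A%02d", seq_len(n_founder_per_line)),
                    sprintf("B%02d", seq_len(n_founder_per_line))),
      sire_id = NA_character_, dam_id = NA_character_,
      generation = "founder",
      sex = rep(rep(c("M", "F"), length.out = n_founder_per_line), 2L),
      family_group = NA_character_,
      line = rep(c("A", "B"), each = n_founder_per_line),
      stringsAsFactors = FALSE)
    a_males <- founders$animal_id[founders$line == "A" & founders$sex == "M"]
    b_females <- founders$animal_id[founders$line == "B" & founders$sex == "F"]
    if (!length(a_males) || !length(b_females)) {
      stop("need at least one male and one female founder per line")
    }
    n_f1 <- n_f1_sires + n_f1_dams
    f1 <- data.frame(
      animal_id = sprintf("F1_%03d", seq_len(n_f1)),
      sire_id = sample(a_males, n_f1, replace = TRUE),
      dam_id = sample(b_females, n_f1, replace = TRUE),
      generation = "F1",
      sex = c(rep("M", n_f1_sires), rep("F", n_f1_dams)),
      family_group = NA_character_, line = NA_character_,
      stringsAsFactors = FALSE)
    sires <- f1$animal_id[f1$sex == "M"]
    dams <- f1$animal_id[f1$sex == "F"]
    f2_list <- vector("list", n_f1_sires * 2L)
    idx <- 0L
    cnt <- 0L
    for (s in seq_len(n_f1_sires)) {
      for (dd in (2L * s - 1L):(2L * s)) {
        idx <- idx + 1L
        f2_list[[idx]] <- data.frame(
          animal_id = sprintf("F2_%04d", cnt + seq_len(f2_per_mating)),
          sire_id = sires[s], dam_id = dams[dd],
          generation = "F2",
          sex = rep(c("M", "F"), length.out = f2_per_mating),
          family_group = sires[s], line = NA_character_,
          stringsAsFactors = FALSE)
        cnt <- cnt + f2_per_mating
      }
    }
    ped <- rbind(founders, f1, do.call(rbind, f2_list))
    rownames(ped) <- NULL
    class(ped) <- c("pedigree", "data.frame")
    ped
  })
}

#' Simulate SNP genotypes by gene dropping through a pedigree
#'
#' Founder haplotypes are drawn from line-specific allele frequencies
#' (independent uniforms on `founder_freq_range` per line and SNP, so the two
#' lines differ in frequency, as in a line cross); each offspring then
#' inherits, independently per locus, one random allele from each parent's
#' two alleles (no linkage map — loci are dropped independently).
#'
#' @param pedigree a `"pedigree"` from [simulate_pedigree()].
#' @param n_snps number of biallelic SNPs.
#' @param founder_freq_range interval inside (0, 1) for founder-line allele
#'   frequencies.
#' @param seed integer seed (optional).
#' @return a [genotype_data] object over all pedigree animals; attributes
#'   `haplotypes` (list of two 0/1 allele matrices) and `pedigree` are
#'   attached for downstream checks.  Use [subset_genotypes()] to restrict to
#'   the F2 study animals (allele frequencies are then recomputed).
#' @export
simulate_genotypes <- function(pedigree, n_snps, founder_freq_range = c(0.05, 0.95),
                               seed = NULL) {
  if (!inherits(pedigree, "pedigree") || nrow(pedigree) == 0L) {
    stop("`pedigree` must be a non-empty pedigree")
  }
  if (n_snps < 1L) stop("`n_snps` must be at least 1")
  rng <- founder_freq_range
  if (length(rng) != 2L || rng[1L] <= 0 || rng[2L] >= 1 || rng[1L] > rng[2L]) {
    stop("`founder_freq_range` must be an interval inside (0, 1)")
  }
  with_seed(seed, {
    n <- nrow(pedigree)
    ids <- pedigree$animal_id
    row_of <- seq_len(n)
    names(row_of) <- ids
    H1 <- matrix(0L, n, n_snps)
    H2 <- matrix(0L, n, n_snps)
    pA <- runif(n_snps, rng[1L], rng[2L])
    pB <- runif(n_snps, rng[1L], rng[2L])
    for (i in seq_len(n)) {
      if (pedigree$generation[i] == "founder") {
        pf <- if (pedigree$line[i] == "A") pA else pB
        H1[i, ] <- as.integer(runif(n_snps) < pf)
        H2[i, ] <- as.integer(runif(n_snps) < pf)
      } else {
        s <- row_of[[pedigree$sire_id[i]]]
        dd <- row_of[[pedigree$dam_id[i]]]
        pick_s <- runif(n_snps) < 0.5
        pick_d <- runif(n_snps) < 0.5
        H1[i, ] <- ifelse(pick_s, H1[s, ], H2[s, ])
        H2[i, ] <- ifelse(pick_d, H1[dd, ], H2[dd, ])
      }
    }
    dos <- H1 + H2
    rownames(dos) <- ids
    colnames(dos) <- sprintf("snp%d", seq_len(n_snps))
    geno <- genotype_data(dos, ids = ids)
    attr(geno, "haplotypes") <- list(H1 = H1, H2 = H2)
    attr(geno, "pedigree") <- pedigree
    geno
  })
}

#' Simulate partly heritable transcript abundances
#'
#' Each transcript column is built as `genetic value + noise`: the genetic
#' value is \eqn{Z\gamma} over a random subset of the SNPs (default 10% per
#' transcript, giving sparse genetic control), scaled so the realized
#' heritable fraction of the column variance equals `h2_transcript`; columns
#' are then standardized.
#'
#' @param genotypes a [genotype_data] object (the study animals).
#' @param k number of transcripts.
#' @param h2_transcript heritability of transcript levels, in \[0, 1).
#' @param prop_snps fraction of SNPs controlling each transcript.
#' @param seed integer seed (optional).
#' @return list with `transcripts` (a [transcript_data]; `W` is the
#'   standardized matrix) and `truth` (list: `h2_transcript_true`,
#'   `genetic_values` — the n x k matrix of scaled transcript genetic
#'   values, `snp_sets`).
#' @export
simulate_transcripts <- function(genotypes, k = 77L, h2_transcript = 0.25,
                                 prop_snps = 0.1, seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_data"))
  if (k < 1L) stop("`k` must be at least 1")
  if (h2_transcript < 0 || h2_transcript >= 1) {
    stop("`h2_transcript` must lie in [0, 1)")
  }
  with_seed(seed, {
    Z <- genotypes$Z
    n <- nrow(Z)
    m <- ncol(Z)
    nsel <- max(1L, round(prop_snps * m))
    gv <- matrix(0, n, k)
    sets <- vector("list", k)
    raw <- matrix(0, n, k)
    for (j in seq_len(k)) {
      if (h2_transcript > 0) {
        idx <- sample.int(m, nsel)
        sets[[j]] <- idx
        g <- drop(Z[, idx, drop = FALSE] %*% rnorm(nsel))
        sg <- stats::sd(g)
        if (sg > 0) g <- g * sqrt(h2_transcript) / sg
        gv[, j] <- g
      }
      raw[, j] <- gv[, j] + rnorm(n, sd = sqrt(1 - h2_transcript))
    }
    rownames(raw) <- genotypes$ids
    colnames(raw) <- sprintf("tr%d", seq_len(k))
    tr <- transcript_data(raw)
    list(transcripts = tr,
         truth = list(h2_transcript_true = h2_transcript,
                      genetic_values = gv, snp_sets = sets))
  })
}

#' Simulate phenotypes with genetic, transcript-mediated and batch components
#'
#' \deqn{y = Xb + Z\alpha + W\tau + e} with SNP effects
#' \eqn{\alpha \sim N(0, \sigma^2_g/\tilde m)} (so the additive genetic
#' component has covariance \eqn{\sigma^2_g G}), transcript effects
#' \eqn{\tau \sim N(0, \sigma^2_t/k)} (covariance \eqn{\sigma^2_t T}),
#' balanced test-day assignment with effects
#' \eqn{b \sim N(0, \mathrm{testday\_sd}^2)}, and residual
#' \eqn{e \sim N(0, \sigma^2_e I)}.
#'
#' @param genotypes a [genotype_data] over the study animals.
#' @param transcripts a [transcript_data] over the same animals (its `W` is
#'   the mediation matrix).
#' @param truth list with elements `sigma2_g`, `sigma2_t`, `sigma2_e`
#'   (variances on the standardized trait scale).
#' @param n_testdays number of test days (default 11); animals are assigned
#'   in balanced fashion.
#' @param testday_sd SD of the test-day effects (default 0.3).
#' @param condition_h2_t when non-`NULL`, the transcript-mediated component
#'   uses the genotype-conditioned matrix
#'   \eqn{W_c = (I - S_\lambda) W} with
#'   \eqn{\lambda = \tilde m (1/\mathrm{condition\_h2\_t} - 1)} instead of
#'   `W`, i.e. the phenotype is drawn from the conditioned (GTCBLUPi-form)
#'   model in which the transcript-level heritability is an identifiable
#'   parameter.  With the default `NULL` the transcript component uses `W`
#'   directly (the two-random-term GTBLUP form).
#' @param seed integer seed (optional).
#' @return object of class `"phenotype_data"`: list with `y` (named), `X`
#'   (test-day design with intercept), `testday` (factor), `ids`, and
#'   `truth` extended with the drawn `snp_effects`, `transcript_effects`,
#'   `testday_effects` and the realized component vectors `g`, `t`.
#' @export
simulate_phenotypes <- function(genotypes, transcripts, truth, n_testdays = 11L,
                                testday_sd = 0.3, condition_h2_t = NULL,
                                seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_data"),
            inherits(transcripts, "transcript_data"))
  if (!identical(genotypes$ids, transcripts$ids)) {
    stop("genotype and transcript animal sets do not match")
  }
  vc <- truth[c("sigma2_g", "sigma2_t", "sigma2_e")]
  if (any(vapply(vc, is.null, logical(1)))) {
    stop("`truth` must contain sigma2_g, sigma2_t, sigma2_e")
  }
  if (any(unlist(vc) < 0)) stop("variance components must be nonnegative")
  if (n_testdays < 1L) stop("`n_testdays` must be at least 1")
  with_seed(seed, {
    Z <- genotypes$Z
    W <- transcripts$W
    if (!is.null(condition_h2_t)) {
      lam <- lambda_from_h2(condition_h2_t, genotypes$m_tilde)
      W <- condition_w(W, genotypes, lam)$W_c
    }
    n <- nrow(Z)
    alpha <- rnorm(ncol(Z), sd = sqrt(vc$sigma2_g / genotypes$m_tilde))
    g <- drop(Z %*% alpha)
    tau <- rnorm(ncol(W), sd = sqrt(vc$sigma2_t / ncol(W)))
    tt <- drop(W %*% tau)
    td <- factor(sample(rep(seq_len(n_testdays), length.out = n)))
    bt <- rnorm(n_testdays, sd = testday_sd)
    e <- rnorm(n, sd = sqrt(vc$sigma2_e))
    y <- bt[as.integer(td)] + g + tt + e
    names(y) <- genotypes$ids
    X <- if (n_testdays == 1L) {
      matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
    } else {
      stats::model.matrix(~td)
    }
    rownames(X) <- genotypes$ids
    structure(list(y = y, X = X, testday = td, ids = genotypes$ids,
                   truth = c(vc, list(snp_effects = alpha,
                                      transcript_effects = tau,
                                      testday_effects = bt,
                                      g = g, t = tt, e = e))),
              class = "phenotype_data")
  })
}

#' Simulate a complete F2-cross multi-omics dataset
#'
#' One call that chains [simulate_pedigree()], [simulate_genotypes()]
#' (restricted to the F2 generation), [simulate_transcripts()] and
#' [simulate_phenotypes()].  The defaults emulate the study conditions the
#' package is designed around: 480 F2 animals in 10 paternal half-sib groups,
#' 4000 SNPs, 77 transcripts with transcript-level heritability 0.25,
#' variance components (0.25, 0.35, 0.40) on the standardized trait scale,
#' and 11 test days.
#'
#' @param n_f1_sires,f2_per_mating,n_snps,k,h2_transcript,vc,n_testdays,seed
#'   see the individual simulators; `vc` is the variance-component triple.
#' @return list with `pedigree`, `geno` (F2 [genotype_data]), `transcripts`,
#'   `pheno` (a `"phenotype_data"`), `groups` (named family-group labels for
#'   the F2 animals), `truth`.
#' @export
simulate_dataset <- function(n_f1_sires = 10L, f2_per_mating = 24L,
                             n_snps = 4000L, k = 77L, h2_transcript = 0.25,
                             vc = list(sigma2_g = 0.25, sigma2_t = 0.35,
                                       sigma2_e = 0.40),
                             n_testdays = 11L, seed = NULL) {
  with_seed(seed, {
    ped <- simulate_pedigree(n_f1_sires = n_f1_sires,
                             n_f1_dams = 2L * n_f1_sires,
                             f2_per_mating = f2_per_mating)
    geno_all <- simulate_genotypes(ped, n_snps = n_snps)
    f2 <- ped$animal_id[ped$generation == "F2"]
    geno <- subset_genotypes(geno_all, f2)
    sim_t <- simulate_transcripts(geno, k = k, h2_transcript = h2_transcript)
    pheno <- simulate_phenotypes(geno, sim_t$transcripts, vc,
                                 n_testdays = n_testdays)
    groups <- ped$family_group[match(f2, ped$animal_id)]
    names(groups) <- f2
    list(pedigree = ped, geno = geno, transcripts = sim_t$transcripts,
         pheno = pheno, groups = groups,
         truth = c(pheno$truth,
                   list(h2_transcript_true = h2_transcript)))
  })
}
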