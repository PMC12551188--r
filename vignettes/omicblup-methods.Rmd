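---
title: "Genomic and transcriptomic BLUP models: methods and design"
author: "omicblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic and transcriptomic BLUP models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicblup)
```

## The problem

Transcript abundances measured in a tissue relevant to a trait carry
predictive information about the phenotype that goes beyond what SNP
genotypes capture: they reflect post-transcriptional regulation, epigenetic
state and environmental exposure.  But transcript levels are themselves
partly heritable, so putting a genomic random effect and a transcriptomic
random effect side by side in one mixed model double-counts the heritable
part of the transcripts.  This package implements a family of animal-model
BLUPs for this situation, centered on a conditioned model in which the
transcript matrix is first stripped of its genotype-predictable component.

## Model family

With $y$ an $n$-vector of (Box-Cox transformed, standardized) phenotypes,
$X$ the fixed-effect design (test day), and standard normal assumptions on
all random terms:

* **GBLUP** — $y = Xb + g + e$, $g \sim N(0, G\sigma^2_g)$ with the VanRaden
  method-1 genomic relationship matrix
  $G = ZZ^{\top}/\sum_j 2p_j(1-p_j)$, $Z$ the centered dosage matrix.
* **TBLUP** — $y = Xb + t + e$, $t \sim N(0, T\sigma^2_t)$ with
  $T = WW^{\top}/k$, $W$ the $n \times k$ matrix of pre-corrected,
  standardized transcript abundances.
* **GTBLUP** — both terms, assumed independent.
* **GTCBLUP / GTCBLUPi** — $y = Xb + g + t_c + e$ where
  $t_c \sim N(0, T_c\sigma^2_{t_c})$, $T_c = W_cW_c^{\top}/k$, and
  $W_c = (I - S_\lambda)W$ with the ridge-regression smoother
  $S_\lambda = Z(Z^{\top}Z + \lambda I_m)^{-1}Z^{\top}$.

The smoother is the BLUP of the transcript-level effects from the SNPs, so
$(I-S_\lambda)W$ retains only the non-heritable part of each transcript
column.  The ridge is tied to the heritability of transcript-level effects,
$\lambda = \tilde m\,(1/\tilde h^2_t - 1)$ with
$\tilde m = \sum_j 2p_j(1-p_j)$.  GTCBLUP plugs in the trait's GBLUP
heritability ($\lambda = m(1/h^2 - 1)$, $m$ the SNP count); GTCBLUPi
profiles $\tilde h^2_t$ on a grid (default step 0.01 on
$[0.01, 0.99]$) and keeps the value maximizing the restricted
log-likelihood.  Zero is excluded from the grid because $\lambda$ is
undefined there; ties break toward the smaller $\tilde h^2_t$, the more
conservative removal of genetic signal.  $\tilde h^2_t$ cannot be estimated
jointly with the other variance components because it enters through $W_c$
itself, which is why the profile search exists at all.

Two algebraically equivalent conditioning routes are provided: the direct
form above (one $m \times m$ inversion) and a Woodbury rearrangement,
$W_c = (I - G^* + G^*(I+G^*)^{-1}G^*)W$ with $G^* = G\,\tilde m/\lambda$
(one $n \times n$ inversion).  `choose_route()` picks direct when animals
outnumber SNPs and Woodbury otherwise, with ties going to the direct route;
the two routes agree to machine precision and that equivalence is the
module's central test.

## REML estimation

`blup_fit()` maximizes the restricted log-likelihood
$\ell_R = -\tfrac12[(n-p)\log 2\pi + \log|V| + \log|X^{\top}V^{-1}X| +
y^{\top}Py]$ by average-information (AI) REML with step-halving, falling
back to a multiplicative fixed-point step
($\sigma^2 \leftarrow \sigma^2\sqrt{y^{\top}PKPy/\mathrm{tr}(PK)}$) when the
AI update fails to improve the objective.  Components are kept on the
natural scale with a floor of $10^{-8}\,\mathrm{var}(y)$; convergence
requires $|\Delta\ell_R| < 10^{-8}$ and a maximum relative parameter change
below $10^{-6}$, within 200 iterations.  (The natural-scale update with a
floor was chosen over a log-scale parameterization: the AI and fallback
algebra stay simple, and the floor enforces the same nonnegativity
constraint.)  Single-kernel models take an exact eigendecomposition path:
after rotating by the eigenvectors of $K$ the profile likelihood in the
variance ratio is one-dimensional and is maximized by Brent search; the two
paths agree to $10^{-8}$ and this is tested.  Standard errors come from the
inverse AI matrix; a singular AI matrix (e.g. a kernel duplicating the
residual) flags the fit as non-identifiable rather than failing.

Variance proportions divide each $\sigma^2_i\,\mathrm{mean(diag}(K_i))$ by
their total.  The mean-diagonal scaling matters for $T_c$ — whose diagonal
shrinks below one by construction, giving
$\tilde\sigma^2_{t_c} = \sigma^2_{t_c}\mathrm{mean(diag}(T_c))$ — and is a
no-op for $G$ and $T$, whose mean diagonal is $\approx 1$; it is applied
uniformly and flagged in the output.  Model comparison uses
$D = 2[\log L_2 - \log L_1]$ against $\chi^2$ for nested pairs (the plain
p-value is reported, with the 50:50 boundary mixture attached as a
diagnostic) and AIC $= -2\ell_R + 2q$ with $q$ the number of variance
parameters only — fixed effects are identical across the compared models.

## Preprocessing

Phenotypes and transcript abundances are Box-Cox transformed
($f(y) = (y^\lambda-1)/\lambda$, $\log y$ at $\lambda = 0$) with $\lambda$
chosen by a profile-likelihood grid search (default $-4$ to $6$ in steps of
0.001 plus a tenfold refinement pass — wide because skewed traits can need
$\lambda$ well outside $(-2, 2)$), then standardized to mean 0 and sample SD
1 (denominator $n-1$, the convention of common statistical software).
Transcript columns are then pre-corrected by OLS on the fixed covariates
(test day, plate, sex, housekeeping-gene abundances as continuous
covariates); with only fixed effects named, a mixed-model correction reduces
to exactly this OLS fit.  The order of operations is fixed: transform,
standardize, pre-correct, re-center.

## Cross-validation and accuracy

`make_folds()` supports the two schemes used for such designs: random 80/20
splits (default 500 repetitions) and family-blocked folds that enumerate
every combination of validation family groups — for 10 paternal half-sib
groups and 20% validation, all $\binom{10}{2} = 45$ folds of 8 reference / 2
validation groups.  Variance components are re-estimated on each reference
set.  Validation animals' total effects are predicted by conditional
expectation from the reference BLUPs,
$\hat u_{val} = K_{val,ref}(K_{ref,ref} + \epsilon I)^{-1}\hat u_{ref}$,
summed over random terms; this equals re-solving the mixed-model equations
with validation phenotypes masked (tested against that oracle to within
0.005 in accuracy).  Accuracy is the Pearson correlation with phenotypes
pre-corrected for test day, the correction being estimated once on the full
data for stability across folds (a per-fold option exists).  Accuracies are
summarized through Fisher's $z$: mean and $\bar z \pm 1.96\,\mathrm{SD}(z)$,
back-transformed — an interval describing the spread of single-repetition
accuracies.  Paired model comparisons use the per-fold accuracy differences
on identical folds with a mean $\pm 1.96\,\mathrm{SD}$ interval on the raw
differences (the $z$ transform is undefined for differences, which can leave
$(-1,1)$; a Fisher-z-per-accuracy variant is available behind a flag);
significance means the interval excludes zero.

In cross-validation GTCBLUPi's $\tilde h^2_t$ is estimated once on the full
data by default.  The grid search uses phenotypes, so this leaks a small
amount of validation information into the conditioning; a per-fold
re-estimation option is the remedy when that matters, and the default is
documented rather than hidden.

## Transcript-effect back-solving

From a TBLUP fit, individual transcript effects are recovered as
$\hat u = \tfrac1k W^{\top}T^{-1}\hat t$ with variance
$\mathrm{Var}(\hat u) = \tfrac1{k^2}W^{\top}T^{-1}(T\sigma^2_t -
C^{tt})T^{-1}W$, where
$C^{tt} = \sigma^2_e(I - X(X^{\top}X)^{-1}X^{\top} + T^{-1}\lambda)^{-1}$,
$\lambda = \sigma^2_e/\sigma^2_t$, is the prediction-error variance of
$\hat t$ (one record per animal, so the incidence matrix is the identity and
this is asserted).  Each effect is tested with
$RNA_j = \hat u_j/\sqrt{\mathrm{Var}(\hat u_j)}$ against a standard normal,
with the nominal 0.05 and Bonferroni $0.05/k$ thresholds reported and a
Manhattan-style plot available.

Two numerical choices matter here.  $T$ with $k < n$ is singular, so a
relative ridge $\epsilon\,\mathrm{mean(diag)}\,I$ (default
$\epsilon = 10^{-6}$, recorded in the result) is added before every
inversion.  And the *same* stabilized $T$ must be used in $C^{tt}$ and in
the difference $T\sigma^2_t - C^{tt}$: that difference is second order in
$\sigma^2_t$ near the boundary, and a ridge mismatch between the two terms
otherwise swamps it, breaking the calibration of $RNA_j$ exactly in the
null-like fits where calibration matters most.  Residual tiny negative
variances are clipped to zero; negatives beyond numerical error raise an
error.  Monte-Carlo replication confirms $\sqrt{\mathrm{Var}(\hat u_j)}$
tracks the empirical SD of $\hat u_j$ within 20%, and the pooled null
p-values are uniform.

## Bivariate transcriptomic correlations

Transcriptomic correlations between traits come from a bivariate TBLUP with
covariance $\Sigma_t \otimes T + \Sigma_e \otimes I$.  Both 2×2 matrices are
parameterized by Cholesky factors with log diagonals, so positive
semidefiniteness is structural; the residual cross-trait covariance is
estimated (the same animals are measured for both traits — omitting it would
confound the transcriptomic correlation), with a flag to fix it at zero.
Eigendecomposing $T$ once rotates the problem into $n$ independent 2×2
blocks, making each REML evaluation $O(np^2)$; the 6-parameter likelihood is
maximized by L-BFGS-B from multiple starts (univariate variance components
with starting correlations $0, \pm 0.8$).  The primary correctness oracle is
a reduction identity: with both covariance matrices diagonal the bivariate
log-likelihood equals the sum of the two univariate TBLUP log-likelihoods
(to $10^{-6}$).  $H_0\!: r_t = 0$ is tested by refitting with $\Sigma_t$
diagonal and comparing $D = 2\Delta\ell_R$ with $\chi^2_1$; $r_t = 0$ is an
interior point, so no boundary correction applies, and the test holds its
nominal size in simulation.

## The synthetic-data generator

No public dataset accompanies the methodology, so the package carries a
first-class simulator of the study design it targets: an F2 cross of two
founder lines.  `simulate_pedigree()` mates line-A males to line-B females,
selects F1 sires and twice as many F1 dams (1:2, without rotation), and
produces F2 offspring whose paternal half-sib groups define the
cross-validation families; the defaults (10 sires × 20 dams × 24 offspring)
give 480 F2 animals in 10 groups.  `simulate_genotypes()` draws line-specific
founder allele frequencies and gene-drops alleles through the pedigree,
independently per locus — no linkage map, since linkage shapes LD but not the
correctness of any estimator here.  Family structure is validated against
the pedigree numerator relationship matrix computed by the tabular method.
`simulate_transcripts()` gives each transcript a sparse genetic basis (10%
of SNPs by default) scaled to a chosen heritable fraction.
`simulate_phenotypes()` composes additive-genetic, transcript-mediated,
balanced test-day (default 11 days, effect SD 0.3 on the standardized
scale) and residual components; the default variance triple is
$(\sigma^2_g, \sigma^2_t, \sigma^2_e) = (0.25, 0.35, 0.40)$, heritability
and transcriptomic proportions in the middle of the range such efficiency
traits show.  All randomness flows from one integer seed; every output is
reproducible bit for bit.

One generator subtlety is worth spelling out.  With independent SNP and
transcript effects, the phenotype covariance is *exactly*
$\sigma^2_gG + \sigma^2_tT + \sigma^2_eI$ — the two-random-term (GTBLUP)
structure.  The conditioned family reproduces that covariance exactly at the
$\tilde h^2_t \to 0$ end of its grid (where $T_c \to T$), so under this
generator the profile search correctly collapses to the grid floor and the
transcript-level heritability is *not identifiable*: no estimator could
recover it.  Parameter-recovery experiments for $\tilde h^2_t$ therefore
simulate from the conditioned model itself — the simulator's
`condition_h2_t` argument draws the transcript-mediated component as
$W_c(h)\tau$ — under which the grid search recovers the truth.  Even then
the estimator is noisy at a few hundred animals (its spread halves in our
experiments going from 480 to 1000 animals), consistent with the original
analysis reporting very small estimated $\tilde h^2_t$ values for several
traits and attributing that to data size.

## What the simulations do and do not show

The generator emulates the study's family structure, marker density,
transcript dimensionality and variance composition, and gives every
downstream stage a ground truth.  It does not emulate linkage and LD decay,
selection of animals by transcript availability, the discordant-sib-pair
transcript selection of the original design, heavy-tailed transcript-effect
distributions, or technical artifacts (plate effects beyond a linear term).
Passing tests therefore certify the estimators and their calibration under
the stated model, not robustness to those real-data features.

## Verification problem sizes

The packaged checks run at sizes chosen to make each property measurable
with modest compute: route equivalence on 30 randomized instances spanning
$n>m$, $n<m$, $n=m$; REML against a brute-force dense oracle at $n = 50$;
GTBLUP recovery over 20 study-scale replicates ($n = 480$, $m = 4000$,
$k = 77$) requiring each true component inside its 2-SE interval in at least
80% of replicates; $\tilde h^2_t$ recovery over 7 replicates at $n = 1000$,
$m = 500$, $k = 80$ (the estimator's spread at 480 animals makes a small
replicate-median uninformative, per the identifiability discussion above);
the null calibration of $RNA_j$ over 200 replicates ($n = 160$, $k = 80$);
and the bivariate LRT size over 200 replicates ($n = 150$, $k = 60$).

The no-conditioning limit deserves a note: the grid's smallest value
$\tilde h^2_t = 0.01$ gives $\lambda = 99\tilde m$, under which the smoother
still shrinks every direction by roughly 1%.  A uniform shrinkage of $T_c$
is absorbed exactly by $\sigma^2_{t_c}$, so the residual gap to the GTBLUP
log-likelihood is driven by the *anisotropy* of the shrinkage over $G$'s
eigenvalue spread.  The limit check therefore uses an unstructured
population with $m/n$ large, where $G$'s spectrum is nearly flat; with
family structure (leading eigenvalues of $G$ an order of magnitude above the
bulk) the gap at the 0.01 grid point is real and expected, not a defect.
The exact statement — conditioning at $\lambda = 10^{12}$ reproduces the
GTBLUP fit — is asserted to $10^{-6}$ alongside.

## Known limitations

Dense-matrix REML scales as $O(n^3)$ per iteration and is intended for
populations up to a few thousand animals.  The ridge $\epsilon = 10^{-6}$ on
singular relationship matrices is a pragmatic default, configurable
everywhere it is used.  Boundary REML estimates make the plain $\chi^2$ LRT
conservative (the mixture p-value is attached as a diagnostic).  Only
Bonferroni and the nominal line are offered for transcript tests, matching
the intended workflow.  Joint modeling of two transcript sets (e.g. miRNA
and mRNA together) and multi-trait extensions beyond the bivariate TBLUP are
out of scope.
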