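#' Container for SNP dosage genotypes
#'
#' Stores an animal-by-SNP dosage matrix together with the quantities every
#' downstream relationship/conditioning computation needs: reference-allele
#' frequencies \eqn{p_j}, the centered matrix \eqn{Z} (dosage \eqn{- 2p_j},
#' polymorphic SNPs only), and the VanRaden scaling constant
#' \eqn{\tilde m = \sum_j 2 p_j (1 - p_j)}.
#'
#' Monomorphic SNPs (\eqn{p_j \le 0} or \eqn{\ge 1}) carry no relationship
#' information; they are kept in `dosages` but excluded from `Z` and
#' `m_tilde`.
#'
#' @param dosages numeric matrix, animals in rows, SNPs in columns, values in
#'   \[0, 2\] (fractional values arise from mean imputation of missing calls).
#' @param p optional vector of reference-allele frequencies; computed from the
#'   data (`colMeans(dosages)/2`) when `NULL`.
#' @param ids animal identifiers (default: rownames).
#' @return object of class `"genotype_data"`: list with `dosages`, `ids`,
#'   `snp_ids`, `p` (all SNPs), `polymorphic` (logical), `Z`, `m` (number of
#'   polymorphic SNPs used) and `m_tilde`.
#' @export
genotype_data <- function(dosages, p = NULL, ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (!is.numeric(dosages)) stop("`dosages` must be a numeric matrix")
  if (anyNA(dosages)) stop("`dosages` contains missing values; impute before construction")
  if (any(dosages < 0 | dosages > 2)) {
    bad <- which(dosages < 0 | dosages > 2, arr.ind = TRUE)[1L, ]
    stop(sprintf("dosage out of [0, 2] at row %d, column %d", bad[1L], bad[2L]))
  }
  n <- nrow(dosages)
  m_all <- ncol(dosages)
  if (n < 1L || m_all < 1L) stop("`dosages` must have at least one row and one column")
  if (is.null(ids)) ids <- sprintf("id%d", seq_len(n))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicated animal ids in genotype data")
  snp_ids <- colnames(dosages)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%d", seq_len(m_all))
  if (is.null(p)) p <- colMeans(dosages) / 2
  if (length(p) != m_all) stop("`p` must have one entry per SNP")
  if (any(p < 0 | p > 1)) stop("allele frequencies must lie in [0, 1]")
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all SNPs are monomorphic; no relationship information")
  Z <- sweep(dosages[, poly, drop = FALSE], 2L, 2 * p[poly])
  rownames(Z) <- ids
  rownames(dosages) <- ids
  colnames(dosages) <- snp_ids
  structure(list(dosages = dosages, ids = ids, snp_ids = snp_ids,
                 p = p, polymorphic = poly, Z = Z,
                 m = sum(poly), m_tilde = sum(2 * p[poly] * (1 - p[poly]))),
            class = "genotype_data")
}

#' Subset a genotype object to a set of animals
#'
#' Allele frequencies, `Z` and `m_tilde` are recomputed from the subset by
#' default, matching the convention that \eqn{p_j} is estimated from the
#' analyzed sample.
#'
#' @param geno a [genotype_data] object.
#' @param ids animal identifiers to keep (order respected).
#' @param recompute_p recompute allele frequencies from the subset (default
#'   `TRUE`); otherwise the parent frequencies are reused.
#' @return a new [genotype_data] object.
#' @export
subset_genotypes <- function(geno, ids, recompute_p = TRUE) {
  stopifnot(inherits(geno, "genotype_data"))
  miss <- setdiff(ids, geno$ids)
  if (length(miss)) {
    stop("animals not present in genotype data: ", paste(head(miss, 5L), collapse = ", "))
  }
  d <- geno$dosages[ids, , drop = FALSE]
  genotype_data(d, p = if (recompute_p) NULL else geno$p, ids = ids)
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("Genotype data: %d animals x %d SNPs (%d polymorphic)\n",
              nrow(x$dosages), length(x$p), x$m))
  cat(sprintf("  m_tilde = sum 2p(1-p) = %.3f\n", x$m_tilde))
  invisible(x)
}
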