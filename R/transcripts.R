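#' Container for transcript abundance data
#'
#' Holds the raw animal-by-transcript matrix and the pre-corrected,
#' standardized matrix `W` used to build the transcriptomic relationship
#' matrix \eqn{T = WW^T/k}.
#'
#' @param raw numeric matrix, animals in rows, transcripts in columns.
#' @param W pre-corrected standardized matrix (same shape); defaults to the
#'   column-standardized `raw` when no correction has been applied yet.
#' @param ids animal identifiers (default rownames).
#' @return object of class `"transcript_data"` with elements `raw`, `W`, `k`,
#'   `transcript_ids`, `ids`.
#' @export
transcript_data <- function(raw, W = NULL, ids = rownames(raw)) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop("`raw` must be a numeric matrix")
  n <- nrow(raw); k <- ncol(raw)
  if (k < 1L) stop("need at least one transcript")
  if (is.null(ids)) ids <- sprintf("id%d", seq_len(n))
  ids <- as.character(ids)
  tids <- colnames(raw)
  if (is.null(tids)) tids <- sprintf("tr%d", seq_len(k))
  if (is.null(W)) W <- apply(raw, 2L, standardize)
  W <- as.matrix(W)
  if (!identical(dim(W), dim(raw))) stop("`W` must have the same shape as `raw`")
  dimnames(raw) <- dimnames(W) <- list(ids, tids)
  structure(list(raw = raw, W = W, k = k, transcript_ids = tids, ids = ids),
            class = "transcript_data")
}

#' @export
print.transcript_data <- function(x, ...) {
  cat(sprintf("Transcript data: %d animals x %d transcripts\n", nrow(x$raw), x$k))
  invisible(x)
}

#' Pre-correct transcript abundances for fixed effects
#'
#' Each transcript column is (optionally) Box-Cox transformed, standardized
#' (mean 0, sample SD 1), and then replaced by its residual from an ordinary
#' least-squares regression on the covariate design (test day, plate, sex,
#' housekeeping-gene abundances, ...).  The residual columns are re-centered
#' and are orthogonal to every covariate column.
#'
#' The fixed-effect correction is a plain OLS fit: with only fixed covariates
#' named, a mixed-model correction reduces to exactly this.
#'
#' @param raw numeric matrix of transcript abundances (animals x transcripts).
#' @param covariates design matrix including an intercept column; rows align
#'   with the rows of `raw`.  Rank-deficient designs have aliased columns
#'   dropped with a warning.
#' @param apply_boxcox apply a per-column Box-Cox ML transform first.
#'   Default `NULL` means: only if all values are strictly positive.
#' @param boxcox_step grid step for the per-column Box-Cox search
#'   (coarser than the trait default: there are many columns).
#' @return a [transcript_data] object whose `W` holds the pre-corrected,
#'   standardized matrix.
#' @export
precorrect_transcripts <- function(raw, covariates, apply_boxcox = NULL,
                                   boxcox_step = 0.01) {
  raw <- as.matrix(raw)
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != nrow(raw)) stop("`covariates` rows must align with animals")
  ## intercept must be representable in the covariate column space
  ones <- rep(1, nrow(raw))
  if (max(abs(qr.resid(qr(covariates), ones))) > 1e-8) {
    stop("`covariates` must include an intercept column")
  }
  covariates <- drop_aliased(covariates)
  if (is.null(apply_boxcox)) apply_boxcox <- all(raw > 0)
  std <- apply(raw, 2L, function(col) {
    if (apply_boxcox) col <- boxcox_mle(col, step = boxcox_step)$transformed
    standardize(col)
  })
  qx <- qr(covariates)
  W <- qr.resid(qx, std)
  W <- sweep(W, 2L, colMeans(W))   # re-center (no-op when intercept present)
  dimnames(W) <- dimnames(raw)
  transcript_data(raw, W = W, ids = rownames(raw))
}
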