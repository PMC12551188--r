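#' Build cross-validation folds
#'
#' Random scheme: `n_reps` independent reference/validation splits with
#' `round(frac_validation * n)` validation animals each.  Family scheme: all
#' \eqn{C(g, v)} combinations of `v = round(frac_validation * g)` validation
#' family groups (e.g. 10 paternal half-sib groups with 20% validation give
#' exactly 45 folds of 8 reference / 2 validation groups); whole families are
#' always kept together.
#'
#' @param animals vector of animal identifiers.
#' @param scheme `"random"` or `"family"`.
#' @param frac_validation validation fraction (default 0.2).
#' @param n_reps number of repetitions (random scheme; default 500).
#' @param groups family-group labels parallel to `animals` (family scheme).
#' @param seed integer seed for the random scheme (optional).
#' @return object of class `"fold_plan"`: list with `scheme`, `folds` (each a
#'   list with `reference`, `validation`), `seed`.
#' @export
make_folds <- function(animals, scheme = c("random", "family"),
                       frac_validation = 0.2, n_reps = 500L,
                       groups = NULL, seed = NULL) {
  scheme <- match.arg(scheme)
  animals <- as.character(animals)
  n <- length(animals)
  if (anyDuplicated(animals)) stop("duplicated animal identifiers")
  if (frac_validation <= 0 || frac_validation >= 1) {
    stop("`frac_validation` must be in (0, 1)")
  }
  if (scheme == "random") {
    v <- round(frac_validation * n)
    if (v == 0L || v == n) stop("validation set would be empty or the full data")
    folds <- with_seed(seed, {
      lapply(seq_len(n_reps), function(i) {
        val <- sort(sample.int(n, v))
        list(reference = animals[-val], validation = animals[val])
      })
    })
  } else {
    if (is.null(groups)) stop("family scheme requires `groups`")
    if (length(groups) != n) stop("`groups` must be parallel to `animals`")
    gs <- unique(as.character(groups))
    v <- round(frac_validation * length(gs))
    if (v == 0L || v == length(gs)) {
      stop("validation would contain none or all of the family groups")
    }
    cmb <- combn(gs, v)
    folds <- lapply(seq_len(ncol(cmb)), function(j) {
      val <- groups %in% cmb[, j]
      list(reference = animals[!val], validation = animals[val])
    })
  }
  structure(list(scheme = scheme, folds = folds, seed = seed,
                 frac_validation = frac_validation),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$validation), integer(1))
  cat(sprintf("Fold plan (%s): %d folds, validation sizes %s\n",
              x$scheme, length(x$folds),
              paste(range(sizes), collapse = "-")))
  invisible(x)
}

#' Predict animal effects for validation animals
#'
#' Conditional-expectation prediction from the reference BLUPs: for each
#' random term, \eqn{\hat u_{val} = K_{val,ref} (K_{ref,ref} + \epsilon I)^{-1}
#' \hat u_{ref}}; the total prediction is the sum over terms.  With
#' \eqn{\epsilon = 0} and an invertible reference block this equals the BLUP
#' obtained from the full mixed-model equations with validation phenotypes
#' masked.
#'
#' @param fit a `"blup_fit"` object estimated on the reference animals.
#' @param K_full named list of relationship matrices over all animals
#'   (dimnames required); names must match the fit's terms.
#' @param validation_ids animals to predict.
#' @param ridge_eps relative ridge for the reference-block inversion.
#' @return named vector of predicted total animal effects, validation order.
#' @export
predict_validation <- function(fit, K_full, validation_ids, ridge_eps = 1e-6) {
  stopifnot(inherits(fit, "blup_fit"))
  if (!all(fit$term_names %in% names(K_full))) {
    stop("`K_full` must contain a matrix for every fitted term: ",
         paste(fit$term_names, collapse = ", "))
  }
  ref <- fit$ids
  validation_ids <- as.character(validation_ids)
  pred <- numeric(length(validation_ids))
  for (nm in fit$term_names) {
    K <- K_full[[nm]]
    if (is.null(rownames(K))) stop("kernel '", nm, "' has no dimnames")
    miss <- setdiff(c(ref, validation_ids), rownames(K))
    if (length(miss)) {
      stop("animals missing from kernel '", nm, "': ",
           paste(head(miss, 5L), collapse = ", "))
    }
    Krr <- ridge_stabilize(K[ref, ref, drop = FALSE], ridge_eps)
    Kvr <- K[validation_ids, ref, drop = FALSE]
    pred <- pred + drop(Kvr %*% solve(Krr, fit$blups[[nm]]))
  }
  names(pred) <- validation_ids
  pred
}

#' Prediction accuracy
#'
#' Pearson correlation between predicted animal effects and observed
#' phenotypes pre-corrected for fixed (test-day) effects.  When `X` is given,
#' `y` is replaced by its least-squares residual on `X`; inside a
#' cross-validation the correction should be estimated once on the full data
#' (see [cross_validate()]) and the corrected values passed directly.
#'
#' @param pred predicted animal effects.
#' @param y observed phenotypes (or already-corrected phenotypes).
#' @param X optional fixed-effect design used to pre-correct `y`.
#' @return Pearson correlation; `NA` (with a warning) if either vector has
#'   zero variance.
#' @export
accuracy <- function(pred, y, X = NULL) {
  if (length(pred) != length(y)) stop("`pred` and `y` must have equal length")
  if (!is.null(X)) y <- qr.resid(qr(as.matrix(X)), y)
  if (stats::sd(pred) == 0 || stats::sd(y) == 0) {
    warning("zero variance; accuracy undefined for this fold")
    return(NA_real_)
  }
  stats::cor(pred, y)
}

#' Fisher z-transformation and its inverse
#'
#' \eqn{z = \tfrac12 \log\{(1+r)/(1-r)\}} and
#' \eqn{r = (e^{2z}-1)/(e^{2z}+1)}.
#'
#' @param r correlation(s) in (-1, 1).
#' @param z z-value(s).
#' @return transformed values.
#' @export
fisher_z <- function(r) 0.5 * log((1 + r) / (1 - r))

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) (exp(2 * z) - 1) / (exp(2 * z) + 1)

#' Fisher-z summary of per-fold accuracies
#'
#' Transforms each correlation to the z scale, forms the mean and the
#' normal-theory 95% interval `mean(z) +/- 1.96 * sd(z)` (an interval for a
#' single repetition's accuracy, matching how CV accuracies are reported with
#' their spread), and back-transforms all three.
#'
#' @param rs vector of per-fold Pearson correlations; values with
#'   \eqn{|r| \ge 1} are clipped to \eqn{1 - 10^{-12}} with a warning, `NA`s
#'   dropped.
#' @return list with `mean_r`, `lo`, `hi`, `n`.
#' @export
fisher_ci <- function(rs) {
  rs <- rs[!is.na(rs)]
  if (!length(rs)) stop("no non-missing correlations")
  if (any(abs(rs) >= 1)) {
    warning("correlations with |r| >= 1 clipped to 1 - 1e-12")
    rs <- pmin(pmax(rs, -1 + 1e-12), 1 - 1e-12)
  }
  z <- fisher_z(rs)
  m <- mean(z)
  s <- if (length(z) > 1L) stats::sd(z) else 0
  list(mean_r = fisher_z_inv(m),
       lo = fisher_z_inv(m - 1.96 * s),
       hi = fisher_z_inv(m + 1.96 * s),
       n = length(rs))
}

#' Cross-validate BLUP models on common folds
#'
#' For every fold and every model: refit the variance components by REML on
#' the reference animals, predict the validation animals' total effects by
#' [predict_validation()], and correlate with phenotypes pre-corrected for
#' the fixed design (correction estimated once on the full data).  All models
#' see identical folds, so paired comparisons ([compare_models()]) are valid.
#'
#' @param y named phenotype vector over all animals.
#' @param X_fixed fixed-effect design over all animals (test-day indicators).
#' @param kernels named list of models; each element is itself a named list
#'   of relationship matrices over all animals, e.g.
#'   `list(GBLUP = list(g = G), GTBLUP = list(g = G, t = T))`.
#' @param folds a `"fold_plan"` from [make_folds()].
#' @param ridge_eps ridge for reference-block inversions.
#' @param verbose print fold progress.
#' @param ... passed to [blup_fit()].
#' @return object of class `"cv_result"`: `accuracy` (folds x models matrix),
#'   `mean_accuracy`, `ci95`, `n_folds`, `folds`.
#' @export
cross_validate <- function(y, X_fixed, kernels, folds, ridge_eps = 1e-6,
                           verbose = FALSE, ...) {
  stopifnot(inherits(folds, "fold_plan"))
  ids <- names(y)
  if (is.null(ids)) stop("`y` must be named by animal id")
  X_fixed <- as.matrix(X_fixed)
  rownames(X_fixed) <- ids
  ycorr <- qr.resid(qr(X_fixed), y)      # full-data test-day correction
  names(ycorr) <- ids
  nf <- length(folds$folds)
  acc <- matrix(NA_real_, nf, length(kernels),
                dimnames = list(NULL, names(kernels)))
  for (f in seq_len(nf)) {
    ref <- folds$folds[[f]]$reference
    val <- folds$folds[[f]]$validation
    for (m in names(kernels)) {
      Ks <- lapply(kernels[[m]], function(K) K[ref, ref, drop = FALSE])
      fit <- tryCatch(
        suppressWarnings(blup_fit(y[ref], X_fixed[ref, , drop = FALSE],
                                  K = Ks, ids = ref, ...)),
        error = function(e) NULL)
      if (is.null(fit)) next
      pred <- predict_validation(fit, kernels[[m]], val, ridge_eps = ridge_eps)
      acc[f, m] <- suppressWarnings(accuracy(pred, ycorr[val]))
    }
    if (verbose && f %% 10L == 0L) message("fold ", f, "/", nf)
  }
  cis <- lapply(colnames(acc), function(m) fisher_ci(acc[, m]))
  names(cis) <- colnames(acc)
  structure(list(accuracy = acc,
                 mean_accuracy = vapply(cis, `[[`, numeric(1), "mean_r"),
                 ci95 = cis, n_folds = nf, folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation (%s, %d folds):\n",
              x$folds$scheme, x$n_folds))
  tab <- t(vapply(x$ci95, function(ci) c(accuracy = ci$mean_r, lo = ci$lo, hi = ci$hi),
                  numeric(3)))
  print(round(tab, 3))
  invisible(x)
}

#' Paired comparison of two models' CV accuracies
#'
#' Per-fold accuracy differences on identical folds; the 95% interval is
#' `mean(diff) +/- 1.96 * sd(diff)` over the per-fold differences (default),
#' or the same construction on the difference of Fisher-z-transformed
#' accuracies (`method = "fisher"`, reported on the z scale).  A significant
#' difference is declared when the interval excludes zero.
#'
#' @param result a `"cv_result"`.
#' @param model_a,model_b model names present in `result`.
#' @param method `"raw"` (default) or `"fisher"`.
#' @return object of class `"paired_comparison"`: `mean_diff`, `ci95`,
#'   `significant`, `per_fold_diff`, `method`.
#' @export
compare_models <- function(result, model_a, model_b, method = c("raw", "fisher")) {
  method <- match.arg(method)
  stopifnot(inherits(result, "cv_result"))
  for (m in c(model_a, model_b)) {
    if (!m %in% colnames(result$accuracy)) stop("model not in CV result: ", m)
  }
  ra <- result$accuracy[, model_a]
  rb <- result$accuracy[, model_b]
  ok <- !is.na(ra) & !is.na(rb)
  if (!any(ok)) stop("no folds with both models evaluated")
  d <- if (method == "raw") ra[ok] - rb[ok] else fisher_z(ra[ok]) - fisher_z(rb[ok])
  m <- mean(d)
  s <- if (length(d) > 1L) stats::sd(d) else 0
  ci <- c(lo = m - 1.96 * s, hi = m + 1.96 * s)
  structure(list(model_a = model_a, model_b = model_b,
                 per_fold_diff = d, mean_diff = m, ci95 = ci,
                 significant = (ci["lo"] > 0 || ci["hi"] < 0),
                 method = method, n = length(d)),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("%s - %s: mean difference %.4f [%.4f, %.4f] over %d folds (%s)%s\n",
              x$model_a, x$model_b, x$mean_diff, x$ci95["lo"], x$ci95["hi"],
              x$n, x$method, if (x$significant) "  *" else ""))
  invisible(x)
}
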