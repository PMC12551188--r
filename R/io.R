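#' Read a genotype dosage file
#'
#' Supports two dialects: plain TSV with an `animal_id` column followed by
#' one integer dosage column per SNP, and the PLINK `.raw` dialect
#' (whitespace-separated, leading columns `FID IID PAT MAT SEX PHENOTYPE`,
#' then one allele-count column per SNP; `IID` is used as the animal id).
#' Dosages must be 0/1/2 or missing; missing values are imputed to the column
#' mean (the standard choice for relationship-matrix construction) with the
#' imputation count reported in a message.
#'
#' @param path file path.
#' @return a [genotype_data] object.
#' @export
read_genotypes <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1L]]
  is_raw <- length(header) >= 7L &&
    identical(header[1:6], c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
  if (is_raw) {
    tab <- read.table(path, header = TRUE, sep = "", check.names = FALSE,
                      stringsAsFactors = FALSE)
    ids <- as.character(tab$IID)
    M <- as.matrix(tab[, -(1:6), drop = FALSE])
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (!"animal_id" %in% names(tab)) {
      stop("genotype TSV must contain an `animal_id` column (or use the PLINK .raw dialect)")
    }
    ids <- as.character(tab$animal_id)
    M <- as.matrix(tab[, setdiff(names(tab), "animal_id"), drop = FALSE])
  }
  storage.mode(M) <- "double"
  bad <- which(!is.na(M) & !(M %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid dosage %s for animal '%s', SNP '%s'",
                 format(M[bad[1L, 1L], bad[1L, 2L]]),
                 ids[bad[1L, 1L]], colnames(M)[bad[1L, 2L]]))
  }
  n_miss <- sum(is.na(M))
  if (n_miss > 0L) {
    message(n_miss, " missing dosage(s) imputed to the SNP mean")
    for (j in which(colSums(is.na(M)) > 0L)) {
      mj <- mean(M[, j], na.rm = TRUE)
      if (is.nan(mj)) mj <- 0
      M[is.na(M[, j]), j] <- mj
    }
  }
  rownames(M) <- ids
  genotype_data(M, ids = ids)
}

#' Write genotypes as TSV or PLINK .raw dialect
#'
#' @param geno a [genotype_data] object.
#' @param path output path.
#' @param format `"tsv"` (animal_id + dosage columns) or `"raw"` (PLINK
#'   `.raw` dialect with placeholder pedigree columns).
#' @export
write_genotypes <- function(geno, path, format = c("tsv", "raw")) {
  format <- match.arg(format)
  stopifnot(inherits(geno, "genotype_data"))
  M <- geno$dosages
  if (format == "tsv") {
    df <- data.frame(animal_id = geno$ids, M, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(FID = geno$ids, IID = geno$ids, PAT = 0L, MAT = 0L,
                     SEX = 0L, PHENOTYPE = -9L, M, check.names = FALSE)
    write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a TSV table keyed by animal id
#'
#' Header-checked tab-separated file with an `animal_id` column; numeric
#' columns are returned as a matrix with animal ids as rownames.
#'
#' @param path file path.
#' @param required character vector of column names that must be present.
#' @return data.frame (attribute-free), `animal_id` as character.
#' @export
read_table_tsv <- function(path, required = character()) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!"animal_id" %in% names(tab)) stop("missing required column: animal_id")
  miss <- setdiff(required, names(tab))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$animal_id)) {
    stop("duplicated animal_id: ",
         paste(unique(tab$animal_id[duplicated(tab$animal_id)]), collapse = ", "))
  }
  tab$animal_id <- as.character(tab$animal_id)
  tab
}

#' Write a matrix as TSV keyed by animal id
#'
#' @param M matrix with animal ids as rownames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(M, path) {
  df <- data.frame(animal_id = rownames(M), M, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align tables by animal id
#'
#' Returns the ids common ordering (the order of the first argument) and
#' fails with an explicit listing when the id sets differ.
#'
#' @param ... two or more character vectors of animal ids.
#' @return the common id vector, in the order of the first argument.
#' @export
align_ids <- function(...) {
  sets <- list(...)
  ref <- sets[[1L]]
  for (i in seq_along(sets)[-1L]) {
    extra <- setdiff(sets[[i]], ref)
    missing <- setdiff(ref, sets[[i]])
    if (length(extra) || length(missing)) {
      stop("animal id mismatch between inputs",
           if (length(missing)) paste0("; missing: ", paste(head(missing, 5L), collapse = ", ")),
           if (length(extra)) paste0("; unexpected: ", paste(head(extra, 5L), collapse = ", ")))
    }
  }
  ref
}

#' Serialize a model fit (or simulation truth) to JSON
#'
#' Variance components, standard errors, log-likelihood, AIC and convergence
#' information for a `"blup_fit"`; arbitrary lists (e.g. simulation truth)
#' are written as-is.
#'
#' @param x a `"blup_fit"` object or a plain list.
#' @param path output path.
#' @export
write_fit_json <- function(x, path) {
  obj <- if (inherits(x, "blup_fit")) {
    list(model = x$model,
         variance_components = as.list(x$variance_components),
         std_errors = as.list(x$std_errors),
         loglik = x$loglik, aic = x$aic,
         converged = x$converged, n_iter = x$n_iter, n = x$n,
         beta = as.list(x$beta))
  } else {
    x
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
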