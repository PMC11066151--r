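#' @useDynLib frontsig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var rnorm pt qbeta dhyper cor predict
#' @importFrom utils combn read.delim write.table
NULL

GROUP_LEVELS <- c("early_relapse", "no_relapse")
POSITIVE_CLASS <- "early_relapse"

#' Validate a gene-by-sample expression matrix
#'
#' An expression matrix is an ordinary numeric matrix of log-scale
#' expression values with genes in rows and samples in columns. Row and
#' column names carry the gene and sample identifiers and must be unique;
#' all values must be finite.
#'
#' @param x Numeric matrix, genes x samples, with rownames (gene IDs) and
#'   colnames (sample IDs).
#' @param min_samples Minimum number of columns required (default 2).
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(x, min_samples = 2L) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix must have gene rownames and sample colnames",
         call. = FALSE)
  }
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g) > 0) {
    stop("duplicate gene IDs: ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s) > 0) {
    stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (ncol(x) < min_samples) {
    stop("expression matrix must have at least ", min_samples, " samples",
         call. = FALSE)
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]), call. = FALSE)
  }
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose header row lists the sample IDs and
#' whose first column holds the gene IDs.
#'
#' @param path Path to the TSV file.
#' @return A validated genes x samples numeric matrix.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 3) {
    stop("expression TSV needs a gene-ID column plus at least 2 samples",
         call. = FALSE)
  }
  gene_ids <- df[[1]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0) {
    stop("duplicate gene IDs in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("non-numeric value at row %d (gene '%s'), column '%s'",
                 bad[1, 1], gene_ids[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]), call. = FALSE)
  }
  dimnames(num) <- list(gene_ids, colnames(vals))
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix to TSV
#'
#' @param x Validated expression matrix.
#' @param path Output path.
#' @param id_column Name of the first (gene ID) column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, id_column = "gene_id") {
  validate_expression_matrix(x)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a phenotype table
#'
#' A phenotype table is a data frame with columns `sample_id` and `group`,
#' where `group` is one of `"early_relapse"` or `"no_relapse"`.
#'
#' @param pheno Data frame with `sample_id` and `group` columns.
#' @param require_both Require both outcome groups to be present (as needed
#'   for training); default FALSE.
#' @return `pheno`, invisibly, if valid.
#' @export
validate_phenotype <- function(pheno, require_both = FALSE) {
  if (!is.data.frame(pheno) ||
      !all(c("sample_id", "group") %in% names(pheno))) {
    stop("phenotype table must have columns 'sample_id' and 'group'",
         call. = FALSE)
  }
  if (anyDuplicated(pheno$sample_id)) {
    stop("duplicate sample IDs in phenotype table", call. = FALSE)
  }
  bad <- setdiff(unique(as.character(pheno$group)), GROUP_LEVELS)
  if (length(bad) > 0) {
    stop("unknown group labels: ", paste(bad, collapse = ", "),
         "; expected ", paste(GROUP_LEVELS, collapse = " or "), call. = FALSE)
  }
  if (require_both && length(unique(as.character(pheno$group))) < 2) {
    stop("both outcome groups must be present", call. = FALSE)
  }
  invisible(pheno)
}

#' Read a phenotype table from TSV
#'
#' @param path Path to a TSV with columns `sample_id` and `group`.
#' @return Validated phenotype data frame.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", stringsAsFactors = FALSE)
  validate_phenotype(df)
  df
}

#' Write a phenotype table to TSV
#'
#' @param pheno Validated phenotype data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(pheno, path) {
  validate_phenotype(pheno)
  write.table(pheno[, c("sample_id", "group")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# 0/1 indicator of the positive (early relapse) class, aligned to samples
phenotype_indicator <- function(pheno, sample_ids) {
  validate_phenotype(pheno)
  idx <- match(sample_ids, pheno$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from phenotype table: ",
         paste(sample_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  as.integer(as.character(pheno$group[idx]) == POSITIVE_CLASS)
}
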