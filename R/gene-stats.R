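coerce_labels <- function(labels, n) {
  if (length(labels) != n) {
    stop("labels must have one entry per value", call. = FALSE)
  }
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop("numeric labels must be 0/1 (1 = early relapse)", call. = FALSE)
    }
    return(as.integer(labels))
  }
  lab <- as.character(labels)
  bad <- setdiff(unique(lab), GROUP_LEVELS)
  if (length(bad) > 0) {
    stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  as.integer(lab == POSITIVE_CLASS)
}

#' Mann-Whitney AUC of a single marker
#'
#' AUC of the decision rule "higher value implies early relapse": the
#' fraction of (early, no-relapse) sample pairs in which the early-relapse
#' value is larger, ties counted 0.5. Equivalent to the normalized
#' Mann-Whitney U statistic, computed from mid-ranks.
#'
#' @param values Numeric marker values (e.g., one gene's expression).
#' @param labels Group labels: `"early_relapse"`/`"no_relapse"`, or a
#'   logical/0-1 indicator of early relapse.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(values, labels) {
  y <- coerce_labels(labels, length(values))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(values)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Direction of a gene's association with early relapse
#'
#' `+1` when the gene's mean expression is higher in the early-relapse
#' group than in the no-relapse group, `-1` when lower, and `NA` on exact
#' equality (the direction is then undefined and the gene cannot be
#' stable).
#'
#' @inheritParams auc_mann_whitney
#' @return `+1`, `-1`, or `NA` (integer).
#' @export
gene_direction <- function(values, labels) {
  y <- coerce_labels(labels, length(values))
  if (!any(y == 1L) || !any(y == 0L)) {
    stop("both classes must be present", call. = FALSE)
  }
  m1 <- mean(values[y == 1L])
  m0 <- mean(values[y == 0L])
  if (m1 > m0) 1L else if (m1 < m0) -1L else NA_integer_
}

#' Bootstrap stability screening of per-gene AUC and direction
#'
#' For `b` stratified bootstrap resamples of the training cohort
#' (resampling within each outcome group at its own size, so both classes
#' are always present), records each gene's Mann-Whitney AUC and direction
#' of association. A gene is *stable* when its direction is defined and
#' identical across all `b` resamples; its reported AUC is the average
#' over the resamples. All genes are evaluated on the same shared
#' bootstrap resamples, which are drawn once from a single seeded stream.
#'
#' @param expr Gene x sample expression matrix.
#' @param pheno Phenotype table covering all columns of `expr`.
#' @param b Number of bootstrap resamples (default 50).
#' @param seed Integer seed for the bootstrap index stream.
#' @return Data frame with columns `gene_id`, `mean_auc`, `direction`
#'   (`NA` when unstable), `stable`, `n_bootstraps`.
#' @export
bootstrap_gene_stability <- function(expr, pheno, b = 50L, seed = 1L) {
  validate_expression_matrix(expr)
  b <- as.integer(b)
  if (b < 1L) stop("b must be >= 1", call. = FALSE)
  y <- phenotype_indicator(pheno, colnames(expr))
  early_cols <- which(y == 1L)
  no_cols <- which(y == 0L)
  if (length(early_cols) < 2 || length(no_cols) < 2) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  set.seed(as.integer(seed))
  ei <- matrix(sample(early_cols, b * length(early_cols), replace = TRUE),
               nrow = b)
  ni <- matrix(sample(no_cols, b * length(no_cols), replace = TRUE),
               nrow = b)
  res <- .boot_gene_stats_cpp(expr, ei, ni)
  data.frame(gene_id = rownames(expr),
             mean_auc = res$mean_auc,
             direction = res$direction,
             stable = res$stable,
             n_bootstraps = b,
             stringsAsFactors = FALSE)
}
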