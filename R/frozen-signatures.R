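#' Load one of the published early-relapse signatures
#'
#' The package ships the three published signature models as frozen data
#' files: `"baseline"` (bulk tumor, cross-platform gene space; 5 modules
#' of 4 genes), `"bulk"` (full platform; 3 modules of 5 genes) and
#' `"invasion_front"` (full platform; 3 modules of 4 genes), with the
#' published per-gene signs and per-module coefficients. No intercept was
#' published, so these models produce uncalibrated linear risk scores:
#' valid for ranking samples within a cohort, not as probabilities.
#'
#' @param name One of `"baseline"`, `"bulk"`, `"invasion_front"`.
#' @return A [signature_model] without intercept.
#' @export
load_published_signature <- function(name) {
  name <- match.arg(name, c("baseline", "bulk", "invasion_front"))
  path <- system.file("extdata", "signatures", paste0(name, ".json"),
                      package = "frontsig", mustWork = TRUE)
  read_signature(path)
}

#' Apply a frozen signature to an expression matrix
#'
#' Computes the per-sample linear risk score
#' \eqn{\sum_m \beta_m \cdot n_{g,m}^{-1} \sum_{g \in m} d_g x_g}
#' of an intercept-free signature. Higher scores mean higher
#' early-relapse risk; without a published intercept or cutoff the score
#' is rank-valid only. Expression is expected on the log scale; with
#' `standardize = TRUE` each gene is z-scored across samples first
#' (useful across platforms, where the raw scale differs).
#'
#' In strict mode (default) every signature gene must be present. With
#' `strict = FALSE`, missing genes are dropped and each affected module
#' is renormalized by its remaining size, with a warning; a module losing
#' all its genes is an error.
#'
#' @param sig A [signature_model] (typically from
#'   [load_published_signature]).
#' @param expr Gene x sample expression matrix.
#' @param strict Require all signature genes (default TRUE).
#' @param standardize Z-score each gene across samples first (default
#'   FALSE).
#' @return Named numeric vector of linear risk scores, one per sample.
#' @export
apply_signature <- function(sig, expr, strict = TRUE, standardize = FALSE) {
  if (!inherits(sig, "signature_model")) {
    stop("sig must be a signature_model", call. = FALSE)
  }
  validate_expression_matrix(expr)
  all_genes <- unique(unlist(lapply(sig$modules, `[[`, "genes")))
  missing <- setdiff(all_genes, rownames(expr))
  if (strict && length(missing) > 0) {
    stop("signature genes missing from expression matrix: ",
         paste(missing, collapse = ", "),
         " (use strict = FALSE to drop and renormalize)", call. = FALSE)
  }
  if (standardize) {
    present <- intersect(all_genes, rownames(expr))
    sub <- expr[present, , drop = FALSE]
    mu <- rowMeans(sub)
    sd <- apply(sub, 1, stats::sd)
    if (any(sd == 0)) {
      stop("cannot standardize zero-variance genes: ",
           paste(present[sd == 0], collapse = ", "), call. = FALSE)
    }
    expr[present, ] <- (sub - mu) / sd
  }
  total <- stats::setNames(numeric(ncol(expr)), colnames(expr))
  for (i in seq_along(sig$modules)) {
    m <- sig$modules[[i]]
    keep <- m$genes %in% rownames(expr)
    if (!all(keep)) {
      if (sum(keep) == 0) {
        stop("module '", m$name, "' has no genes left in the expression ",
             "matrix", call. = FALSE)
      }
      warning(sprintf(
        "module '%s': dropping %d missing gene(s) (%s), renormalizing by %d",
        m$name, sum(!keep), paste(m$genes[!keep], collapse = ", "),
        sum(keep)), call. = FALSE)
    }
    x <- expr[m$genes[keep], , drop = FALSE]
    value <- colSums(x * m$directions[keep]) / sum(keep)
    total <- total + sig$module_coefficients[i] * value
  }
  total
}
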