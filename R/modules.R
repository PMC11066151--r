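#' Per-sample value of a signed gene module
#'
#' The module value of sample \eqn{s} is the direction-weighted mean
#' \eqn{n_g^{-1} \sum_g d_g x_{gs}} over the module's genes.
#'
#' @param expr Gene x sample expression matrix containing all module
#'   genes.
#' @param module A [gene_module].
#' @return Named numeric vector, one value per sample of `expr`.
#' @export
module_score <- function(expr, module) {
  if (!inherits(module, "gene_module")) {
    stop("module must be a gene_module", call. = FALSE)
  }
  missing <- setdiff(module$genes, rownames(expr))
  if (length(missing) > 0) {
    stop("module genes missing from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- expr[module$genes, , drop = FALSE]
  colSums(x * module$directions) / length(module$genes)
}

#' Enumerate candidate modules from one gene set
#'
#' Restricts a gene set to its stable genes present in the expression
#' matrix, ranks them by *oriented* bootstrap AUC — the AUC of the
#' direction-weighted gene, i.e. `mean_auc` for genes with `d = +1` and
#' `1 - mean_auc` for genes with `d = -1`, so strongly down-regulated
#' genes rank as high as strongly up-regulated ones — and enumerates
#' every `n_g`-gene subset of the top `pool_size` ranked genes. Each
#' subset is scored by the training AUC of its module value (directions
#' taken from the stability screen), and the `top_k` best-scoring subsets
#' are returned as modules named `<set>_1`, `<set>_2`, ... in decreasing
#' AUC order. Returns an empty list when the set holds fewer than `n_g`
#' stable genes.
#'
#' Ties on module AUC are broken by the larger sum of member gene AUCs,
#' then by lexicographic gene order, so the enumeration is deterministic.
#'
#' @param set_name Name of the gene set to draw from.
#' @param gene_sets Gene-set collection (named list).
#' @param stats Stability table from [bootstrap_gene_stability].
#' @param expr Training expression matrix.
#' @param pheno Training phenotype table.
#' @param n_g Module size (number of genes).
#' @param top_k Number of top subsets kept per set (default 5).
#' @param pool_size Number of top-ranked stable genes the subsets are
#'   drawn from (default 8; bounds the combinatorics).
#' @return List of [gene_module] objects, possibly empty.
#' @export
candidate_modules <- function(set_name, gene_sets, stats, expr, pheno,
                              n_g, top_k = 5L, pool_size = 8L) {
  if (n_g < 1) stop("n_g must be >= 1", call. = FALSE)
  if (!set_name %in% names(gene_sets)) {
    stop("unknown gene set: ", set_name, call. = FALSE)
  }
  y <- phenotype_indicator(pheno, colnames(expr))
  st <- stats[stats$stable & stats$gene_id %in% gene_sets[[set_name]] &
                stats$gene_id %in% rownames(expr), , drop = FALSE]
  if (nrow(st) < n_g) return(list())
  st$oriented_auc <- ifelse(st$direction == 1L, st$mean_auc,
                            1 - st$mean_auc)
  st <- st[order(-st$oriented_auc, st$gene_id), , drop = FALSE]
  pool <- utils::head(st, pool_size)
  if (nrow(pool) < n_g) return(list())
  dirs <- pool$direction
  names(dirs) <- pool$gene_id
  member_auc <- pool$oriented_auc
  names(member_auc) <- pool$gene_id

  subsets <- combn(pool$gene_id, n_g, simplify = FALSE)
  sub_x <- expr[pool$gene_id, , drop = FALSE] * dirs
  auc <- numeric(length(subsets))
  auc_sum <- numeric(length(subsets))
  key <- character(length(subsets))
  for (i in seq_along(subsets)) {
    g <- subsets[[i]]
    score <- colSums(sub_x[g, , drop = FALSE]) / n_g
    auc[i] <- auc_mann_whitney(score, y)
    auc_sum[i] <- sum(member_auc[g])
    key[i] <- paste(sort(g), collapse = "|")
  }
  ord <- order(-auc, -auc_sum, key)
  keep <- utils::head(ord, top_k)
  lapply(seq_along(keep), function(r) {
    g <- subsets[[keep[r]]]
    gene_module(name = paste0(set_name, "_", r),
                genes = g, directions = dirs[g],
                source_set = set_name, train_auc = auc[keep[r]])
  })
}

#' Enumerate candidate modules across a whole collection
#'
#' Applies [candidate_modules] to every set of the collection and
#' concatenates the results.
#'
#' @inheritParams candidate_modules
#' @return List of [gene_module] objects (possibly empty).
#' @export
candidate_modules_all <- function(gene_sets, stats, expr, pheno, n_g,
                                  top_k = 5L, pool_size = 8L) {
  validate_gene_sets(gene_sets)
  out <- lapply(names(gene_sets), function(nm) {
    candidate_modules(nm, gene_sets, stats, expr, pheno, n_g,
                      top_k = top_k, pool_size = pool_size)
  })
  do.call(c, out)
}

#' Select the top modules across all gene sets
#'
#' Keeps the `n_f` modules with highest training AUC over the whole
#' candidate collection. Several modules may come from the same set, and
#' genes may recur across modules; no constraint is imposed on either.
#'
#' @param modules List of candidate [gene_module] objects.
#' @param n_f Number of modules to keep.
#' @return List of `n_f` modules in decreasing training-AUC order (fewer,
#'   with a warning, when fewer candidates exist).
#' @export
select_top_modules <- function(modules, n_f) {
  if (length(modules) == 0) {
    stop("no candidate modules to select from", call. = FALSE)
  }
  auc <- vapply(modules, function(m) m$train_auc, numeric(1))
  nm <- vapply(modules, function(m) m$name, character(1))
  ord <- order(-auc, nm)
  if (length(modules) < n_f) {
    warning(sprintf("only %d candidate modules for n_f = %d",
                    length(modules), n_f), call. = FALSE)
  }
  modules[utils::head(ord, n_f)]
}
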