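#' Read a probeset-to-gene map
#'
#' Two-column TSV (`probeset_id`, `gene_id`); an empty `gene_id` marks an
#' unmapped probeset (speculative transcript, miRNA, missing symbol, ...).
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `probeset_id` and `gene_id`
#'   (`NA` where unmapped).
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    stop("probe map needs columns probeset_id and gene_id", call. = FALSE)
  }
  names(df)[1:2] <- c("probeset_id", "gene_id")
  if (anyDuplicated(df$probeset_id)) {
    stop("duplicate probeset IDs in probe map", call. = FALSE)
  }
  df$gene_id[!nzchar(trimws(df$gene_id))] <- NA_character_
  df[, c("probeset_id", "gene_id")]
}

#' Collapse a probeset-level matrix to gene level
#'
#' Summarizes array data at gene level by keeping, for every mapped gene,
#' the single most variable probeset (largest sample variance, denominator
#' n-1). Probesets without a gene mapping are discarded. A variance tie is
#' broken by the lexicographically smallest probeset ID, so the result is
#' deterministic.
#'
#' @param probe_matrix Probeset x sample expression matrix (rownames are
#'   probeset IDs).
#' @param map Probe map as returned by [read_probe_map] (probeset_id,
#'   gene_id; `NA` = unmapped).
#' @return Gene x sample expression matrix (one row per mapped gene).
#' @export
collapse_probesets <- function(probe_matrix, map) {
  validate_expression_matrix(probe_matrix)
  if (!all(c("probeset_id", "gene_id") %in% names(map))) {
    stop("map needs columns probeset_id and gene_id", call. = FALSE)
  }
  gene_of <- map$gene_id[match(rownames(probe_matrix), map$probeset_id)]
  mapped <- !is.na(gene_of)
  if (!any(mapped)) {
    stop("no probeset maps to any gene", call. = FALSE)
  }
  probes <- rownames(probe_matrix)[mapped]
  genes <- gene_of[mapped]
  vars <- apply(probe_matrix[mapped, , drop = FALSE], 1, var)
  ord <- order(genes, -vars, probes)
  first <- !duplicated(genes[ord])
  chosen <- probes[ord][first]
  out <- probe_matrix[chosen, , drop = FALSE]
  rownames(out) <- genes[ord][first]
  validate_expression_matrix(out)
  out
}

#' Restrict an expression matrix to a gene intersection
#'
#' Keeps only the genes of `a` that are also in `b_gene_ids`, preserving
#' the row order of `a`. Used to build the cross-platform baseline gene
#' space (the genes common to both array platforms).
#'
#' @param a Expression matrix.
#' @param b_gene_ids Character vector of gene IDs of the other platform.
#' @return `a` restricted to the common genes.
#' @export
intersect_genes <- function(a, b_gene_ids) {
  validate_expression_matrix(a)
  keep <- rownames(a) %in% b_gene_ids
  if (!any(keep)) {
    stop("no genes in common", call. = FALSE)
  }
  a[keep, , drop = FALSE]
}
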