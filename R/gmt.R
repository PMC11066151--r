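#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Set order is preserved.
#' Duplicate genes within one line are removed with a warning; a line with
#' fewer than three fields is an error.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (one element per set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    sets <- list()
    names(sets) <- character(0)
    return(sets)
  }
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d field(s); expected at least 3 (name, description, genes)",
                   i, length(fields)), call. = FALSE)
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s' (line %d): duplicate genes removed",
                      fields[1], i), call. = FALSE)
      genes <- unique(genes)
    }
    nms[i] <- fields[1]
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  names(sets) <- nms
  validate_gene_sets(sets)
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Named list of character vectors of gene IDs.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled `"na"` by default).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  validate_gene_sets(sets)
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a gene-set collection
#'
#' @param sets Named list of character vectors; set names unique, each set
#'   non-empty with distinct genes.
#' @return `sets`, invisibly, if valid.
#' @export
validate_gene_sets <- function(sets) {
  if (!is.list(sets)) stop("gene sets must be a named list", call. = FALSE)
  if (length(sets) > 0) {
    if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
      stop("all gene sets must be named", call. = FALSE)
    }
    if (anyDuplicated(names(sets))) {
      stop("gene-set names must be unique", call. = FALSE)
    }
    empty <- names(sets)[lengths(sets) == 0]
    if (length(empty) > 0) {
      stop("empty gene sets: ", paste(empty, collapse = ", "), call. = FALSE)
    }
    for (nm in names(sets)) {
      if (anyDuplicated(sets[[nm]])) {
        stop("duplicate genes within set '", nm, "'", call. = FALSE)
      }
    }
  }
  invisible(sets)
}
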