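#' Construct a signed gene module
#'
#' A gene module is a small ordered set of genes from one source gene set,
#' each with a direction \eqn{d_g \in \{-1,+1\}}. Its per-sample value is
#' the direction-weighted mean of the member genes' expression,
#' \eqn{n_g^{-1} \sum_g d_g x_g}.
#'
#' @param name Module name (conventionally the source set name plus a rank
#'   suffix).
#' @param genes Character vector of distinct gene IDs (length `n_g`).
#' @param directions Integer vector of +1/-1, one per gene.
#' @param source_set Name of the gene set the module was drawn from.
#' @param train_auc Optional training AUC of the module score.
#' @return An object of class `gene_module`.
#' @export
gene_module <- function(name, genes, directions, source_set = NA_character_,
                        train_auc = NA_real_) {
  genes <- as.character(genes)
  directions <- as.integer(directions)
  if (length(genes) < 1) stop("a module needs at least one gene", call. = FALSE)
  if (anyDuplicated(genes)) stop("module genes must be distinct", call. = FALSE)
  if (length(directions) != length(genes) ||
      !all(directions %in% c(-1L, 1L))) {
    stop("directions must be +1/-1, one per gene", call. = FALSE)
  }
  structure(list(name = as.character(name), genes = genes,
                 directions = directions,
                 source_set = as.character(source_set),
                 train_auc = as.numeric(train_auc)),
            class = "gene_module")
}

#' @exportS3Method base::print
print.gene_module <- function(x, ...) {
  signs <- ifelse(x$directions > 0, "+", "-")
  cat(sprintf("<gene_module> %s (from %s): %s\n", x$name, x$source_set,
              paste(paste0(signs, x$genes), collapse = " ")))
  if (!is.na(x$train_auc)) cat(sprintf("  train AUC: %.3f\n", x$train_auc))
  invisible(x)
}

#' Construct a signature model
#'
#' A fitted early-relapse signature: `n_f` gene modules of `n_g` genes
#' each, one elastic-net coefficient per module, and an optional logistic
#' intercept. With an intercept the model scores samples as posterior
#' probabilities of early relapse; without one (the published frozen
#' signatures) it yields an uncalibrated linear risk score.
#'
#' @param modules List of [gene_module] objects.
#' @param coefficients Numeric vector, one coefficient per module.
#' @param intercept Logistic intercept, or `NULL` if absent.
#' @param region One of `"bulk"`, `"invasion_front"`, `"baseline"`.
#' @param metadata Named list of training metadata (grid choice, seed, ...).
#' @return An object of class `signature_model`.
#' @export
signature_model <- function(modules, coefficients, intercept = NULL,
                            region = "bulk", metadata = list()) {
  if (length(modules) < 1) stop("at least one module required", call. = FALSE)
  if (!all(vapply(modules, inherits, logical(1), "gene_module"))) {
    stop("modules must be gene_module objects", call. = FALSE)
  }
  if (length(coefficients) != length(modules)) {
    stop("need exactly one coefficient per module", call. = FALSE)
  }
  region <- match.arg(region, c("bulk", "invasion_front", "baseline"))
  sizes <- vapply(modules, function(m) length(m$genes), integer(1))
  structure(list(modules = modules,
                 module_coefficients = as.numeric(coefficients),
                 intercept = if (is.null(intercept)) NULL else as.numeric(intercept),
                 n_g = if (length(unique(sizes)) == 1) sizes[1] else NA_integer_,
                 n_f = length(modules),
                 region = region,
                 metadata = metadata),
            class = "signature_model")
}

#' @exportS3Method base::print
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> region=%s, n_f=%d modules, n_g=%s genes/module\n",
              x$region, x$n_f,
              if (is.na(x$n_g)) "mixed" else as.character(x$n_g)))
  cat(sprintf("  intercept: %s\n",
              if (is.null(x$intercept)) "absent (linear risk score)"
              else format(x$intercept)))
  for (i in seq_along(x$modules)) {
    m <- x$modules[[i]]
    signs <- ifelse(m$directions > 0, "+", "-")
    cat(sprintf("  %+.4f * [%s] %s\n", x$module_coefficients[i], m$name,
                paste(paste0(signs, m$genes), collapse = " ")))
  }
  invisible(x)
}

SIGNATURE_SCHEMA_VERSION <- 1L

#' Write a signature model to JSON
#'
#' Serializes the module gene lists, directions, module coefficients,
#' optional intercept and metadata in a small versioned JSON schema, so
#' fitted signatures can ship and round-trip as plain data files.
#'
#' @param model A [signature_model].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(model, path) {
  if (!inherits(model, "signature_model")) {
    stop("model must be a signature_model", call. = FALSE)
  }
  obj <- list(
    schema_version = SIGNATURE_SCHEMA_VERSION,
    region = model$region,
    n_g = model$n_g,
    n_f = model$n_f,
    intercept = model$intercept,
    modules = lapply(seq_along(model$modules), function(i) {
      m <- model$modules[[i]]
      list(name = m$name, source_set = m$source_set,
           genes = as.list(m$genes), directions = as.list(m$directions),
           coefficient = model$module_coefficients[i],
           train_auc = if (is.na(m$train_auc)) NULL else m$train_auc)
    }),
    metadata = model$metadata
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a signature model from JSON
#'
#' @param path Path to a signature JSON written by [write_signature].
#' @return A [signature_model].
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$schema_version)) {
    stop("signature file lacks a schema_version field", call. = FALSE)
  }
  if (obj$schema_version != SIGNATURE_SCHEMA_VERSION) {
    stop("unknown signature schema version: ", obj$schema_version,
         call. = FALSE)
  }
  if (is.null(obj$modules) || length(obj$modules) == 0) {
    stop("signature file has no 'modules' field", call. = FALSE)
  }
  modules <- lapply(obj$modules, function(m) {
    gene_module(name = m$name,
                genes = unlist(m$genes),
                directions = unlist(m$directions),
                source_set = if (is.null(m$source_set)) NA_character_ else m$source_set,
                train_auc = if (is.null(m$train_auc)) NA_real_ else m$train_auc)
  })
  coefs <- vapply(obj$modules, function(m) as.numeric(m$coefficient),
                  numeric(1))
  metadata <- if (is.null(obj$metadata)) list() else obj$metadata
  signature_model(modules, coefs,
                  intercept = obj$intercept,
                  region = obj$region,
                  metadata = metadata)
}
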