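#' Train a gene-module signature over a size grid
#'
#' The full feature-generation and training pipeline on one training
#' cohort: (1) bootstrap-stability screening of per-gene AUC and
#' direction; (2) enumeration of candidate signed modules of `n_g` genes
#' from every gene set; (3) selection of the `n_f` modules with highest
#' training AUC; (4) an elastic-net logistic classifier on the module
#' values, tuned by internal stratified cross-validation. Steps 2-4 are
#' repeated for every `(n_g, n_f)` pair of the grid and the model with
#' the best internal-CV AUC is returned (AUC ties prefer the smaller
#' out-of-fold deviance, then the earlier grid point, i.e. smaller
#' modules and fewer of them). Only the provided samples are ever touched, so the
#' function can safely sit inside an external resampling loop.
#'
#' @param expr Training expression matrix (genes x samples).
#' @param pheno Training phenotype table.
#' @param gene_sets Gene-set collection (named list, e.g. from
#'   [read_gmt]).
#' @param ng_values,nf_values Candidate module sizes and module counts
#'   (default 3, 4, 5 each).
#' @param seed Integer seed driving the bootstrap screen and the internal
#'   CV folds.
#' @param b Bootstrap resamples for the stability screen (default 50).
#' @param top_k,pool_size Candidate-enumeration controls, see
#'   [candidate_modules].
#' @param region Label stored on the model (`"bulk"`, `"invasion_front"`
#'   or `"baseline"`).
#' @return A fitted [signature_model] with training metadata.
#' @export
train_signature_model <- function(expr, pheno, gene_sets,
                                  ng_values = c(3L, 4L, 5L),
                                  nf_values = c(3L, 4L, 5L),
                                  seed = 1L, b = 50L, top_k = 5L,
                                  pool_size = 8L, region = "bulk") {
  validate_expression_matrix(expr)
  validate_phenotype(pheno, require_both = TRUE)
  validate_gene_sets(gene_sets)
  stats <- bootstrap_gene_stability(expr, pheno, b = b, seed = seed)

  cand_by_ng <- list()
  for (n_g in unique(ng_values)) {
    cand_by_ng[[as.character(n_g)]] <-
      candidate_modules_all(gene_sets, stats, expr, pheno, n_g,
                            top_k = top_k, pool_size = pool_size)
  }

  best <- NULL
  for (n_g in ng_values) {
    cands <- cand_by_ng[[as.character(n_g)]]
    if (length(cands) == 0) next
    for (n_f in nf_values) {
      modules <- suppressWarnings(select_top_modules(cands, n_f))
      feats <- module_features(expr, modules)
      fit <- fit_elasticnet(feats, pheno, seed = seed)
      cand <- list(n_g = n_g, n_f = n_f, modules = modules, fit = fit)
      if (is.null(best) || fit$cv_auc > best$fit$cv_auc + 1e-12 ||
          (abs(fit$cv_auc - best$fit$cv_auc) <= 1e-12 &&
           !is.na(fit$cv_deviance) && !is.na(best$fit$cv_deviance) &&
           fit$cv_deviance < best$fit$cv_deviance - 1e-12)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    stop("no gene set yielded candidate modules at any grid point ",
         "(too few stable genes)", call. = FALSE)
  }
  signature_model(
    modules = best$modules,
    coefficients = best$fit$coefficients[
      vapply(best$modules, `[[`, character(1), "name")],
    intercept = best$fit$intercept,
    region = region,
    metadata = list(n_g = best$n_g, n_f = best$n_f,
                    alpha = best$fit$alpha, lambda = best$fit$lambda,
                    cv_auc = best$fit$cv_auc, seed = as.integer(seed),
                    b = as.integer(b), pool_size = as.integer(pool_size),
                    top_k = as.integer(top_k)))
}

#' External leave-one-out evaluation of the signature pipeline
#'
#' For every sample, the *entire* pipeline — bootstrap screening, module
#' enumeration, module selection, grid search and elastic-net fitting —
#' is re-run from scratch on the remaining samples, and the held-out
#' sample is scored by the resulting model. The held-out label is never
#' seen at any stage, so the returned out-of-fold scores give an
#' (almost) unbiased performance estimate.
#'
#' On a fold where no gene set yields a candidate module (possible on
#' signal-free data, where few genes pass the stability screen), the fold
#' falls back to the featureless model and scores the held-out sample
#' 0.5; such folds are marked by `n_f = 0` in the fold table. Any other
#' training failure is propagated.
#'
#' @inheritParams train_signature_model
#' @param progress Print a dot per completed fold (default FALSE).
#' @return List of class `loocv_result`: `scores` (named out-of-fold
#'   score per sample) and `folds` (data frame of the per-fold grid
#'   choice and internal-CV AUC, plus the selected module names).
#' @export
loocv <- function(expr, pheno, gene_sets, ng_values = c(3L, 4L, 5L),
                  nf_values = c(3L, 4L, 5L), seed = 1L, b = 50L,
                  top_k = 5L, pool_size = 8L, region = "bulk",
                  progress = FALSE) {
  validate_expression_matrix(expr)
  validate_phenotype(pheno, require_both = TRUE)
  samples <- colnames(expr)
  n <- length(samples)
  set.seed(as.integer(seed))
  fold_seeds <- sample.int(.Machine$integer.max, n)

  scores <- stats::setNames(numeric(n), samples)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    train_cols <- samples[-i]
    train_pheno <- pheno[pheno$sample_id %in% train_cols, , drop = FALSE]
    model <- tryCatch(
      train_signature_model(
        expr[, train_cols, drop = FALSE], train_pheno,
        gene_sets, ng_values = ng_values, nf_values = nf_values,
        seed = fold_seeds[i], b = b, top_k = top_k,
        pool_size = pool_size, region = region),
      error = function(e) {
        if (grepl("no gene set yielded", conditionMessage(e))) NULL
        else stop(e)
      })
    if (is.null(model)) {
      # featureless fold: the uninformative score, constant across folds
      # (a prevalence score would differ by held-out class and so be
      # anti-predictive by construction in leave-one-out)
      scores[i] <- 0.5
      folds[[i]] <- data.frame(sample_id = samples[i], n_g = NA_integer_,
                               n_f = 0L, cv_auc = NA_real_, modules = "",
                               stringsAsFactors = FALSE)
    } else {
      feats <- module_features(expr[, samples[i], drop = FALSE],
                               model$modules)
      scores[i] <- predict_score(model, feats)
      folds[[i]] <- data.frame(
        sample_id = samples[i],
        n_g = model$metadata$n_g, n_f = model$metadata$n_f,
        cv_auc = model$metadata$cv_auc,
        modules = paste(vapply(model$modules, `[[`, character(1), "name"),
                        collapse = ","),
        stringsAsFactors = FALSE)
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  structure(list(scores = scores, folds = do.call(rbind, folds)),
            class = "loocv_result")
}

#' @exportS3Method base::print
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %d out-of-fold scores\n", length(x$scores)))
  print(summary(x$scores))
  invisible(x)
}
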