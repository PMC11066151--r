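#' ROC AUC with DeLong 95% confidence interval
#'
#' Mann-Whitney AUC of the scores against the outcome (early relapse =
#' positive, higher score = riskier) with the DeLong confidence interval,
#' truncated to `[0, 1]`.
#'
#' @param scores Named numeric scores.
#' @param labels Group labels or 0/1 indicator aligned with `scores` (a
#'   phenotype data frame is also accepted and matched by sample ID).
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(auc, ci_low, ci_high)`.
#' @export
roc_auc_ci <- function(scores, labels, conf = 0.95) {
  y <- resolve_labels(scores, labels)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  roc <- pROC::roc(response = y, predictor = as.numeric(scores),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- withCallingHandlers(
    as.numeric(pROC::ci.auc(roc, conf.level = conf, method = "delong")),
    warning = function(w) {
      # pROC warns that a degenerate (AUC = 1) DeLong interval is 1-1;
      # that is the expected answer here, not a problem
      if (grepl("always 1-1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  c(auc = ci[2], ci_low = max(0, ci[1]), ci_high = min(1, ci[3]))
}

resolve_labels <- function(scores, labels) {
  if (is.data.frame(labels)) {
    if (is.null(names(scores))) {
      stop("scores must be named to match a phenotype table", call. = FALSE)
    }
    return(phenotype_indicator(labels, names(scores)))
  }
  coerce_labels(labels, length(scores))
}

#' Sensitivity and specificity at a score cutoff
#'
#' Binary classification performance of the scores at a fixed cutoff
#' (default 0.5): a sample is called early relapse when its score is
#' strictly above the cutoff (a score exactly at the cutoff is called
#' no relapse). Sensitivity and specificity come with exact
#' Clopper-Pearson 95% confidence intervals.
#'
#' @inheritParams roc_auc_ci
#' @param cutoff Score cutoff (default 0.5).
#' @return List with `sensitivity`, `specificity` (each
#'   `c(estimate, ci_low, ci_high)`), and the counts `tp`, `fn`, `tn`,
#'   `fp`.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff = 0.5, conf = 0.95) {
  y <- resolve_labels(scores, labels)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  pred <- as.integer(scores > cutoff)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  se_ci <- clopper_pearson(tp, tp + fn, conf)
  sp_ci <- clopper_pearson(tn, tn + fp, conf)
  list(sensitivity = c(estimate = tp / (tp + fn), se_ci),
       specificity = c(estimate = tn / (tn + fp), sp_ci),
       tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Average two matched score sets
#'
#' Arithmetic mean of two per-sample score vectors matched by sample ID,
#' as used to combine the bulk-tumor and invasion-front classifier
#' outputs. Samples present in only one set are excluded and reported via
#' a message and the `"excluded"` attribute.
#'
#' @param scores_a,scores_b Named numeric score vectors.
#' @return Named numeric vector of combined scores over the common
#'   samples, with attribute `"excluded"` listing dropped sample IDs.
#' @export
combine_scores <- function(scores_a, scores_b) {
  if (is.null(names(scores_a)) || is.null(names(scores_b))) {
    stop("both score sets must be named by sample ID", call. = FALSE)
  }
  common <- intersect(names(scores_a), names(scores_b))
  if (length(common) == 0) {
    stop("no samples in common between the two score sets", call. = FALSE)
  }
  excluded <- setdiff(union(names(scores_a), names(scores_b)), common)
  if (length(excluded) > 0) {
    message("combine_scores: excluding unmatched samples: ",
            paste(excluded, collapse = ", "))
  }
  out <- (scores_a[common] + scores_b[common]) / 2
  attr(out, "excluded") <- excluded
  out
}

#' Agreement between two matched score sets
#'
#' Pearson and Spearman correlations of the scores and Cohen's kappa of
#' the binary class assignments at the cutoff, over the samples present
#' in both sets.
#'
#' @inheritParams combine_scores
#' @param cutoff Classification cutoff for the kappa (default 0.5).
#' @return Named numeric vector `c(pearson, spearman, kappa)`; the
#'   correlations are `NA` (with a warning) when either score set has
#'   zero variance.
#' @export
score_agreement <- function(scores_a, scores_b, cutoff = 0.5) {
  if (is.null(names(scores_a)) || is.null(names(scores_b))) {
    stop("both score sets must be named by sample ID", call. = FALSE)
  }
  common <- intersect(names(scores_a), names(scores_b))
  if (length(common) < 3) {
    stop("need at least 3 matched samples", call. = FALSE)
  }
  a <- as.numeric(scores_a[common])
  b <- as.numeric(scores_b[common])
  if (var(a) == 0 || var(b) == 0) {
    warning("zero-variance scores: correlations undefined", call. = FALSE)
    pe <- sp <- NA_real_
  } else {
    pe <- cor(a, b, method = "pearson")
    sp <- cor(a, b, method = "spearman")
  }
  c(pearson = pe, spearman = sp,
    kappa = cohens_kappa(as.integer(a > cutoff), as.integer(b > cutoff)))
}

# Cohen's kappa for two binary raters: (p_o - p_e) / (1 - p_e)
cohens_kappa <- function(ca, cb) {
  po <- mean(ca == cb)
  pe <- mean(ca == 1) * mean(cb == 1) + mean(ca == 0) * mean(cb == 0)
  if (1 - pe == 0) {
    if (po == 1) return(1)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Full evaluation report for a set of out-of-fold scores
#'
#' Bundles the AUC (DeLong CI), sensitivity and specificity
#' (Clopper-Pearson CIs) at the cutoff, per-group sample counts, and the
#' scores themselves.
#'
#' @inheritParams confusion_at_cutoff
#' @return List of class `evaluation_report`.
#' @export
evaluate_scores <- function(scores, labels, cutoff = 0.5, conf = 0.95) {
  y <- resolve_labels(scores, labels)
  auc <- roc_auc_ci(scores, y, conf)
  conf_mat <- confusion_at_cutoff(scores, y, cutoff, conf)
  structure(list(scores = scores, auc = auc,
                 sensitivity = conf_mat$sensitivity,
                 specificity = conf_mat$specificity,
                 n_early = sum(y == 1), n_no = sum(y == 0),
                 cutoff = cutoff),
            class = "evaluation_report")
}

#' @exportS3Method base::print
print.evaluation_report <- function(x, ...) {
  fmt <- function(v) sprintf("%.3f (95%% CI %.3f-%.3f)", v[1], v[2], v[3])
  cat(sprintf("<evaluation_report> n = %d early relapse, %d no relapse\n",
              x$n_early, x$n_no))
  cat("  AUC:", fmt(x$auc), "\n")
  cat(sprintf("  Se:  %s  Sp:  %s  (cutoff %.2f)\n",
              fmt(x$sensitivity), fmt(x$specificity), x$cutoff))
  invisible(x)
}
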