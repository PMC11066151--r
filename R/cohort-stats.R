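#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional hypergeometric test. With both margins fixed, the
#' two-sided p-value is the sum of the probabilities of every table whose
#' probability does not exceed that of the observed table (within a
#' relative tolerance of 1e-7, guarding against floating-point
#' near-ties) — the classical "probability at most observed" rule.
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = category,
#'   columns = outcome group).
#' @return Two-sided p-value in `(0, 1]`.
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(tab) < 1) stop("table total must be >= 1", call. = FALSE)
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  support <- max(0, r1 - c2):min(r1, c1)
  probs <- dhyper(support, c1, c2, r1)
  p_obs <- dhyper(a, c1, c2, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Two-sample t-test
#'
#' Student's pooled-variance t-test (default), or Welch's unequal
#' variance variant, two-sided.
#'
#' @param x,y Numeric samples (each of size >= 2).
#' @param pooled Use the pooled-variance Student statistic with
#'   `df = n_x + n_y - 2` (default TRUE); otherwise Welch.
#' @return Named numeric vector `c(t, df, p)`.
#' @export
two_sample_t <- function(x, y, pooled = TRUE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs >= 2 values", call. = FALSE)
  if (pooled) {
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
    if (sp2 == 0) stop("zero pooled variance", call. = FALSE)
    tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    vx <- var(x) / nx; vy <- var(y) / ny
    if (vx + vy == 0) stop("zero variance in both samples", call. = FALSE)
    tt <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  }
  c(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

#' Two-sample pooled t-test from summary statistics
#'
#' Same statistic as [two_sample_t] with `pooled = TRUE`, computed from
#' group means, standard deviations and sizes (as printed in a
#' demographics table).
#'
#' @param mean_x,sd_x,n_x Summary statistics of the first group.
#' @param mean_y,sd_y,n_y Summary statistics of the second group.
#' @return Named numeric vector `c(t, df, p)`.
#' @export
two_sample_t_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y) {
  if (n_x < 2 || n_y < 2) stop("each group needs n >= 2", call. = FALSE)
  sp2 <- ((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / (n_x + n_y - 2)
  if (sp2 == 0) stop("zero pooled variance", call. = FALSE)
  tt <- (mean_x - mean_y) / sqrt(sp2 * (1 / n_x + 1 / n_y))
  df <- n_x + n_y - 2
  c(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact interval for a binomial proportion via beta-distribution
#' quantiles: the lower bound is 0 when there are no successes and the
#' upper bound is 1 when every trial succeeded. Used for the sensitivity
#' and specificity intervals.
#'
#' @param successes,trials Non-negative integer counts with
#'   `successes <= trials`, `trials >= 1`.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @export
clopper_pearson <- function(successes, trials, conf = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials ||
      successes != round(successes) || trials != round(trials)) {
    stop("need integer counts with 0 <= successes <= trials, trials >= 1",
         call. = FALSE)
  }
  alpha <- 1 - conf
  low <- if (successes == 0) 0 else
    qbeta(alpha / 2, successes, trials - successes + 1)
  high <- if (successes == trials) 1 else
    qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(ci_low = low, ci_high = high)
}

#' Demographics ("Table 1") comparison of two outcome groups
#'
#' For every covariate column, compares the early-relapse and no-relapse
#' groups: numeric covariates by the pooled t-test (reported as
#' mean (SD)), two-level categorical covariates by the Fisher exact
#' test (reported as counts).
#'
#' @param pheno Phenotype table (`sample_id`, `group`).
#' @param covariates Data frame with a `sample_id` column plus covariate
#'   columns.
#' @return Data frame with one row per covariate: `covariate`,
#'   `early_relapse`, `no_relapse`, `p_value`, `test`.
#' @export
cohort_table_one <- function(pheno, covariates) {
  validate_phenotype(pheno, require_both = TRUE)
  if (!"sample_id" %in% names(covariates)) {
    stop("covariates must have a sample_id column", call. = FALSE)
  }
  y <- phenotype_indicator(pheno, covariates$sample_id)
  vars <- setdiff(names(covariates), "sample_id")
  rows <- lapply(vars, function(v) {
    val <- covariates[[v]]
    if (is.numeric(val)) {
      res <- two_sample_t(val[y == 1], val[y == 0])
      data.frame(
        covariate = v,
        early_relapse = sprintf("%.1f (%.2f)", mean(val[y == 1]),
                                stats::sd(val[y == 1])),
        no_relapse = sprintf("%.1f (%.2f)", mean(val[y == 0]),
                             stats::sd(val[y == 0])),
        p_value = unname(res["p"]), test = "Student's t-test",
        stringsAsFactors = FALSE)
    } else {
      lev <- sort(unique(as.character(val)))
      if (length(lev) != 2) {
        stop("categorical covariate '", v, "' must have exactly 2 levels",
             call. = FALSE)
      }
      tab <- matrix(c(sum(val == lev[1] & y == 1), sum(val == lev[1] & y == 0),
                      sum(val == lev[2] & y == 1), sum(val == lev[2] & y == 0)),
                    2, 2, byrow = TRUE)
      data.frame(
        covariate = v,
        early_relapse = paste0(lev, ": ", tab[, 1], collapse = ", "),
        no_relapse = paste0(lev, ": ", tab[, 2], collapse = ", "),
        p_value = fisher_exact_two_sided(tab), test = "Fisher's exact test",
        stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
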