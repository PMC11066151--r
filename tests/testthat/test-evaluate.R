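er <- "early_relapse"
nr <- "no_relapse"

test_that("ROC AUC point estimate matches the rank estimator", {
  y <- rep(c(1, 0), c(4, 6))
  s <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1, 0.05)
  res <- roc_auc_ci(s, y)
  expect_equal(unname(res["auc"]), 1)
  set.seed(99)
  for (rep in 1:20) {
    v <- sample(1:4, 10, replace = TRUE)
    expect_equal(unname(roc_auc_ci(v, y)["auc"]), auc_mann_whitney(v, y))
  }
})

test_that("AUC confidence bounds are ordered and inside [0, 1]", {
  set.seed(3)
  y <- rep(c(1, 0), 10)
  s <- y + rnorm(20, sd = 0.8)
  res <- roc_auc_ci(s, y)
  expect_lte(res["ci_low"], res["auc"])
  expect_gte(res["ci_high"], res["auc"])
  expect_gte(res["ci_low"], 0)
  expect_lte(res["ci_high"], 1)
  expect_error(roc_auc_ci(s, rep(1, 20)), "both classes")
})

test_that("sensitivity and specificity match the printed worked example", {
  # 14 of 19 early-relapse above the cutoff; 16 of 20 controls below
  scores <- c(seq(0.55, 0.9, length.out = 14), seq(0.1, 0.45, length.out = 5),
              seq(0.1, 0.45, length.out = 16), seq(0.55, 0.9, length.out = 4))
  labels <- rep(c(er, nr), c(19, 20))
  cm <- confusion_at_cutoff(scores, labels, cutoff = 0.5)
  expect_equal(unname(cm$sensitivity["estimate"]), 14 / 19)
  expect_equal(round(unname(cm$sensitivity["estimate"]), 3), 0.737)
  expect_equal(unname(cm$sensitivity[c("ci_low", "ci_high")]),
               c(0.488, 0.908), tolerance = 1e-3)
  expect_equal(unname(cm$specificity["estimate"]), 16 / 20)
  expect_equal(unname(cm$specificity[c("ci_low", "ci_high")]),
               c(0.563, 0.943), tolerance = 1e-3)
})

test_that("a score exactly at the cutoff is called no-relapse", {
  scores <- c(a = 0.5, b = 0.7, c = 0.5, d = 0.2)
  labels <- c(er, er, nr, nr)
  cm <- confusion_at_cutoff(scores, labels, cutoff = 0.5)
  expect_equal(cm$tp, 1)  # only b
  expect_equal(cm$tn, 2)  # both controls at or below 0.5
  all_right <- confusion_at_cutoff(c(0.9, 0.8, 0.1, 0.2), labels)
  expect_equal(unname(all_right$sensitivity["estimate"]), 1)
  expect_equal(unname(all_right$specificity["estimate"]), 1)
})

test_that("combining matched scores averages and reports the unmatched", {
  a <- c(s1 = 0.2, s2 = 0.8, s3 = 0.4)
  b <- c(s1 = 0.4, s2 = 0.6)
  expect_message(comb <- combine_scores(a, b), "s3")
  expect_equal(comb, c(s1 = 0.3, s2 = 0.7), ignore_attr = TRUE)
  expect_identical(attr(comb, "excluded"), "s3")
  expect_equal(combine_scores(a, a), a, ignore_attr = TRUE)
  expect_error(combine_scores(a, c(zz = 1)), "no samples in common")
})

test_that("averaging two noisy independent scores improves the AUC", {
  # two conditionally independent rank-equivalent views of the same signal
  set.seed(21)
  auc_single <- auc_comb <- numeric(100)
  for (r in 1:100) {
    y <- rep(c(1, 0), c(20, 20))
    ids <- paste0("s", 1:40)
    a <- stats::setNames(plogis(1.5 * y + rnorm(40)), ids)
    b <- stats::setNames(plogis(1.5 * y + rnorm(40)), ids)
    auc_single[r] <- (auc_mann_whitney(a, y) + auc_mann_whitney(b, y)) / 2
    auc_comb[r] <- auc_mann_whitney(combine_scores(a, b), y)
  }
  expect_gt(mean(auc_comb), mean(auc_single))
})

test_that("score agreement statistics behave on canonical cases", {
  a <- c(s1 = 0.1, s2 = 0.6, s3 = 0.9, s4 = 0.4)
  expect_equal(unname(score_agreement(a, a)), c(1, 1, 1))
  flipped <- 1 - a
  res <- score_agreement(a, flipped)
  expect_equal(unname(res["pearson"]), -1)

  # binary assignments [1,1,0,0] vs [1,0,1,0]: observed agreement 0.5
  # equals chance agreement, so kappa is 0
  x <- c(s1 = 0.9, s2 = 0.8, s3 = 0.1, s4 = 0.2)
  z <- c(s1 = 0.9, s2 = 0.1, s3 = 0.8, s4 = 0.2)
  expect_equal(unname(score_agreement(x, z)["kappa"]), 0)

  expect_warning(res0 <- score_agreement(a, c(s1 = 0.5, s2 = 0.5,
                                              s3 = 0.5, s4 = 0.5)),
                 "zero-variance")
  expect_true(is.na(res0["pearson"]))
  expect_error(score_agreement(a[1:2], a[1:2]), "at least 3")
})

test_that("evaluation report bundles AUC and operating characteristics", {
  co <- small_cohort(seed = 12)
  y <- phenotype_ind <- co$phenotype$group
  set.seed(4)
  scores <- stats::setNames(
    plogis(2 * (y == er) - 1 + rnorm(length(y))), co$phenotype$sample_id)
  rep <- evaluate_scores(scores, co$phenotype)
  expect_s3_class(rep, "evaluation_report")
  expect_equal(unname(rep$auc["auc"]), auc_mann_whitney(scores, y))
  expect_equal(rep$n_early, 8)
  expect_output(print(rep), "AUC")
})
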