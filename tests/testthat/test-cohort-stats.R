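test_that("Fisher exact p-values reproduce the printed cohort table", {
  # gender: 7/9 female vs 12/11 men
  expect_equal(fisher_exact_two_sided(matrix(c(7, 12, 9, 11), 2)),
               0.747, tolerance = 1e-3)
  # grade: G2 18/20, G3 1/0
  expect_equal(fisher_exact_two_sided(matrix(c(18, 1, 20, 0), 2)),
               0.487, tolerance = 1e-3)
  # tumor site: right 14/12, left 5/8
  expect_equal(fisher_exact_two_sided(matrix(c(14, 5, 12, 8), 2)),
               0.501, tolerance = 1e-3)
  expect_equal(fisher_exact_two_sided(matrix(c(5, 5, 5, 5), 2)), 1)
})

test_that("Fisher test equals full-margin enumeration and stats::fisher.test", {
  set.seed(17)
  for (rep in 1:60) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_two_sided(tab)
    expect_equal(p, oracle_fisher(tab))
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("Fisher test is invariant under row/column swap and transpose", {
  set.seed(23)
  for (rep in 1:20) {
    tab <- matrix(sample(0:10, 4, replace = TRUE) + c(1, 0, 0, 0), 2)
    p <- fisher_exact_two_sided(tab)
    expect_equal(fisher_exact_two_sided(tab[2:1, ]), p)
    expect_equal(fisher_exact_two_sided(tab[, 2:1]), p)
    expect_equal(fisher_exact_two_sided(t(tab)), p)
  }
  expect_error(fisher_exact_two_sided(matrix(c(-1, 1, 1, 1), 2)),
               "non-negative")
})

test_that("pooled t-test matches stats::t.test and its permutation oracle", {
  set.seed(31)
  x <- rnorm(6); y <- rnorm(6) + 1
  res <- two_sample_t(x, y)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(unname(res["t"]), unname(ref$statistic))
  expect_equal(unname(res["p"]), ref$p.value)

  ident <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(ident["t"]), 0)
  expect_equal(unname(ident["p"]), 1)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero pooled variance")

  # p decreases monotonically as the shift grows
  ps <- vapply(c(0.5, 1, 2, 4), function(d) {
    unname(two_sample_t(c(1, 2, 3), c(1, 2, 3) + d)["p"])
  }, numeric(1))
  expect_true(all(diff(ps) < 0))

  # small-sample agreement with exhaustive label permutations (5+5:
  # 252 permutations, fine enough for the t approximation to track)
  diffs <- vapply(1:10, function(s) {
    set.seed(40 + s)
    x <- rnorm(5); y <- rnorm(5) + 1.2
    abs(unname(two_sample_t(x, y)["p"]) - oracle_perm_t(x, y))
  }, numeric(1))
  expect_lt(mean(diffs), 0.02)
})

test_that("summary-statistic t-test agrees with the raw-data version", {
  set.seed(51)
  x <- rnorm(10, 69.5, 9); y <- rnorm(12, 68.9, 9.5)
  expect_equal(two_sample_t_summary(mean(x), sd(x), 10, mean(y), sd(y), 12),
               two_sample_t(x, y))
})

test_that("Clopper-Pearson intervals reproduce the printed bounds", {
  expect_equal(unname(clopper_pearson(14, 19)), c(0.488, 0.908),
               tolerance = 1e-3)
  expect_equal(unname(clopper_pearson(16, 20)), c(0.563, 0.943),
               tolerance = 1e-3)
  expect_equal(unname(clopper_pearson(0, 10))[1], 0)
  expect_equal(unname(clopper_pearson(10, 10))[2], 1)
  expect_error(clopper_pearson(5, 4), "successes")
  # agreement with the exact binomial test interval
  for (x in c(0, 3, 10, 17, 20)) {
    expect_equal(unname(clopper_pearson(x, 20)),
                 as.numeric(stats::binom.test(x, 20)$conf.int))
  }
})

test_that("Clopper-Pearson empirical coverage is at least nominal", {
  set.seed(61)
  for (p in c(0.1, 0.5, 0.9)) {
    x <- stats::rbinom(10000, 20, p)
    covered <- vapply(x, function(xi) {
      ci <- clopper_pearson(xi, 20)
      ci[1] <= p && p <= ci[2]
    }, logical(1))
    expect_gte(mean(covered), 0.948)
  }
})

test_that("the demographics table assembles counts and tests per covariate", {
  set.seed(71)
  n <- 30
  ph <- data.frame(sample_id = paste0("s", 1:n),
                   group = rep(c("early_relapse", "no_relapse"), c(14, 16)),
                   stringsAsFactors = FALSE)
  cov <- data.frame(sample_id = ph$sample_id,
                    age = rnorm(n, 69, 9),
                    sex = sample(c("F", "M"), n, replace = TRUE),
                    stringsAsFactors = FALSE)
  t1 <- cohort_table_one(ph, cov)
  expect_equal(t1$covariate, c("age", "sex"))
  expect_equal(t1$test, c("Student's t-test", "Fisher's exact test"))
  y <- ph$group == "early_relapse"
  expect_equal(t1$p_value[1],
               unname(two_sample_t(cov$age[y], cov$age[!y])["p"]))
  tab <- table(cov$sex, ph$group)[, c("early_relapse", "no_relapse")]
  expect_equal(t1$p_value[2], fisher_exact_two_sided(as.matrix(tab)))
})
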