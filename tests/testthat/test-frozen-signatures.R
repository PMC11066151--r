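test_that("published signatures have the printed shapes and coefficients", {
  base <- load_published_signature("baseline")
  expect_equal(base$n_f, 5)
  expect_equal(base$n_g, 4)
  expect_null(base$intercept)
  m1 <- base$modules[[1]]
  expect_equal(m1$name, "INTERFERON_GAMMA_RESPONSE_up1")
  expect_equal(m1$genes, c("LATS2", "IRF1", "TRIM14", "APOL6"))
  expect_equal(m1$directions, c(1L, -1L, -1L, -1L))
  expect_equal(base$module_coefficients[1], 1.0545)

  bulk <- load_published_signature("bulk")
  expect_equal(bulk$n_f, 3)
  expect_equal(bulk$n_g, 5)
  aj <- bulk$modules[[3]]
  expect_equal(aj$genes, c("CLDN4", "LAYN", "ITGA9", "NRAP", "CADM3"))
  expect_true(all(aj$directions == 1L))

  front <- load_published_signature("invasion_front")
  expect_equal(front$n_f, 3)
  expect_equal(front$n_g, 4)
  expect_equal(front$module_coefficients, c(0.1652, 0.1527, 0.0915))
  expect_equal(front$modules[[1]]$genes,
               c("VCAN", "CLDN19", "PTEN", "CDH1"))

  expect_error(load_published_signature("nope"))
})

test_that("packaged signatures round-trip bit-exactly through JSON", {
  for (nm in c("baseline", "bulk", "invasion_front")) {
    sig <- load_published_signature(nm)
    path <- withr::local_tempfile(fileext = ".json")
    write_signature(sig, path)
    back <- read_signature(path)
    expect_identical(back$modules, sig$modules)
    expect_identical(back$module_coefficients, sig$module_coefficients)
    expect_null(back$intercept)
    expect_identical(back$region, sig$region)
  }
})

front_expr <- function(values = 0) {
  sig <- load_published_signature("invasion_front")
  genes <- unique(unlist(lapply(sig$modules, `[[`, "genes")))
  m <- matrix(values, nrow = length(genes), ncol = 3,
              dimnames = list(genes, c("s1", "s2", "s3")))
  m
}

test_that("signature scores are linear in expression", {
  sig <- load_published_signature("invasion_front")
  zero <- front_expr(0)
  expect_equal(apply_signature(sig, zero),
               c(s1 = 0, s2 = 0, s3 = 0))

  # +1 on VCAN moves the score by its module coefficient / module size
  bumped <- zero
  bumped["VCAN", "s2"] <- 1
  sc <- apply_signature(sig, bumped)
  expect_equal(sc[["s2"]] - sc[["s1"]], 0.1652 / 4)
})

test_that("signature scores ignore row and column order", {
  set.seed(5)
  expr <- front_expr(0)
  expr[] <- rnorm(length(expr)) + 7
  sc <- apply_signature(load_published_signature("invasion_front"), expr)
  perm <- expr[sample(nrow(expr)), sample(ncol(expr))]
  sc2 <- apply_signature(load_published_signature("invasion_front"), perm)
  expect_equal(sc2[names(sc)], sc)
})

test_that("scores increase in positively signed genes of positive modules", {
  set.seed(6)
  expr <- front_expr(0)
  expr[] <- rnorm(length(expr))
  sig <- load_published_signature("invasion_front")
  for (g in c("VCAN", "CDH1", "EZH1")) {
    up <- expr
    up[g, ] <- up[g, ] + 2
    expect_true(all(apply_signature(sig, up) >
                      apply_signature(sig, expr)))
  }
})

test_that("strict mode rejects missing genes; relaxed mode renormalizes", {
  sig <- load_published_signature("invasion_front")
  expr <- front_expr(0)
  expr[] <- 1
  expr <- expr[setdiff(rownames(expr), "VCAN"), ]
  expect_error(apply_signature(sig, expr), "VCAN")

  expect_warning(sc <- apply_signature(sig, expr, strict = FALSE),
                 "renormalizing by 3")
  # remaining apical junction genes all at 1, d = +1: module value is
  # still 1, so the total equals the all-genes score at x = 1
  full <- front_expr(0); full[] <- 1
  expect_equal(sc, apply_signature(sig, full))
})

test_that("per-gene standardization centers the cohort scores", {
  set.seed(9)
  expr <- front_expr(0)
  expr <- matrix(rnorm(length(expr) * 4, 7, 1.5), nrow(expr), 12,
                 dimnames = list(rownames(expr), paste0("s", 1:12)))
  sig <- load_published_signature("invasion_front")
  sc <- apply_signature(sig, expr, standardize = TRUE)
  expect_lt(abs(mean(sc)), 0.5)
  # standardization preserves within-cohort ranking structure per gene
  expect_length(sc, 12)
})
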