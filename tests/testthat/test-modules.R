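test_that("module value is the direction-weighted mean", {
  # published baseline module shape: +LATS2 -IRF1 -TRIM14 -APOL6
  m <- gene_module("IFN_up1", c("LATS2", "IRF1", "TRIM14", "APOL6"),
                   c(1, -1, -1, -1))
  expr <- matrix(c(2, 1, 1, 1), ncol = 1,
                 dimnames = list(m$genes, "s1"))
  expr <- cbind(expr, s2 = 0)
  expect_equal(module_score(expr, m), c(s1 = -0.25, s2 = 0))

  single <- gene_module("one", "LATS2", 1)
  expr2 <- matrix(c(5, 1), 1, dimnames = list("LATS2", c("a", "b")))
  expect_equal(module_score(expr2, single), c(a = 5, b = 1))

  m2 <- gene_module("x", c("LATS2", "IRF1"), c(1, -1))
  expect_error(module_score(expr2, m2), "IRF1")
})

test_that("module score is linear and reduces to the mean for all +1", {
  set.seed(1)
  expr <- matrix(rnorm(20), 5, 4,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  m <- gene_module("m", paste0("g", 1:4), c(1, -1, 1, -1))
  base <- module_score(expr, m)
  shifted <- expr
  shifted[, 2] <- shifted[, 2] + 3
  expect_equal(module_score(shifted, m)[2],
               base[2] + 3 * sum(m$directions) / 4)

  m_all <- gene_module("m2", paste0("g", 1:4), rep(1, 4))
  expect_equal(module_score(expr, m_all),
               colMeans(expr[paste0("g", 1:4), ]))
})

test_that("candidate enumeration respects pool and stability rules", {
  co <- small_cohort(seed = 3)
  st <- bootstrap_gene_stability(co$bulk, co$phenotype, b = 25, seed = 1)

  # a set with exactly n_g stable genes yields exactly one module
  stable_genes <- st$gene_id[st$stable]
  sets <- list(EXACT = stable_genes[1:3],
               SHORT = c(stable_genes[4:5], st$gene_id[!st$stable][1]))
  mods <- candidate_modules("EXACT", sets, st, co$bulk, co$phenotype,
                            n_g = 3)
  expect_length(mods, 1)
  expect_setequal(mods[[1]]$genes, stable_genes[1:3])
  expect_equal(mods[[1]]$name, "EXACT_1")

  # n_g - 1 stable genes: no module
  expect_length(candidate_modules("SHORT", sets, st, co$bulk,
                                  co$phenotype, n_g = 3), 0)
})

test_that("candidate module AUCs are non-increasing and top_k bounded", {
  co <- small_cohort(seed = 4)
  st <- bootstrap_gene_stability(co$bulk, co$phenotype, b = 25, seed = 2)
  mods <- candidate_modules("SET_1", co$gene_sets, st, co$bulk,
                            co$phenotype, n_g = 3, top_k = 5)
  expect_lte(length(mods), 5)
  aucs <- vapply(mods, `[[`, numeric(1), "train_auc")
  expect_true(all(diff(aucs) <= 1e-12))
  for (m in mods) {
    expect_true(all(m$genes %in% co$gene_sets$SET_1))
    expect_equal(m$train_auc,
                 auc_mann_whitney(module_score(co$bulk, m),
                                  co$phenotype$group))
  }
})

test_that("planted signal is recovered in the top module", {
  # a set mixing 4 signal-carrying genes with 8 null genes: the top
  # module of size 4 should consist of the signal genes
  hits <- 0
  for (s in 1:10) {
    cfg <- sim_config(n_genes = 300, n_sets = 3, genes_per_set = 8,
                      n_early = 19, n_no = 20, planted_sets = "SET_1",
                      effect_size = 1.5, frac_negative = 0.25,
                      missing_if = 0, seed = 100 + s)
    co <- simulate_cohort(cfg)
    planted4 <- names(co$planted_effects)[1:4]
    nulls <- setdiff(rownames(co$bulk), names(co$planted_effects))[1:8]
    sets <- c(co$gene_sets, list(MIX = c(planted4, nulls)))
    st <- bootstrap_gene_stability(co$bulk, co$phenotype, b = 50, seed = s)
    mods <- candidate_modules("MIX", sets, st, co$bulk,
                              co$phenotype, n_g = 4, pool_size = 8)
    if (length(mods) > 0 && all(mods[[1]]$genes %in% planted4)) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})

test_that("top-module selection ranks by training AUC across sets", {
  mk <- function(name, auc, set = "S") {
    gene_module(name, paste0(name, "_g", 1:2), c(1, 1),
                source_set = set, train_auc = auc)
  }
  mods <- list(mk("a", 0.7), mk("b", 0.9, "T"), mk("c", 0.8),
               mk("d", 0.95, "T"))
  top <- select_top_modules(mods, 3)
  expect_identical(vapply(top, `[[`, character(1), "name"),
                   c("d", "b", "c"))
  # two modules from the same source set are both kept
  expect_equal(sum(vapply(top, `[[`, character(1), "source_set") == "T"), 2)

  expect_warning(all_two <- select_top_modules(mods[1:2], 5), "only 2")
  expect_length(all_two, 2)
  expect_error(select_top_modules(list(), 3), "no candidate")
})
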