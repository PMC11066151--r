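# Independent brute-force oracles the implementation is checked against.

# Pair-counting AUC: fraction of (positive, negative) pairs won, ties 0.5.
oracle_auc <- function(values, y) {
  pos <- values[y == 1]
  neg <- values[y == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Two-sided Fisher p by full enumeration of every table with the observed
# margins, using explicit binomial coefficients (no dhyper).
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(a_range, function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }, numeric(1))
  p_obs <- prob[a_range == tab[1, 1]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Exhaustive label-permutation p-value for the pooled t statistic.
oracle_perm_t <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v)
  nx <- length(x)
  t_obs <- abs(unname(two_sample_t(x, y)["t"]))
  combos <- combn(n, nx)
  hits <- 0
  for (j in seq_len(ncol(combos))) {
    xi <- combos[, j]
    tj <- abs(unname(two_sample_t(all_v[xi], all_v[-xi])["t"]))
    if (tj >= t_obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(combos)
}

# Small planted-signal cohort for fast pipeline tests.
small_cohort <- function(seed = 1L, effect_size = 2, n_early = 8L,
                         n_no = 8L, n_genes = 120L, n_sets = 6L,
                         genes_per_set = 12L, planted = "SET_1") {
  cfg <- sim_config(n_genes = n_genes, n_sets = n_sets,
                    genes_per_set = genes_per_set,
                    n_early = n_early, n_no = n_no,
                    planted_sets = planted, effect_size = effect_size,
                    missing_if = 2L, seed = seed)
  simulate_cohort(cfg)
}

tiny_expr <- function() {
  m <- matrix(c(1, 2, 3, 4,
                4, 3, 2, 1,
                0, 1, 0, 1), nrow = 3, byrow = TRUE)
  dimnames(m) <- list(c("gA", "gB", "gC"), paste0("s", 1:4))
  m
}
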