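#' Simulation configuration for a paired two-region cohort
#'
#' Bundles and validates the parameters of the synthetic cohort generator.
#' The defaults emulate the kind of data the discovery pipeline targets: a
#' small matched case-control cohort (19 early-relapse vs. 20 no-relapse
#' bulk profiles, 4 samples lacking an invasion-front profile), RMA-like
#' log-intensity values, a hallmark-style collection of gene sets, and
#' differential signal planted in a few sets with mixed per-gene signs.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_sets Number of gene sets generated.
#' @param genes_per_set Genes per set (sets may overlap).
#' @param n_early Early-relapse samples.
#' @param n_no No-relapse samples.
#' @param planted_sets Names of sets carrying differential signal
#'   (subset of `paste0("SET_", seq_len(n_sets))`).
#' @param effect_size Per-gene mean shift (log2 units) of planted genes
#'   between outcome groups; must be >= 0.
#' @param frac_negative Fraction of planted genes shifted downward in the
#'   early-relapse group (so modules with mixed directions arise).
#' @param region_correlation Correlation in `[0, 1]` between a sample's
#'   bulk and invasion-front residuals, induced by a shared latent draw.
#' @param noise_sd Residual standard deviation (log2 units).
#' @param missing_if Number of samples without an invasion-front profile.
#' @param seed Integer seed; fixed seed gives bit-identical cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_sets = 30L, genes_per_set = 25L,
                       n_early = 19L, n_no = 20L,
                       planted_sets = character(0),
                       effect_size = 1, frac_negative = 0.3,
                       region_correlation = 0.6, noise_sd = 1,
                       missing_if = 4L, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_sets = as.integer(n_sets),
              genes_per_set = as.integer(genes_per_set),
              n_early = as.integer(n_early), n_no = as.integer(n_no),
              planted_sets = as.character(planted_sets),
              effect_size = as.numeric(effect_size),
              frac_negative = as.numeric(frac_negative),
              region_correlation = as.numeric(region_correlation),
              noise_sd = as.numeric(noise_sd),
              missing_if = as.integer(missing_if), seed = as.integer(seed))
  counts <- c(n_genes = cfg$n_genes, n_sets = cfg$n_sets,
              genes_per_set = cfg$genes_per_set,
              n_early = cfg$n_early, n_no = cfg$n_no)
  if (any(counts < 1L)) {
    stop("counts must be >= 1: ",
         paste(names(counts)[counts < 1L], collapse = ", "), call. = FALSE)
  }
  if (cfg$missing_if < 0L) stop("missing_if must be >= 0", call. = FALSE)
  if (cfg$missing_if >= cfg$n_early + cfg$n_no) {
    stop("missing_if must be smaller than the total number of samples",
         call. = FALSE)
  }
  if (cfg$genes_per_set > cfg$n_genes) {
    stop("genes_per_set cannot exceed n_genes", call. = FALSE)
  }
  if (cfg$region_correlation < 0 || cfg$region_correlation > 1) {
    stop("region_correlation must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (cfg$frac_negative < 0 || cfg$frac_negative > 1) {
    stop("frac_negative must lie in [0, 1]", call. = FALSE)
  }
  set_names <- paste0("SET_", seq_len(cfg$n_sets))
  bad <- setdiff(cfg$planted_sets, set_names)
  if (length(bad) > 0) {
    stop("planted_sets not among generated set names: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic gene-set collection
#'
#' Draws `n_sets` sets of `genes_per_set` distinct genes from a universe
#' of `n_genes` genes (`g0001`, `g0002`, ...). Sets are named `SET_1` ...
#' `SET_n` and may overlap, like hallmark-style collections do.
#'
#' @param n_sets Number of sets.
#' @param genes_per_set Genes per set.
#' @param n_genes Size of the gene universe.
#' @param seed Integer seed.
#' @return Named list of character vectors (a gene-set collection).
#' @export
generate_gene_sets <- function(n_sets, genes_per_set, n_genes, seed = 1L) {
  if (genes_per_set > n_genes) {
    stop("genes_per_set cannot exceed n_genes", call. = FALSE)
  }
  if (n_sets < 1 || genes_per_set < 1) {
    stop("n_sets and genes_per_set must be >= 1", call. = FALSE)
  }
  universe <- gene_universe(n_genes)
  set.seed(as.integer(seed))
  sets <- lapply(seq_len(n_sets), function(i) {
    sort(sample(universe, genes_per_set))
  })
  names(sets) <- paste0("SET_", seq_len(n_sets))
  validate_gene_sets(sets)
  sets
}

gene_universe <- function(n_genes) {
  sprintf("g%04d", seq_len(n_genes))
}

# Signed per-gene shifts for the planted sets: the union of their genes,
# with a deterministic frac_negative share flipped downward.
planted_effects <- function(cfg, sets) {
  planted_genes <- sort(unique(unlist(sets[cfg$planted_sets])))
  if (length(planted_genes) == 0) {
    return(numeric(0))
  }
  n_neg <- floor(cfg$frac_negative * length(planted_genes))
  signs <- rep(1, length(planted_genes))
  if (n_neg > 0) signs[seq_len(n_neg)] <- -1
  effects <- signs * cfg$effect_size
  names(effects) <- planted_genes
  effects
}

#' Simulate a paired bulk / invasion-front cohort
#'
#' Generates log-intensity-like expression for two outcome groups in two
#' tumor regions. Each gene has a baseline level; genes belonging to the
#' planted sets are shifted by `effect_size` (in expectation) between the
#' early-relapse and no-relapse groups, with a `frac_negative` share
#' shifted downward; all other genes have equal group means. For every
#' sample the bulk and invasion-front residuals share a latent draw so
#' that their correlation equals `region_correlation`. The last
#' `missing_if` samples (alternating between outcome groups) lack an
#' invasion-front profile, as happens when region sampling fails QC.
#'
#' @param config A [sim_config].
#' @param gene_sets Optional gene-set collection; by default generated
#'   from the config via [generate_gene_sets] with the same seed.
#' @return A list with elements `bulk` and `invasion_front` (expression
#'   matrices), `phenotype` (data frame), `gene_sets`, and
#'   `planted_effects` (named per-gene signed shifts).
#' @export
simulate_cohort <- function(config, gene_sets = NULL) {
  if (!inherits(config, "sim_config")) {
    stop("config must be built with sim_config()", call. = FALSE)
  }
  cfg <- config
  if (is.null(gene_sets)) {
    gene_sets <- generate_gene_sets(cfg$n_sets, cfg$genes_per_set,
                                    cfg$n_genes, seed = cfg$seed)
  }
  validate_gene_sets(gene_sets)
  universe <- gene_universe(cfg$n_genes)
  n <- cfg$n_early + cfg$n_no
  sample_ids <- c(sprintf("ER_%02d", seq_len(cfg$n_early)),
                  sprintf("NR_%02d", seq_len(cfg$n_no)))
  group <- rep(GROUP_LEVELS, c(cfg$n_early, cfg$n_no))
  is_early <- group == POSITIVE_CLASS

  effects <- planted_effects(cfg, gene_sets)
  delta <- numeric(cfg$n_genes)
  names(delta) <- universe
  delta[names(effects)] <- effects

  set.seed(cfg$seed)
  baseline <- rnorm(cfg$n_genes, mean = 7, sd = 1.5)
  # split the shift symmetrically so neither group carries the whole offset
  mu <- outer(baseline, rep(1, n)) +
    outer(delta / 2, ifelse(is_early, 1, -1))
  rho <- cfg$region_correlation
  latent <- matrix(rnorm(cfg$n_genes * n), cfg$n_genes, n)
  eps_b <- matrix(rnorm(cfg$n_genes * n), cfg$n_genes, n)
  eps_f <- matrix(rnorm(cfg$n_genes * n), cfg$n_genes, n)
  bulk <- mu + cfg$noise_sd * (sqrt(rho) * latent + sqrt(1 - rho) * eps_b)
  front <- mu + cfg$noise_sd * (sqrt(rho) * latent + sqrt(1 - rho) * eps_f)
  dimnames(bulk) <- dimnames(front) <- list(universe, sample_ids)

  dropped <- dropped_front_samples(cfg$n_early, cfg$n_no, cfg$missing_if)
  keep <- setdiff(sample_ids, sample_ids[dropped])
  front <- front[, keep, drop = FALSE]

  pheno <- data.frame(sample_id = sample_ids, group = group,
                      stringsAsFactors = FALSE)
  validate_expression_matrix(bulk)
  if (ncol(front) >= 2) validate_expression_matrix(front)
  validate_phenotype(pheno)
  list(bulk = bulk, invasion_front = front, phenotype = pheno,
       gene_sets = gene_sets, planted_effects = effects)
}

# Deterministic choice of which samples lack an invasion-front profile:
# taken from the tail of each group, alternating early / no relapse.
dropped_front_samples <- function(n_early, n_no, missing_if) {
  if (missing_if == 0) return(integer(0))
  early_tail <- rev(seq_len(n_early))
  no_tail <- rev(n_early + seq_len(n_no))
  picks <- integer(0)
  i_e <- 1L
  i_n <- 1L
  for (k in seq_len(missing_if)) {
    if (k %% 2 == 1 && i_e <= n_early) {
      picks <- c(picks, early_tail[i_e]); i_e <- i_e + 1L
    } else if (i_n <= n_no) {
      picks <- c(picks, no_tail[i_n]); i_n <- i_n + 1L
    } else {
      picks <- c(picks, early_tail[i_e]); i_e <- i_e + 1L
    }
  }
  sort(picks)
}

#' Write a simulated cohort to disk
#'
#' Writes the bulk and invasion-front expression TSVs, the phenotype TSV
#' and the gene-set GMT into a directory.
#'
#' @param cohort Result of [simulate_cohort].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_matrix(cohort$bulk, file.path(dir, "bulk.tsv"))
  write_expression_matrix(cohort$invasion_front,
                          file.path(dir, "invasion_front.tsv"))
  write_phenotype(cohort$phenotype, file.path(dir, "phenotype.tsv"))
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  invisible(dir)
}
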