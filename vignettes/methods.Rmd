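---
title: "Signature discovery for early relapse from bulk and invasion-front expression: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature discovery for early relapse: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frontsig)
```

## The problem

Stage IIA (pT3N0) microsatellite-stable colon cancers are classed as
low risk and usually not given adjuvant chemotherapy, yet a fraction of
these patients relapse within five years. `frontsig` implements a
discovery pipeline for gene-expression signatures of that early relapse,
designed for the data situation such studies face: a retrospective
matched case-control cohort of a few dozen patients, log-scale
expression matrices from each tumor's bulk and from its invasion front
(the tumor–host contact border), and a curated gene-set collection
(hallmark-style, in GMT format) to structure the feature space. The
endpoint contrast is deliberately sharpened: relapse within 5 years
versus no relapse for at least 6 years.

At this sample size (roughly 19 vs. 20), single genes do not survive
multiple-testing correction, so the pipeline never relies on per-gene
significance. Instead it ranks genes by a robust discrimination measure,
stabilizes the ranking by resampling, and aggregates genes into small
signed modules before any classifier sees the data.

## The model, step by step

### Per-gene screening

For gene $g$ with expression $x_g$, the discrimination measure is the
Mann–Whitney AUC of the rule "higher $x_g$ implies early relapse":
the fraction of (early, no-relapse) sample pairs with
$x_{g,\text{early}} > x_{g,\text{no}}$, ties counted $1/2$. The
direction of association is

$$d_g = \begin{cases} +1 & \bar x_g(\text{early}) > \bar x_g(\text{no}) \\
                      -1 & \bar x_g(\text{early}) < \bar x_g(\text{no}) \end{cases}$$

with exact equality leaving the direction undefined. Over $b = 50$
bootstrap resamples of the training set, a gene is **stable** when its
direction is defined and identical in every resample, and its reported
AUC is the bootstrap average. Resampling is stratified by outcome group
(each group resampled at its own size) so both classes are present in
every resample and the per-resample AUC is always defined; whether the
original analysis stratified is not documented, but without
stratification a resample can lose a class entirely at these group
sizes. All genes are evaluated on the *same* resamples, drawn once from
one seeded stream, because the resampling unit is the sample, not the
gene.

### Signed modules

A module of $n_g$ genes from one gene set scores sample $s$ as

$$v(s) = \frac{1}{n_g} \sum_{g} d_g\, x_{gs},$$

the direction-weighted mean. Within each set, stable genes are ranked by
**oriented AUC** — $\mathrm{auc}_g$ if $d_g = +1$ and
$1 - \mathrm{auc}_g$ if $d_g = -1$ — so strongly down-regulated genes
compete equally with up-regulated ones; this is what lets modules with
mixed signs arise. The enumeration space for "the top subsets of a
set" is not fully specified by a ranking alone, so the package
enumerates *all* $n_g$-subsets of the top `pool_size` (default 8)
ranked genes, scores each subset by the training AUC of its module
value, and keeps the best `top_k` (default 5) subsets as candidate
modules. The cap of 8 bounds the combinatorics at
$\binom{8}{4} = 70$ subsets per set while leaving room above $n_g$ for
the subset search to matter. Ties between equal-AUC subsets break by the
larger sum of member oriented AUCs, then lexicographic gene order —
fully deterministic.

### Classifier and grid

The $n_f$ candidate modules with highest training AUC across the whole
collection (several modules per set allowed, gene reuse allowed) become
features of an elastic-net logistic regression. Penalty mixing
$\alpha \in \{0.1, 0.5, 0.9\}$ and strength $\lambda$ (30-point glmnet
path) are tuned by internal stratified 5-fold cross-validation
maximizing out-of-fold AUC. At $n \approx 38$ the CV AUC routinely
plateaus at its maximum across a stretch of the $\lambda$ path; AUC
ties are therefore broken by the smaller out-of-fold binomial deviance
(better-calibrated posteriors), then the stronger penalty, then the
smaller $\alpha$. Without the deviance tie-break the plateau's most
penalized end wins, producing near-intercept-only models whose pooled
leave-one-out scores are dominated by per-fold calibration noise.

Module size and count are searched over
$n_g, n_f \in \{3, 4, 5\}$ — small on purpose, to limit overfitting —
and the grid point with the best internal-CV AUC is kept (ties: smaller
deviance, then the earlier grid point). The selection rule for the
published models' reported $(n_g, n_f)$ is not documented; internal-CV
AUC inside the training fold is the non-leaky choice.

### External leave-one-out loop

All of the above — screening, enumeration, selection, grid search,
fitting — is wrapped in an external leave-one-out loop: every stage is
re-run from scratch on $n - 1$ samples and the held-out sample is
scored by the resulting model. The held-out label is never touched, and
the test suite asserts this directly by flipping a held-out label and
requiring the identical score. Per-fold seeds derive from one master
seed, so the whole loop is reproducible bit for bit.

If a training fold yields no candidate module anywhere (possible on
signal-free data, where few genes pass the stability screen), the fold
falls back to the featureless model and scores the held-out sample 0.5.
The constant matters: a class-prevalence score would differ by the
held-out sample's own class (18/38 vs. 19/38) and hence be
anti-predictive by construction — an artifact of pooled leave-one-out,
not a property of the data.

### Evaluation and region combination

Out-of-fold scores are summarized by the Mann–Whitney AUC with DeLong
95% CI and, at the fixed 0.5 cutoff, sensitivity and specificity with
exact Clopper–Pearson intervals (a score exactly at the cutoff is
called no-relapse). Matched bulk and invasion-front scores are combined
by the arithmetic mean; their agreement is reported as Pearson and
Spearman correlations of the scores and Cohen's kappa of the 0.5-cutoff
class assignments. Zero-variance score vectors make the correlations
undefined; they are returned as `NA` with a warning rather than a
silent 0.

### Cohort statistics

The demographics comparisons use the two-sided Fisher exact test with
the "probability at most observed" summation rule (tables with the
observed margins whose conditional probability does not exceed the
observed table's, within a relative tolerance of $10^{-7}$) and the
pooled-variance Student t-test. This Fisher convention reproduces the
reference demographics p-values exactly (e.g. $p = 0.487 = 19/39$ for
an 18/1 vs. 20/0 grade split), which is how the convention was pinned
down. Sensitivity/specificity intervals use Clopper–Pearson beta
quantiles — the only standard method consistent with the printed
intervals for 14/19 and 16/20.

## The synthetic cohort generator

`simulate_cohort()` emulates exactly the structure the pipeline
assumes, and is itself tested code:

* **Cohort shape.** Two outcome groups (default 19 early relapse, 20 no
  relapse); invasion-front profiles missing for `missing_if = 4`
  samples, dropped deterministically from the tails of both groups
  (giving the 39 bulk / 35 front split).
* **Values.** Additive Gaussian noise on the log scale around per-gene
  baselines $\mathcal N(7, 1.5^2)$ — the simplest model matching
  RMA-style log intensities. Default residual SD 1.
* **Pairing.** Bulk and invasion-front residuals of the same
  gene–sample cell share a latent draw with mixing weight
  $\sqrt{\rho}$, giving between-region correlation exactly
  `region_correlation` (default 0.6, chosen a priori to produce the
  kind of modest between-region score agreement a paired-region study
  reports; with the default it lands near 0.5–0.65).
* **Signal.** Genes of the `planted_sets` shift by `effect_size`
  (default 1 noise-SD, a realistic per-gene effect for a detectable
  small-cohort signature) between groups, split symmetrically; a
  `frac_negative` share (default 0.3) shifts downward so modules with
  mixed $d_g$ arise.

What it does **not** emulate: probe-level structure, cross-platform
batch effects, survival times, gene–gene correlation beyond the shared
latent factor, or heavier-than-Gaussian tails. Passing tests on this
generator therefore demonstrate the pipeline's statistical mechanics —
calibration under the null, recovery of planted signal, leakage
freedom — not performance on real microarray cohorts.

## Numerical and degenerate-input choices

* AUC ties count 0.5; mid-ranks handle tied expression values.
* Exact mean equality leaves a gene's direction undefined and the gene
  unstable — the conservative reading.
* Probeset collapse (for probe-level input) keeps the most variable
  probeset per gene, variance with denominator $n - 1$; variance ties
  break to the lexicographically smallest probeset ID.
* Constant-feature designs return zero coefficients and class-prior
  scores; single-feature designs are padded internally for glmnet.
* Frozen signatures ship without intercepts (none were published): they
  yield rank-valid linear risk scores, and classification requires a
  user-chosen cutoff. Whether the published coefficients expect raw or
  standardized log expression is not documented either; a
  `standardize` flag covers the per-gene z-scored reading, with raw
  log-scale input as the default.
* In relaxed mode, `apply_signature()` drops missing genes and
  renormalizes each affected module by its remaining size, with a
  warning; strict mode (default) errors.

## Problem sizes used by the test suite

Unit tests run on small generated cohorts (8–16 samples, 40–300
genes). The end-to-end acceptance checks run at the target scale — 39
samples, 2,000 genes, 30 sets of 25 genes — with 20 replicate null
cohorts for the calibration check and 5 replicate planted cohorts
(signal in 3 of 30 sets) for the recovery check. Under the null the
pooled leave-one-out AUC of this pipeline is *not* centered at 0.5 but
slightly below (mean $\approx 0.41$ across replicates): in-fold module
selection overfits the training samples, so held-out samples regress to
the mean — a known pessimistic bias of pooled leave-one-out with
in-loop feature selection. The calibration band in the tests
($[0.40, 0.60]$ for the mean) sits right at the edge of that bias,
which is why the mean is taken over 20 replicates.

## Known limitations

* The subset-enumeration rule ("top five subsets of $n_g$ genes") and
  the grid-selection rule are under-specified by the source method
  description; the package's choices (pool of 8, internal-CV AUC with
  deviance tie-breaks) are deterministic and documented but not the
  only defensible readings.
* Pooled leave-one-out AUC is pessimistically biased under weak signal
  (see above); reported AUCs are conservative.
* The frozen signatures cannot be re-validated here against their
  original cohorts, which require external microarray data; the package
  only guarantees faithful application of the published coefficients.
* `cohort_table_one()` handles numeric and two-level categorical
  covariates — the shapes that occur in this design — not multi-level
  exact tests.
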