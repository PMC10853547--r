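---
title: "Methods: linking single-cell tumor populations to bulk prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking single-cell tumor populations to bulk prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmelink)
```

# Overview

`tmelink` connects three data worlds that tumor-microenvironment studies
must reconcile: single-cell expression (which resolves cell populations
but has no outcomes), bulk expression cohorts (which have survival
follow-up but mix cell types), and cell-line pharmacogenomics (which
links expression to drug response). The pipeline is: discover a
population's marker signature in single cells; score that signature per
patient in purity-adjusted bulk cohorts; dichotomize at a maximally
selected log-rank cutpoint and call a population prognostically adverse
only when the association replicates in every cohort; then characterize
the population's ecosystem through frequency co-enrichment,
ligand–receptor permutation tests, spatial proximity, and a
stratified in-silico drug screen.

This vignette records the models, the tunable parameters, the numerical
choices, and the design decisions taken where the design was genuinely
open. Every empirical statement here is computed by the test suite or by
`scripts/acceptance.R`; nothing is quoted from elsewhere.

# Single-cell core

**QC.** Cells are kept when they have strictly more than `min_genes`
(default 200) detected genes, total counts strictly above `min_counts`
(1000) and at most `max_counts` (30000), and a mitochondrial fraction of
at most `max_mito_frac` (0.20). Mitochondrial genes default to the
`MT-` symbol prefix because no canonical list is universal; an explicit
list can be supplied, as can an exclusion-list collection (mitochondrial
/ heat-shock / ribosomal / dissociation genes) that is removed *after*
the cell filter so the filter statistics reflect the full library.
Doublet detection is out of scope; the QC report states that it was not
applied rather than silently implying it was. The filter is idempotent.

**Normalization** is library-size scaling to 10,000 counts followed by
natural `log1p`. The inverse identity `colSums(expm1(out)) == 10^4` is
asserted in tests.

**Marker discovery** is a one-vs-rest two-sided Wilcoxon rank-sum test
per gene and cluster with BH adjustment within cluster, and
`log2((mean expm1 in + 1e-9) / (mean expm1 out + 1e-9))` as the fold
change. The test uses the exact rank-sum distribution when both groups
have ≤ 50 tie-free observations and a normal approximation with tie and
continuity correction otherwise — the same switching rule as base R's
`wilcox.test`, which makes the p-values verifiable against exhaustive
permutation enumeration on small groups. Signature sets are then cut at
log2FC > 1 and adjusted p < 0.05.

**CNV inference** deliberately simplifies the HMM-based tools: per-gene
reference subtraction, clipping at ±3, a centered moving average of 101
genes within each chromosome (truncated at the ends, chromosomes with
fewer than 3 genes dropped), per-cell median recentering, and the score
`mean(smoothed²)`. Malignancy is a 2-means split on the scores with the
higher-mean class malignant. The simplification is adequate for the task
the score serves here — separating cells carrying multi-hundred-gene
expression shifts from diploid references — which the tests quantify: a
+0.5 log2 block over 220 of 800 genes yields a score-ranking AUC above
0.9, while the hard 2-means *call* is noticeably noisier than the
ranking (accuracy ≈ 0.7–0.85). Downstream analyses should prefer the
scores where possible.

# Gene-set scoring

Four scorers are implemented from scratch because they are the
analytical core being exercised, each with its conventional defaults
exposed:

- **ssGSEA** (`alpha = 0.25`, `normalize = TRUE`): per observation,
  genes are ranked by decreasing expression (average ties); the score is
  the sum over rank positions of the weighted in-set cumulative fraction
  (weight `rank^alpha`) minus the uniform out-of-set fraction.
  Normalization divides by the global max−min across all observations
  and sets. Whether scores are normalized before survival
  dichotomization is not an established convention; both modes are
  supported, the default is flagged as an assumption, and the cutpoint
  split itself is rank-invariant so the choice only matters across sets.
- **GSVA-like** (`tau = 1`, `mx_diff = TRUE`, bandwidth sd/4): per gene,
  a Gaussian-kernel CDF across observations; per observation the
  statistics become ranks symmetrized about the midpoint, and a KS-like
  walk weighted by `|rank|^tau` gives max-positive plus min-negative
  deviation. Constant genes get the midpoint statistic with a warning.
- **AUCell** (`max_rank_frac = 0.05`): area under the recovery curve of
  set genes within the top ranks, normalized by the maximum achievable
  area; expression ties are broken uniformly at random under the seed,
  which is recorded in the output parameters.
- **Module score** (24 bins, 100 controls/gene): set mean minus the mean
  of bin-matched control genes, sampled with replacement when a bin is
  small.

ssGSEA and AUCell are invariant to strictly monotone transforms; GSVA is
invariant to per-gene constant shifts. All scorers commute with
observation permutation. These are property-tested, and ssGSEA is
checked against a naive running-sum oracle.

# Survival linking

**Purity.** The ESTIMATE-style transform
`purity = cos(a + b·(stromal + immune ssGSEA score))` uses the original
publication's constants (configurable); user-supplied purity is always
accepted since real signature lists are external resources. Expression
is then residualized gene-wise on purity by OLS; residuals are mean-zero
and orthogonal to purity by construction (asserted to 1e-8).

**Cutpoint, log-rank, Cox.** The cutpoint scan evaluates every unique
score value whose split leaves at least `minprop = 0.1` of samples on
each side and takes the maximal standardized log-rank statistic, ties
toward the smaller value. The log-rank O/E/V tabulation and the
univariate Cox fit (Newton–Raphson on the Breslow partial likelihood,
convergence 1e-8, complete separation reported as an infinite/zero HR
sentinel) are implemented here and cross-checked in the test suite
against `survival::survdiff` / `coxph` and a brute-force hypergeometric
oracle. Hazard ratios for the population grid come from this univariate
Cox fit on the high/low split, a decision recorded in the output.

**Consistency rule.** Adverse = HR > 1 and log-rank p < 0.05 in *every*
cohort (favorable symmetric); anything else is inconsistent. A
direction-only mode exists but is not the default, because
maximally-selected cutpoints inflate single-cohort type-I error and the
all-cohorts significance requirement is what restores specificity: in
null calibration (no planted hazard) roughly 1% of population×scan
combinations produce a spurious consistent call, and none were adverse
in the planted-scan calibration.

**TME module.** Marker sets of the co-enriched populations are unioned,
scored by GSVA per patient, split at the optimal cutpoint, and TME
feature sets are compared high-vs-low by Wilcoxon with BH adjustment.

# Crosstalk

Co-enrichment is plain Pearson correlation of per-sample population
frequencies with the r > 0.3 significance rule (strict inequality,
off-diagonal). The ligand–receptor test mirrors the permutation logic of
the established cluster-pair tools: statistic = mean of (sender ligand
mean, receiver receptor mean); labels permuted within the union of the
two clusters only (`n_perm = 1000`, one-sided with add-one correction,
so the p floor is 1/1001); pairs below a 10 % expression fraction in
either role are skipped. Raw p < 0.05 is the primary readout, matching
the convention of the method emulated; a BH column is optional.
Multi-subunit complexes are not modeled — pairs are gene–gene.

Spatial proximity uses exact nearest-neighbor distances within each ROI,
capped at 200 μm (beyond-radius sources are excluded and counted), and
reports both per-ROI means and the pooled cell-level Wilcoxon comparison
of the two source phenotypes, since either summary is defensible for
ROI-based imaging data.

# Drug screen

The imputer is ridge regression of log-IC50 on standardized
top-variance genes (default 1000) with an unpenalized intercept. λ is
selected by generalized cross-validation over `10^seq(-3, 3)` — a
deterministic analogue of the auto-selection in the cited ridge
pipelines — computed via SVD so the normal-equations residual can be
asserted below 1e-8. Cross-platform harmonization between cell lines and
patients defaults to independent per-gene z-scoring within each matrix,
a deliberate simplification of batch-correction pipelines; a
training-moments mode is available and is also what makes "patient equal
to training line reproduces its fitted value" testable. Candidates are
drugs with lower predicted log-IC50 in the high stratum (Δ median < 0)
at Wilcoxon p < 0.05; integration requires candidacy in all datasets
(`intersection`, the conservative default, with `any_dataset`
available because the published integration rule is under-specified) and
then at both the patient and the cell-line evidence level.

# Synthetic data: what it emulates and what it does not

The generators define the study conditions for every test:

- **Single-cell counts** are negative binomial (dispersion 0.4) around
  `lambda_g · mult_{g,pop} · libsize_cell`, with `lambda_g` log-normal
  (meanlog `log 2`, sdlog 1), library sizes log-normal (sdlog 0.3),
  planted markers multiplied by `2^log2FC`, and CNV blocks as
  multiplicative mean shifts in the malignant population. This captures
  overdispersion and library-size variation; it does not model dropout
  beyond NB zeros, ambient RNA, doublets, or batch structure, so passing
  tests demonstrate statistical correctness of the machinery, not
  robustness to real-data artifacts.
- **Composition** follows a logistic-normal: per-sample latent Gaussian
  (sd 0.8) softmaxed onto the simplex. The closure operation attenuates
  pairwise latent correlations, so the latent correlation is analytically
  pre-compensated (see `coenrich_sigma`) to land the *fraction*
  correlation near its target; Monte-Carlo calibration puts a 0.8 target
  in [0.6, 0.95] at 50 samples. Closure also forces real negative
  correlations with the remaining populations — and, with ≥ 4
  populations, positive co-movement within the complement — which is why
  recovery tests use the three-population design and why "favorable"
  calls for populations anti-correlated with a planted adverse one are
  correct discoveries, not false positives.
- **Bulk cohorts** mix population profiles by purity,
  `log2(1 + purity·Σ_p a_p·profile_p + (1−purity)·normal) + N(0, 0.2)`,
  with purity Normal(0.7, 0.1) clipped to (0.05, 1]. Survival is
  exponential with log-hazard linear in abundance; censoring is a
  Bernoulli(`censoring_rate`) draw with censoring times uniform on
  (0, T), giving the requested censoring fraction exactly and keeping
  censoring independent given T. No effect sizes are published for these
  links, so the defaults (hazard coefficient 1.5 per unit abundance in
  the recovery tests, baseline hazard 0.02) are calibration choices made
  once: they produce split hazard ratios around 1.5–2.7 at n = 300,
  i.e. realistic single-signature prognostic effects.
- **Pharmacogenomics**: three datasets share the gene space (gene 1 is
  the UPP1 proxy) with dataset-specific response offsets; log-IC50 is a
  5-gene sparse linear function plus the planted UPP1 coefficient (−1 in
  tests) and N(0, 0.5) noise.
- **Spatial**: uniform points per ROI; attracted phenotypes are Gaussian
  displacements (length scale 10 μm in tests) from random parents of
  their target, reflected at ROI borders.

# Problem sizes, determinism and degenerate inputs

Tests and the acceptance script use desk-scale sizes chosen as the
smallest that leave comfortable statistical margins: 800-gene /
240-cell CNV runs, 3 cohorts × 300 patients × 20 seeds for the
prognostic scan, 50 samples × 20 seeds for co-enrichment, 100 cell lines
× 20 drugs × 3 datasets for the screen. Every generator is
seed-deterministic (asserted byte-identical); scorers that randomize
tie-breaks or control draws take explicit seeds and echo them in their
parameter records.

Degenerate inputs are rejected loudly rather than coerced: zero-count
cells in normalization, constant purity in residualization, event-free
groups in survival tests, all-identical scores in the median split
(everything labeled low, with a warning), zero-margin 2×2 tables
(p = 1, odds ratio missing), constant genes in correlation tables
(missing r). Ties resolve deterministically where feasible (cutpoint
ties toward the smaller value; duplicate gene symbols keep the
highest-signal row with a warning).

# Known limitations

Clustering, embedding, batch integration and cell-type annotation are
inputs, not outputs. The CNV caller has no HMM or subclone model. The
LR test ignores multi-subunit complexes. The purity transform's cosine
constants are taken from the original deconvolution method rather than
refit. The drug-screen harmonization is a z-score simplification of
proper cross-platform correction. All "recovery" guarantees are
statements about the generator's model class, not about any real cohort.
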