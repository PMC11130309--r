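---
title: "Screening for condition-discordant ligand-receptor programs in replicated single-cell experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for condition-discordant ligand-receptor programs in replicated single-cell experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Tumor-associated macrophages (TAMs) are plastic: the same tumor can host
pro-inflammatory states (here `TAM_C1`, marked by Il1b/Rgs1 and high MHC-II)
and anti-inflammatory, pro-tumor states (`TAM_C3`, marked by Mrc1/Pf4 and
CD206). When a therapy works in one tumor model and fails in another, one
mechanistic hypothesis is that malignant cells in the resistant setting
recruit or sustain the pro-tumor TAM state through a specific
ligand-receptor (LR) axis. `tamscreen` implements a complete, testable
pipeline for finding such an axis in a replicated two-model, two-treatment
single-cell design, together with the downstream patient-level statistics
(signature scores, the C5aR1^hi^/CD86^hi^ myeloid ratio, ROC and survival
analysis) used to ask whether the axis matters clinically.

## The core statistic: replicate-pairwise interaction counting

LR calls from single samples are noisy and replicate counts are small
(a typical design here: 2 vehicle vs 4 treated tumors per model), so the
package compares conditions by exhaustive replicate pairing rather than by
averaging. For conditions A (a replicates) and B (b replicates), every
ordered pair of samples is compared, giving `a x b` comparison pairs; for
each interaction unit (an LR pair between a sender and receiver type)

\[
N \;=\; \sum_{i=1}^{k} n^{up}_{l} - n^{dn}_{l},
\]

where `n_up` counts the comparison pairs in which the unit was called in
the A sample but not the B sample, `n_dn` the converse, and the sum runs
over the `k` interaction units being aggregated (e.g. the ligands of one
receptor). `N` is integer-valued, bounded by `a x b` per unit, and
antisymmetric under swapping A and B; the implementation is exact integer
arithmetic and is tested against exhaustive enumeration.

The *discordance screen* then selects units with `N >= +m` in the
resistant-model contrast (treated vs vehicle) and `N <= -m` in the
sensitive-model contrast: interactions gained under treatment exactly where
treatment fails and lost where it works. "Increased in a pair" defaults to
presence/absence of a significant call (`mode = "presence"`); a
strength-fold alternative (`mode = "strength"`, default fold 1.5) is
provided because the categorical and quantitative readings are both
defensible and the choice is recorded in the result metadata.

## The interaction caller

The per-sample caller is deliberately simple and fully specified, in the
spirit of permutation-based communication tools:

* **Expression gate** — a gene participates only if detected in strictly
  more than 10% of the cells of its compartment, and a type participates
  only with at least 10 cells (both configurable).
* **Strength** — the product of trimmed-mean ligand expression in the
  sender and trimmed-mean receptor expression in the receiver, on
  log-normalized data. The trimmed mean averages the central 80% of cells
  (`trim = 0.10` per tail, `ceiling(trim * n)` cells removed per side, with
  a small epsilon guarding `ceiling` against floating-point noise).
* **Null** — sender/receiver labels are shuffled jointly over the union of
  the two compartments; `p = (1 + #{permuted >= observed}) / (1 + n_perm)`,
  so p can never be exactly 0 and the test is valid (super-uniform) under
  exchangeability, which the test suite verifies by simulation. An observed
  strength of 0 short-circuits to p = 1.

Mass-action kinetics, cofactors and pathway aggregation used by richer
communication frameworks are intentionally out of scope; every downstream
statistic in this package is defined on the strength above.

## What the synthetic generator emulates

`generate_experiment()` draws negative-binomial counts (shared dispersion 2,
log-normal library sizes with mean 3000) over a ~240-gene universe:
~200 unstructured background genes, mitochondrial genes at ~4% of UMIs,
and the marker genes of 16 populations (malignant, 4 TAM states,
2 monocyte states, 7 lymphoid/dendritic populations, fibroblasts,
endothelium) at an 8-fold multiplier in their own population. The default
design is the study design the analysis assumes: sensitive and resistant
models, vehicle (n = 2) and treated (n = 4) arms, 1000 cells per sample,
6% planted doublets (sums of two independently drawn cells).

The planted communication program multiplies the ligand (Rps19) in
malignant cells and the receptor (C5ar1) in a 50% subset of TAM_C3 cells,
with arm-dependent strengths `{sensitive-vehicle 6, sensitive-treated 0.01,
resistant-vehicle 0.01, resistant-treated 6}` — i.e. the axis collapses
under treatment in the sensitive model and emerges under treatment in the
resistant model, the discordant pattern the screen is built to find. The
receptor baseline weight is pinned near zero so that (i) the expression
gate removes the unit in program-off arms and (ii) receptor *detection*
cleanly marks the planted C5aR1-high half of TAM_C3, mimicking the
C5aR1^hi^/C5aR1^lo^ substructure of the anti-inflammatory TAM state.
Constitutive axes (Csf1-Csf1r, Cx3cl1-Cx3cr1) are planted uniformly across
arms as negative controls: they are called in every sample and therefore
cancel in `N`.

What the generator does **not** emulate: ambient RNA, batch effects,
spliced/unspliced layers, realistic gene-gene correlation beyond the
type-level mean structure, and continuous state gradients. Passing tests on
this generator therefore demonstrate correctness of the statistics and
rules, not robustness to the full messiness of real tissue data.

## QC, demultiplexing and annotation choices

* **Cell filter** — keep cells with >= 1000 detected genes and <= 20%
  mitochondrial UMIs (both boundaries kept; the exclusions are
  strict inequalities). Stated gene-count and UMI-count floors are often
  conflated in practice;
  detected genes is the primary rule and an optional UMI floor is exposed
  separately. On the synthetic universe (~240 genes) the pipeline passes
  `min_genes_detected = 100`, scaled to the universe size.
* **Doublets** — a simplified simulated-doublet score: artificial doublets
  (pool ratio 0.5) are embedded with the cells in PCA space; each cell's
  score is a posterior built from the fraction of artificial doublets among
  its ~sqrt(n) nearest neighbors, with the expected doublet rate (6%) as
  prior; cells above the 95th score percentile are flagged. We found a
  pool sized at the expected rate alone too sparse for a stable
  nearest-neighbor score, so pool size and prior are separate knobs. This
  is a stand-in for full doublet callers and is validated only on planted
  doublets.
* **Hashtag demultiplexing** — Louvain communities (resolution 1.2) on a
  kNN graph of log-normalized tag counts; a community is assigned to a tag
  only when that tag is the argmax for >= 90% of its cells ("exclusively
  unique"), otherwise its cells stay unassigned.
* **Annotation** — expression clustering is an *input* (any partition of
  cells); the package contributes the rule cascade, not a clustering
  algorithm. On synthetic data the generator's anonymized partition is
  used, so annotation tests measure the marker rules alone. Rules fire at
  cluster level: a marker is "expressed" when the cluster-mean expression,
  z-scored across clusters, exceeds 0.25. We use 0.25 rather than 0.5
  because near-ubiquitous markers (Cd45/Ptprc is high in ~11 of 16
  populations) top out near z ~ 0.5 by construction of a cross-cluster
  z-score, while true non-expressers sit well below 0; 0.25 splits the two
  groups with a wide margin. First matching rule wins, in the listing order
  of the rule table; malignant cells come from a caller-provided mask
  (truth labels on synthetic data), standing in for CNV-based calling,
  which is out of scope.

## Signature scoring and pseudobulk statistics

`ucell_score()` is a rank-based per-cell score: genes ranked per cell
(mid-ranks for ties, ranks capped at `r_max = 1500` after tie resolution),
`U = sum(R_i) - n(n+1)/2`, `score = max(0, 1 - U / (n r_max))`. It is
invariant under monotone transforms of a cell's expression and is tested
exactly against an explicit rank-table implementation, including the
closed-form floor `(n+1) / (2 r_max)`. Per-sample, per-subcluster Z-ranks
standardize subcluster *mean* scores across the subclusters of each sample
(the cell-level alternative is not used; means match the cross-subcluster
reading of the procedure). `pathway_score()` follows the binned-control
convention: control genes drawn from the same mean-expression bin, so a
random gene set scores 0 in expectation. Pseudobulk Pearson correlations
are significant when `r > 0.3` and `p < 0.05`, both strict; the signed
threshold is the default reading, an absolute-value mode is one flag away.
DEG ranking for "top 3 DEGs per cluster" uses the Wilcoxon rank-sum z
statistic, ties broken by symbol.

## Cohort outcome statistics

Myeloid cells are classified with precedence C5aR1^hi^ (receptor detected)
> CD86^hi^ (CD86 in the top 25% of expressing cells and no
C5AR1/CD163/MRC1) > other. The patient covariate is the pseudocounted
ratio `(C5aR1hi + 1) / (CD86hi + 1)` (pseudocount 1 guards empty
denominators and is logged); patients at or above the linear-interpolation
75th percentile form the high-ratio group (ties high). ROC AUC is the
Mann-Whitney statistic with half-weight ties and a tie-corrected normal
p-value; Kaplan-Meier/log-rank and univariate Cox (Breslow ties,
Newton-Raphson partial likelihood, Wald intervals) are delegated to the
survival package behind the module interface and are cross-checked in the
test suite against a hand-computed log-rank oracle and
parameter-recovery/coverage simulations. The synthetic cohort draws class
counts from negative binomials, survival from an exponential hazard
`h0 exp(beta z)` in the standardized ratio, independent exponential
censoring, and response from a logistic model in the same covariate.

## Numerical and degenerate-input policy

* Trimmed means fall back to the plain mean when trimming would remove
  everything; `ceiling` is guarded with a 1e-9 epsilon identically in the
  R and C++ paths.
* HVG ranking breaks ties lexicographically by symbol; constant genes are
  never selected.
* Zero-denominator composition ratios are reported as `Inf` with a flag;
  an all-equal ratio cohort degenerates to everyone "high", flagged.
* All stochastic steps (generator, doublet pool, permutations, control-gene
  sampling, community detection) take explicit seeds and restore the
  caller's RNG state.

## Problem sizes used by the automated checks

The test-suite and acceptance-script simulations use sizes chosen to make
each property measurable with comfortable margins: end-to-end recovery runs
use the full default design (12 samples x 1000 cells) with 200
permutations per compartment pair; null-screen replicates use 400 cells
per sample; permutation calibration uses 200 null units at 199
permutations; Cox recovery uses 100 cohorts of 500 patients and coverage
500 cohorts of 60. These are the package's own choices of simulation size
and are stated here so results can be reproduced exactly.

## Known limitations

* The interaction strength is this package's own documented statistic; it
  is not numerically comparable to mass-action communication scores, and
  `N` inherits that definition.
* No significance is attached to `N` itself; the screen is a ranking and
  thresholding device, which mirrors how such counts are used in practice.
* Marker rules assume the rule table's genes are measured; missing markers
  make a rule inert with a warning rather than an error.
* The annotation path evaluated here uses the generator's partition as the
  cluster input; with a real clustering the rule cascade is only as good as
  the clustering's purity.
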