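---
title: "Phenotyping coding variants from Perturb-seq screens: methods and design notes"
author: "perturbpheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping coding variants from Perturb-seq screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the models and
rules implemented, the defaults and why they were chosen, the numerical
decisions at the edges, and what the synthetic data do and do not tell you
about real screens. Nothing here states an empirical result beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## The screen and its analysis model

A variant-barcoded overexpression screen couples each cell to one construct
— a coding variant of the studied transcription factor, the wild-type (WT)
protein, or a loss-of-function (LoF) construct in which the protein is
replaced by a fluorophore — and reads out the cell's transcriptome. The
analysis treats the WT and LoF cells as two reference distributions in a
low-dimensional expression space and asks, per variant, whether its cells
are distinguishable from each reference.

### Single-cell processing

The chain mirrors standard scRNA-seq practice, with every threshold exposed
in `pipeline_config()`:

* **QC** (`qc_filter`): keep cells with exactly one detected construct
  barcode, between `min_genes` = 200 and `max_genes` = 5000 detected genes,
  and at most `max_mito` = 20% mitochondrial reads; drop genes seen in
  fewer than 3 cells; drop variants that never reach
  `min_cells_per_variant` = 10 cells in any condition. Because the gene and
  cell rules feed back on each other, the filter iterates to a fixed point,
  which also makes it idempotent — a property the test suite checks.
* **Normalisation** (`lognormalize`): `ln(1 + c · SF / total)` with
  `SF = 10^4`; invariant to per-cell depth.
* **Highly variable genes** (`select_hvg`): only the count of variable
  genes (2000) is fixed by convention; the ranking statistic is an open
  choice. We rank by a *binned dispersion*: genes are cut
  into 20 equal-frequency bins of mean log-expression and the log variance
  is z-scored within each bin. This removes the mean–variance trend without
  any curve-fitting machinery and is reproducible to the last tie (ties
  break by gene identifier, so the choice is invariant to input order).
  Mitochondrial and ribosomal genes are excluded before ranking.
* **Cell-cycle regression** (`score_and_regress_cell_cycle`): per-cell S
  and G2M scores are marker means minus the mean of a size-matched random
  control gene set (seeded); each gene is residualised by OLS on the two
  scores and z-scored, clipping at ±10. The clip bound is our choice — the
  source analyses do not state one — and exists to keep single outlier
  cells from dominating the PCA.
* **PCA** (`run_pca`): truncated SVD of the scaled HVG matrix, top
  `n_pcs` = 20 components, with a deterministic sign convention (the
  largest-magnitude loading of each component is positive) so repeated runs
  and reordered inputs agree exactly.
* **Graph clustering** (`cluster_graph`): exact k-nearest-neighbour graph
  (`n_neighbors` = 20, a conventional value; the source does not state one)
  and Leiden modularity optimisation at resolution 0.3 for cells and 0.8
  for variant profiles.

### Hotelling T² scores and phenotype calls

For a variant with cells `X₁` (n₁ × p) against control cells `X₂` (n₂ × p)
in the p = 20 PC embedding:

$$T^2 = \frac{n_1 n_2}{n_1+n_2}\, \bar d' S_p^{-1} \bar d, \qquad
F = T^2\,\frac{n_1+n_2-p-1}{p\,(n_1+n_2-2)} \sim F_{p,\; n_1+n_2-p-1},$$

with `S_p` the pooled covariance (denominator n₁+n₂−2). The statistic is
affine-invariant and reduces to the squared pooled t in one dimension; both
properties are tested, and the null F calibration is verified by a
Kolmogorov–Smirnov uniformity check on 2000 simulated null p-values.

Calls use raw p-values at α = 0.05 (the conventional per-variant
significance rule for this design; BH-adjusted values are also
reported): significant only against
LoF → *WT-like*; only against WT → *LoF-like*; against both →
*hypomorphic*. We add an explicit *indeterminate* category for variants
significant against neither — the three published labels come from variant
clustering with the T² rule as corroboration, and the rule alone is not
exhaustive. A nearly singular pooled covariance (possible when a variant
has barely more cells than dimensions) is ridged by `1e-6 · tr(S)/p` on the
diagonal with a warning rather than failing.

### Variant-level clustering

Variant mean profiles (per-gene mean log-expression over the variant's
cells, HVG only) are clustered with distance `1 − Pearson r` and average
linkage (the linkage is not stated in the source; complete and Ward are
accepted alternatives via the `linkage` argument). Dendrogram leaves are
reordered towards increasing T²-vs-WT using `stats::reorder()` on the
dendrogram with the T² scores as weights: this performs exactly the flips
the tree allows, ordering branches by mean weight. It is not guaranteed to
maximise a rank-agreement objective, but on trees whose structure follows
the scores (the practical case) it yields the sorted order, which is what
the tests assert. Gene clustering uses Manhattan distance over the profile
columns. Cluster–class enrichments report the *sample* log odds ratio
(Haldane–Anscombe 0.5 correction on zero cells, flagged) with the exact
two-sided p of the package's own test — see below.

### Exact 2×2 inference

`fisher_cmle()` is the package's central estimator. Conditional on both
margins of a 2×2 table, the count `A` in the top-left cell follows a Fisher
noncentral hypergeometric distribution with parameter ψ (the odds ratio).
The conditional MLE solves `E[A | margins, ψ] = a`; since the expectation
is strictly increasing in log ψ, we bisect on log ψ ∈ [−36, 36] (then
Newton-polish) until the expectation matches the observed count to 1e-9.
Hypergeometric weights are evaluated in log space via `lchoose`, so tables
with totals in the hundreds cannot overflow. Boundary counts give ψ ∈
{0, ∞}; a zero margin gives an undefined, flagged estimate with p = 1. The
two-sided p-value sums the null probabilities of all tables at most as
probable as the observed one, with a `1 + 1e-7` relative tie tolerance.

This estimator — not the sample cross-product ratio — is what standard
exact-test software prints: on the DNA-contact table (7, 1; 31, 40) the
sample odds ratio is 9.03 while the conditional MLE is 8.82, and matching
the latter is what validates the implementation. The test suite audits the
estimator against direct likelihood maximisation on 200 random tables and
against `stats::fisher.test`. One symmetry worth recording: *transposing* a
2×2 table leaves ψ̂ unchanged (the cross-product is symmetric in the
off-diagonal cells); it is the row swap or column swap that inverts it.

### Fitness

Per sample (replicate × day), barcode counts are normalised to relative
abundances, divided by the same replicate's day-2 abundance, and log₂
transformed; day-2 fitness is identically zero and the score is invariant
to sequencing depth. The per-variant summary averages the day-14
replicates. No pseudocount is added by default (matching the plain ratio
definition); variants with a zero day-2 count are flagged and excluded from
summaries rather than imputed.

### Structure module

Interface residues follow a single geometric criterion: a protein residue
is a DNA contact when any of its non-hydrogen atoms lies strictly within
3.5 Å (Euclidean) of a non-hydrogen atom of a DNA chain; the comparison is
a strict inequality, not ≤. Only polymer atoms participate
— waters, ions and other heteroatoms are excluded. Protein–protein
interfaces reuse the same rule with a configurable cutoff, since the source
delegates that case to prior work without restating a threshold; one
consistent criterion seemed preferable to a second convention. Altloc
groups collapse to the highest-occupancy conformer; residue identity
includes the insertion code; author-numbering offsets are always supplied
by the caller, never inferred.

Burial classes come from a from-scratch Shrake–Rupley implementation:
100 quasi-uniform sphere points per atom (golden-spiral lattice, so the
point set is deterministic), probe 1.4 Å, van der Waals radii from the
standard element table, relative accessibility against the theoretical
Gly-X-Gly maxima of Tien et al. (2013). Thresholds default to rSASA ≤ 0.05
for core and ≥ 0.25 for surface — conventional bands, exposed as arguments
because the source does not state its own. The fixed point lattice makes
SASA only approximately rotation-invariant; the tests bound the deviation
at 0.05 rSASA and require exact invariance of contact calls.

### Library design

All nine single-nucleotide variants of every codon are translated under the
standard genetic code; silent and nonsense products are reported separately
(they seed control categories). The per-residue selection rule is: restrict
to tumour-observed candidates when any exist (reading "prioritizing cancer
mutations where possible" as a hard filter), then maximise the VEST
pathogenicity score, break ties by larger FoldX destabilisation, then by
alphabetical alternate amino acid. A highest-VEST-or-FoldX rule is
ambiguous on its own; VEST-primary with FoldX as tie-breaker keeps the
pathogenicity score in charge and makes the choice a deterministic,
permutation-invariant function of the candidate set. Barcodes are random
12-mers kept at pairwise Hamming distance ≥ 3 (the source states only
uniqueness; a distance floor adds error tolerance at negligible cost).

### Classifier stage

The variant-effect classifier is deliberately thin: a stratified 60–40
split (per class, `round(frac · n)` into training — note that the
published 49/30 split of 79 variants is not reproducible from any standard
rounding of 0.6 × (38, 41), which we record as an open question and do not
emulate), a random forest with 1000 trees and √p features per split
(library-backed; an off-the-shelf learner is not this package's
contribution), scores defined as the fraction of trees voting functional,
a strict 0.5 threshold, and evaluation through the package's single
AUROC/AUPR implementation (tie-corrected rank formula; step-interpolated
precision).

## The synthetic screen

`simulate_screen()` generates the package's test bed and defines the
conditions under which its guarantees are demonstrated:

* negative binomial counts (size 2) with log-normal per-gene means
  (median scaled so the mean count is 2; log-sd 1.2) and a log-normal
  per-cell depth factor (log-sd 0.3) — typical magnitudes for UMI data;
* three planted classes over disjoint 50-gene modules: LoF-like variants
  and the LoF control share a 1.0 log-unit shift on the LoF module;
  hypomorphic variants get half that shift plus a 1.0 log-unit shift on an
  orthogonal module (the half/orthogonal construction makes them genuinely
  different from both references, not merely intermediate); WT-like
  variants and the WT control are unshifted. Effect sizes separating real
  hypomorphic alleles from LoF are not published quantities; these defaults
  are free parameters of the simulator, not estimates of real data;
* a standard-normal latent cell-cycle factor scaling a 50-gene set with
  amplitude 0.5, so the regression step has real work to do;
* barcode noise: 5% of cells with no detected barcode, 5% with two;
* two replicates and a dox/nodox condition flag with condition-independent
  effects by default (an optional multiplicative shrinkage attenuates all
  effects in the nodox condition, emulating residual endogenous activity);
* a growth-rate-driven barcode timecourse: equal day-2 shares, expected
  abundance ∝ exp(g·(t−2)) with per-day class rates 0 / 0.05 / 0.10
  (WT-like / hypomorphic / LoF-like, jitter 0.02 across variants — the
  direction follows the published observation that losing the factor's
  activity accelerates proliferation in this cell context), multinomial
  sampling at 2.5 × 10⁵ reads per sample (the published depth scaled down
  tenfold). With one variant at advantage g, its expected day-14 fitness
  sits exactly g·12/ln 2 log₂ units above the neutral pool — the identity
  the timecourse tests exploit.

What the simulator does *not* emulate: ambient RNA, doublet transcriptome
mixtures, batch effects between libraries, UMI saturation, overdispersion
heterogeneity across genes, or any read-level artefact. Passing the
recovery tests therefore demonstrates the statistical machinery under the
stated generative model — it does not certify performance on real data,
where QC and batch structure carry most of the difficulty.

## Problem sizes and determinism

The default acceptance-scale simulation is 2000 genes × (60 perturbation
variants + 2 controls) × 150 cells ≈ 9300 cells, chosen as the smallest
screen at which per-variant T² tests on 20 PCs are comfortably
well-conditioned (150 cells ≫ 20 dimensions) while the whole chain runs in
well under a minute. Unit tests use smaller screens (300–800 genes, tens of
cells per variant) with thresholds scaled accordingly. Every stochastic
step takes an explicit seed and is bit-reproducible; the null-calibration
and recovery checks hold with margin across seeds rather than at one lucky
value.

## Known limitations

* T² p-values assume approximate Gaussianity of cells in PC space; with
  very few cells per variant the F calibration degrades before the ridge
  fallback engages. Results with `n₁ + n₂ ≤ p + 1` are flagged invalid
  rather than extrapolated.
* The phenotype rule at raw α = 0.05 mislabels ~5% of genuinely WT-like
  variants as significant against WT by construction; the
  BH-adjusted columns are provided for users who prefer FDR control at the
  cost of sensitivity.
* The HVG statistic is one defensible choice among several (Seurat offers
  three flavours); rankings near the 2000-gene boundary are not comparable
  across flavours.
* Leaf ordering optimises branch-mean weights, not a global rank
  objective; for pathological trees the two differ.
* `classify_burial` evaluates occlusion within the selected chain only —
  burial of the isolated protomer, not of the complex; pass a merged chain
  if complex burial is wanted.
* The exact test's two-sided p uses the probability-ordering convention;
  other conventions (doubling the one-sided p) give different values on
  asymmetric tables.
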