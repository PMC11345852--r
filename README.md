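# perturbpheno

Coding-variant phenotyping for variant-barcoded overexpression screens with
single-cell transcriptome readout (Perturb-seq / SEUSS style).

## The problem

In screens of this kind, each cell overexpresses one barcoded coding variant
of a transcription factor (for example, RUNX1 variants in leukemia cells with
the endogenous gene repressed), alongside a wild-type (WT) construct and a
loss-of-function (LoF) construct (the protein replaced by GFP). The question
is which variants behave like WT, which like a functional null, and which are
*hypomorphic* — significantly different from both references. `perturbpheno`
implements the full analysis chain for such screens, plus the structural and
library-design steps that surround them, for computational biologists who
want each stage available as a tested, seeded R function.

## What is computed

**Variant scores.** Cells are QC-filtered (unique barcode; 200–5000 detected
genes; ≤ 20% mitochondrial reads; ≥ 10 cells per variant and condition),
log-normalised (`ln(1 + c·10⁴/total)`), reduced to 2000 highly variable
genes, residualised against cell-cycle scores, and embedded in the top 20
principal components. Each variant's cells are then compared to the WT and
LoF control cells with Hotelling's two-sample T² statistic,

T² = (n₁n₂/(n₁+n₂)) · d′ S⁻¹ d,  F = T² (n₁+n₂−p−1)/(p(n₁+n₂−2)) ~ F(p, n₁+n₂−p−1),

where d is the mean difference in the embedding and S the pooled covariance.
The phenotype call at level α = 0.05 is: significant only vs LoF → **WT-like**;
significant only vs WT → **LoF-like**; significant vs both → **hypomorphic**;
vs neither → indeterminate.

**Exact enrichment.** Associations between phenotype classes and structural
or clinical categories are 2×2 tables; `fisher_cmle()` reports the
*conditional maximum-likelihood* odds ratio — the ψ maximising the Fisher
noncentral hypergeometric likelihood given the margins, found by solving
E[A | margins, ψ] = a — with the exact two-sided p-value. This is the
estimator printed by standard exact-test software and is noticeably smaller
than the sample cross-product ratio on extreme tables.

**Everything around them.** A seeded negative-binomial screen simulator with
planted WT-like / LoF-like / hypomorphic classes and a truth record; barcode
fitness across timepoints (log₂ abundance ratio to the day-2 baseline);
protein–DNA interface residues from PDB structures (non-hydrogen atom pairs
strictly under 3.5 Å) with Shrake–Rupley burial classes; single-base
substitution missense enumeration and the most-damaging-substitution library
selection rule; a stratified-split random-forest classifier stage with
rank-based AUROC/AUPR.

## Worked example

Simulate a small screen (18 variants + WT + LoF controls, 120 cells each),
phenotype every variant, and test a structural enrichment:

```r
library(perturbpheno)

cfg <- sim_config(n_genes = 800, n_cells_per_variant = 120,
                  n_variants_per_class = c(wt_like = 6, lof_like = 6,
                                           hypomorphic = 6), seed = 7)
sim <- simulate_screen(cfg)
ph  <- phenotype_screen(sim$screen, pipeline_config(seed = 7),
                        sim$truth$modules$s_genes,
                        sim$truth$modules$g2m_genes)
summary(ph)
#> Phenotype calls (T2 vs WT and LoF controls):
#>
#> hypomorphic    LoF-like     WT-like
#>           7           5           6
#>
#> T2 vs WT, five-number summary:
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   18.38   29.63 1829.17 1263.23 1914.42 2014.75
#>
#> Strongest deviations from WT:
#>    variant    t2_wt         p_wt        call
#> 13    V013 2014.750 3.148669e-86 hypomorphic
#> 16    V016 2013.230 3.357827e-86 hypomorphic
#> 14    V014 2011.876 4.641724e-88 hypomorphic
#> 11    V011 1942.481 2.025530e-86    LoF-like
#> 10    V010 1926.011 3.512485e-85    LoF-like
#> 8     V008 1879.642 3.515193e-85    LoF-like
```

17 of the 18 planted phenotypes are recovered here (one LoF-like variant is
called hypomorphic); shifted variants sit orders of magnitude above the
WT-like group in T². Enrichment of functional phenotypes among DNA-contact
variants, from the published 8-vs-71 split of calls:

```r
fisher_cmle(matrix(c(7, 1, 31, 40), 2, byrow = TRUE))
#> 2x2 exact inference (conditional-MLE odds ratio)
#>           positive negative
#> exposed          7        1
#> unexposed       31       40
#> psi_hat = 8.821, two-sided p = 0.02537
```

(The sample odds ratio of this table is 9.03; the conditional MLE of 8.82 is
what exact-test software reports.) Barcode fitness recovers the planted
growth rates:

```r
ft <- fitness_scores(simulate_barcode_timecourse(cfg, sim$truth))
cor(ft$mean_fitness, sim$truth$growth_rate[names(ft$mean_fitness)],
    method = "spearman")
#> [1] 0.998
```

## Documentation

The methods vignette (`vignettes/variant-phenotyping.Rmd`) describes the
statistical model, the defaults of the synthetic screen and what they do and
do not emulate, numerical choices, and known limitations.
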