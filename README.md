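# bsmix

Tissue deconvolution and 3′ coverage-bias diagnostics for bundle-sheath /
mesophyll RNA-seq and enzyme/metabolite data from C4 leaves.

## What problem this solves

C4 photosynthesis splits labor between mesophyll (M) cells, which fix
carbon via PEPC, and bundle-sheath (BS) cells, which reduce it via
Rubisco. Measuring what each tissue expresses requires physically
separating them, and every separation method is imperfect in one of two
ways:

* **Impurity.** Serial filtration over liquid nitrogen yields enrichment
  fractions (BS-e, I-e, M-e) that are *mixtures* of the tissues, so
  observed differences are attenuated versions of the true ones.
* **Degradation.** Harsher methods (mechanical separation, laser
  micro-dissection) degrade RNA, producing 3′-biased coverage. Degradation
  sensitivity is gene-specific, and when the M preparation degrades more
  than the BS preparation (or vice versa), sensitive transcripts
  masquerade as tissue-specific ones.

`bsmix` is aimed at researchers comparing BS/M separation experiments (or
any two-tissue enrichment design). It provides:

* **Deconvolution** of analyte tissue specificity from marker enzymes: the
  slope of ln(target/M-marker) on ln(BS-marker/M-marker) across enrichment
  fractions estimates the fraction of the target in pure BS, tested
  against the 50/50 null, with pure-tissue abundances reconstructed as
  2 × slice mean × fraction (`deconvolveActivity()`).
* **3′ bias metrics** per transcript and sample (mean coverage over the
  3′-most 100 nt over the transcript mean), gene-set bias profiles against
  the genomic background, and conflict-set construction between studies
  (`geneThreePrimeBias()`, `setBiasProfile()`, `buildConflictSets()`).
* **Differential expression** with an exact conditional negative-binomial
  test (pluggable common dispersion, `nbTest()`) and a purity-adjusted
  linear-unmixing estimator that undoes contamination attenuation
  (`purityAdjustedDE()`): at purities π and 1−π a true ratio F is observed
  as (πF+1−π)/((1−π)F+π), and the unmixing recovers F.
* **Cross-study harmonization**: quantile normalization of log2 fold
  changes, back-calculation of tissue-level TPM from (log2FC, mean TPM),
  ortholog direction agreement, developmental-switch support, hierarchical
  clustering with Pearson/Spearman correlation distances, and Fisher-exact
  category enrichment with BH FDR.
* **A synthetic-data module** (`simulateCounts()`, `simulateCoverage()`,
  `simulateActivityTable()`, `studyTemplate()`) generating two-tissue
  mixtures with gene-specific degradation sensitivity and known ground
  truth, used by the test suite for parameter-recovery validation.

## Worked example

Deconvolve three simulated analytes (true BS fractions 0.2, 0.8, 0.15)
from a 3-fraction × 4-replicate enrichment design with 10% lognormal
noise:

```r
library(bsmix)
act <- simulateActivityTable(
  data.frame(analyte_id = c("malate", "serine", "AspAT"),
             alpha = c(0.2, 0.8, 0.15), scale = c(2, 1, 1)),
  config = simConfig(noise_sigma = 0.1, seed = 42))
deconvolveActivity(act)
#> DeconvResults: 3 analyte/slice estimates (markers M=PEPC, BS=NADPME)
#>    analyte_id     slice   slope_b        se    t_stat     p_value  n_points
#> 1      malate         2  0.195548 0.0402894  -7.55662 1.93327e-05        12
#> 2      serine         2  0.776580 0.0573919   4.81915 7.03122e-04        12
#> 3       AspAT         2  0.207261 0.0480198  -6.09623 1.16271e-04        12
```

The slopes recover the simulated fractions (0.20, 0.78, 0.21 vs truth
0.2, 0.8, 0.15); the t statistics and p-values test each against an even
50/50 tissue split, and `bs_pure`/`m_pure` columns (not shown) give the
reconstructed pure-tissue abundances.

The full synthetic cross-study experiment chains simulation, both DE
engines, fold-change harmonization, conflict sets and bias profiling:

```r
demo <- runDemo(seed = 1)
sum(demo$res_mech$fdr < 0.05 & demo$res_mech$log2fc > 0)
#> [1] 205        # spurious "BS-enriched" calls in the degraded-M study
demo$recovery$sensitivity
#> [1] 1          # top-decile degradation-sensitive genes all recovered
round(demo$recovery$fdr, 3)
#> [1] 0.095
```

With no true BS/M differences simulated, the study whose M samples degrade
more still makes 205 "BS-enriched" calls — 99% of them in the top quartile
of degradation sensitivity — while the clean filtration study correctly
finds (almost) nothing. The vignette
(`vignettes/bsmix-methods.Rmd`) walks through the model, the estimators
and the conditions under which cross-study conflict sets populate.

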