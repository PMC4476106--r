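# miRTargetCor

Integrative miRNA–mRNA negative-correlation target analysis for hepatic
stellate cell (HSC) quiescence.

## The problem

Quiescent hepatic stellate cells (qHSCs) maintain the healthy liver;
their activation into myofibroblast-like cells (aHSCs) drives fibrosis.
miRNAs abundant in qHSCs whose predicted target genes are induced during
activation are candidate repressors of the activation program. Finding
them requires integrating three evidence layers: differential expression
of miRNAs (TaqMan-style Ct arrays) and mRNAs (log2 expression matrices
covering HSCs plus hepatocyte/LSEC reference cells), expression
anticorrelation across paired quiescent/activated donor samples, and
sequence-based target predictions.

`miRTargetCor` implements that pipeline for bioinformaticians working
with paired-design qPCR-array and expression data:

1. **Normalization & detection** — $-\Delta Ct = -(Ct_{assay} - Ct_{ref})$
   against an endogenous control (RNU6); assays kept when Ct ≤ 35 in at
   least half of one state group.
2. **Differential classification** — fold changes from group means,
   $FC = 2^{\bar{x}_A-\bar{x}_B}$, two-sided Student t-tests;
   quiescence-associated miRNAs at FC ≥ 1.5 (p ≤ 0.05),
   activation-associated at FC ≥ 2 (p ≤ 0.05); genes additionally require
   ≥ 2-fold enrichment over both hepatocytes and LSECs.
3. **Integration** — Pearson correlation of every deregulated miRNA ×
   deregulated mRNA pair over the shared HSC samples, Benjamini–Hochberg
   FDR across all pairs, and selection of pairs with FDR < 0.05, r < 0 and
   database prediction p < 0.05.
4. **Network summaries** — targets per miRNA, the panel of
   quiescence-associated miRNAs with more than 6 targets, per-class
   target statistics, coverage of activation-induced genes, and the
   most-targeted gene.

A first-class synthetic-data module (`simParams()`, `simulateStudy()`)
plants a known repression network in the paired-donor design so every
stage can be validated against ground truth, and a bundled fixture ships
a published-style 31-miRNA quiescence panel for the summary operations.

## Worked example

```r
library(miRTargetCor)

study <- simulateStudy(simParams(seed = 1))   # 4 paired donors + references
res <- runPipeline(study)

res$report$class_counts
#>    class_label  n pct
#> 1 q_associated 20  40
#> 2 a_associated 30  60

res$report$class_stats[, c("class_label", "mean_targets", "sd_targets")]
#>    class_label mean_targets sd_targets
#> 1 q_associated        15.65   5.173567
#> 2 a_associated         2.10   1.322224

str(res$evaluation)
#> List of 8
#>  $ tp           : int 320
#>  $ fp           : int 56
#>  $ fn           : int 38
#>  $ n_selected   : int 376
#>  $ n_true       : int 358
#>  $ precision    : num 0.851
#>  $ recall       : num 0.894
#>  $ empirical_fdr: num 0.149
```

Of the 50 detected miRNAs, the 20 quiescence-associated ones average
~15.7 selected targets each while the 30 activation-associated ones
average ~2.1 — the planted asymmetry in which a few qHSC miRNAs each
repress many activation-induced genes. Against the planted truth the
selected pairs reach 85% precision and 89% recall; the residual false
calls come from database false positives among anticorrelated non-target
pairs, which is the expected failure mode with 8 HSC samples.

Real data enter through `readExpressionMatrix()`, `readSampleSheet()`
and `readPredictionTable()` (all TSV), assembled with `CtExperiment()`
and `HscStudy()`; `parsePanelTable()` reads published panel tables with
decimal commas and middle-dot scientific notation.

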