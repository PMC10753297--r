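# glycodiff

Differential expression analysis for comparative glycomics, with
motif-level quantification.

## The problem

Glycomics experiments measure the relative abundances of intact glycans,
normalized to 100 per sample. The data are compositional, heteroscedastic,
full of non-detections stored as zeros, and the biology often acts on
substructures (sialyl-Tn, Lewis antigens, core fucose, "any α2-6-linked
sialic acid") rather than on whole structures. glycodiff is aimed at
glycoscientists who have such a table — glycans in IUPAC-condensed
notation in the rows, samples in the columns — and want statistically
defensible answers at the sequence, motif, and motif-set level.

## What it does

* **Glycan handling.** IUPAC-condensed strings (Greek or latin letters,
  journal or bracket branch style, inline substituents like `GlcNAc6S`)
  are canonicalized and parsed into rooted labeled trees. Motifs are
  counted by wildcard-aware subtree matching with positional constraints
  (terminal / internal / reducing-end / flexible) and exclusion contexts
  (core 1 is not double-counted inside core 2). A curated named-motif
  library ships with the package and can be replaced by a TSV.

* **Motif quantification.** Relative abundances are turned into
  proportional motif abundances by the weighted sum
  `A[m,s] = Σ_g count(g,m)·A[g,s]`, rescaled to 100 per sample, with
  redundant motifs collapsed (named > disaccharide > terminal >
  monosaccharide) and informative wildcard generalizations
  (`Neu5Ac(a2-?)`) added automatically.

* **Preprocessing.** Sparsity filtering (missing in more than half of any
  group's replicates), total normalization, MissForest-style iterative
  random-forest imputation (5 iterations, sample-median start, +1e-6
  shift, applied within each biological condition), variance filtering
  (default 0.01 on the percent scale), and variance-stabilizing
  normalization (log2 + standardization; pooled within-group scaling
  before tests).

* **Statistics.** Two-tailed Welch or paired t-tests with Cohen's
  *d*/*d_z* and their variances; Hotelling's T² with bootstrapped
  Mahalanobis effect sizes for correlation-network motif sets (edge iff
  0.9 ≤ r < 1); Levene's (Brown–Forsythe) test for variance differences;
  log2 fold changes of group means on the relative scale;
  Benjamini-Hochberg correction. Multi-group ANOVA with Tukey HSD
  (`getGlycanova`) and time-series regression with polynomial fits
  (`getTimeSeries`). Fixed-effects and DerSimonian–Laird random-effects
  meta-analysis across studies with forest-plot data
  (`getMetaAnalysis`).

* **Simulation.** A Dirichlet glycome simulator with known ground truth
  (`simulateGlycomes`), missingness injection, and recovery scoring used
  to validate the workflow (`runImputationBenchmark`,
  `runMotifCalibration`, `evaluateRecovery`).

## Worked example

```r
library(glycodiff)

canonicalizeIUPAC("Neu5Acα2-3Galβ1-3(Neu5Acα2-6)GalNAc")
#> [1] "Neu5Ac(a2-3)Gal(b1-3)[Neu5Ac(a2-6)]GalNAc"

countMotif("Neu5Ac(a2-3)Gal(b1-3)[Neu5Ac(a2-6)]GalNAc",
           "Neu5Ac(a2-?)", constraint = "terminal")
#> [1] 2

## simulate a two-group O-glycomics experiment with known ground truth
sim <- simulateGlycomes(nGlycans = 60, nReplicates = 8, nEffects = 5,
                        effectScale = 5, missingFraction = 0.2, seed = 7)
m <- cbind(abundances(sim$control), abundances(sim$test))

## motif-level differential expression (group2 = case)
res <- getDifferentialExpression(
  m, group1 = colnames(abundances(sim$control)),
  group2 = colnames(abundances(sim$test)),
  motifs = TRUE, featureSets = c("known", "terminal"), seed = 7)
head(res[, c("feature", "log2fc", "statistic", "p_adj", "effect_size")], 5)
#>           feature     log2fc statistic      p_adj effect_size
#> 1       Man(a1-?) -6.8501302  3.421444 0.05297991  -1.7107220
#> 2       Man(a1-3) -6.8501302  3.421444 0.05297991  -1.7107220
#> 3    Oligomannose -6.8501302  3.421444 0.05297991  -1.7107220
#> 4     GalOS(b1-3)  0.4770200 -2.236914 0.45311426   1.1184570
#> 5 BisectingGlcNAc  0.2558741 -1.323999 0.89108622   0.6619995

## score sequence-level recovery of the injected effects
seq_res <- getDifferentialExpression(
  m, colnames(abundances(sim$control)), colnames(abundances(sim$test)),
  seed = 7)
unlist(evaluateRecovery(seq_res, sim$truth)[c("sensitivity", "fpr")])
#> sensitivity         fpr
#>         0.1         0.0

## combine effect sizes across studies
fixedEffectsMeta(d = c(0.5, 1.0), varD = c(0.1, 0.1))[
  c("d_combined", "se_combined", "p")]
#> $d_combined
#> [1] 0.75
#> $se_combined
#> [1] 0.2236068
#> $p
#> [1] 0.0007962302
```

The motif-level table reads: oligomannose-type features dropped ~6.9 log2
units in the case group (they carry three redundant-but-not-identical
motif columns), with a BH-adjusted p of 0.053 — borderline at n = 8+8 with
20% missing cells — while the sequence-level run recovers 10% of the
injected structures at zero false positives. Negative `statistic` with
positive `log2fc` reflects the usual two-sample t orientation (first group
minus second).

A command-line interface over the same functions is installed as
`exec/glycodiff` (subcommands `annotate`, `diff`, `anova`, `timeseries`,
`meta`, `simulate`; run it with `--help`).

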