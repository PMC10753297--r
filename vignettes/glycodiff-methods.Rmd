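---
title: "Differential glycomics expression analysis with glycodiff"
author: "glycodiff authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential glycomics expression analysis with glycodiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycodiff)
```

# The problem

Glycomics experiments report, per sample, the relative abundances of intact
glycan structures, normalized so that all glycans of a sample sum to 100.
Such data are compositional (an increase of one structure necessarily
depresses the shares of all others), heteroscedastic (variance grows with
abundance), plagued by non-detections stored as zeros or blanks, and the
biological signal often lives not in whole structures but in substructures
— motifs such as sialyl-Tn, Lewis antigens, core fucose, or "any
α2-6-linked sialic acid". glycodiff implements an end-to-end statistical
workflow for this data type: glycan parsing and motif quantification,
robust preprocessing, univariate and multivariate differential expression,
multi-group and time-series designs, meta-analysis across studies, and a
generative simulator with known ground truth used to validate all of the
above.

# Glycans as rooted labeled trees

A glycan in IUPAC-condensed notation, e.g. the di-sialyl-T antigen
`Neu5Ac(a2-3)Gal(b1-3)[Neu5Ac(a2-6)]GalNAc`, is parsed into a rooted
directed tree (`GlycanGraph`): the reducing-end residue is the root, every
other monosaccharide is attached to its parent through a linkage (anomeric
configuration, child and parent carbon positions), and substituents such as
sulfate are stored as (position, group) pairs on the residue
(`GlcNAc6S`, or `GalOS` when the position is unknown). Input may use Greek
or latin anomeric letters, parenthesized (journal-style) or bracketed
branches, and bare or parenthesized linkages; `canonicalizeIUPAC()` maps
all of these onto one canonical dialect.

The canonical serialization orders the branches at every node by parent
attachment position (ascending, `?` last, ties broken by the subtree
string) and writes the first branch as the unbracketed backbone. This key
is deterministic and dialect-independent, so canonicalization is idempotent
and invariant to the branch order of the input; note that it may reorder a
"longest-chain backbone" layout as printed in the literature, without
changing the underlying tree.

## Motif matching

A motif (`MotifDefinition`) is a connected glycan fragment plus

* a positional constraint — `terminal` (leaf-most pattern residues must map
  to non-reducing termini), `reducing-end` (the pattern root is anchored at
  the glycan root), `internal` (no pattern node may map to a non-reducing
  terminus), or `flexible`;
* an optional excluded context, a branch that must *not* hang off the
  matched root (so core 1, `Gal(b1-3)GalNAc` with excluded context
  `GlcNAc(b1-6)`, is not double-counted inside core 2 structures);
* a class (`named`, `terminal`, `disaccharide`, `monosaccharide`,
  `generalized`) that controls deduplication priority.

`countMotif()` counts the distinct node subsets of the glycan whose induced
connected subtree matches the pattern. Wildcards follow one rule
everywhere: `?` matches anything (including `?`), a concrete value matches
itself or `?`. Matches are counted as node subsets, not mappings, so
automorphic rearrangements of a symmetric pattern do not double-count. The
test suite validates every count against a brute-force enumerator of all
connected node subsets.

A single residue followed by a dangling linkage (e.g. `Neu5Ac(a2-?)`)
denotes a terminal residue-plus-linkage motif; single-residue glycans
expose the null linkage `?1-?` so that terminal counting remains defined.

The `internal` constraint is implemented as "no pattern node maps to a
leaf"; the reducing end itself is not excluded, which is the behaviour
wanted for internal LacNAc on real N- and O-glycans (their reducing end is
never part of a LacNAc unit).

# Motif quantification

`annotateDataset()` builds a glycans × motifs count matrix from any
combination of three feature sets: the packaged library of named epitopes
(`loadKnownMotifs()`, a curated subset of the named motifs in common use —
a drop-in TSV can replace it with a larger collection), all observed
terminal (residue, linkage) combinations, and all observed mono- and
disaccharide sub-patterns. For terminal and exhaustive motifs, wildcard
generalizations (e.g. `Neu5Ac(a2-?)` from `Neu5Ac(a2-3)`; `GlcNAcOS` from
`GlcNAc6S`) are generated one field at a time and retained only if their
count vector differs from that of every concrete family member — a
generalization that merely mirrors its only specialization carries no new
information and is dropped.

`quantifyMotifs()` converts glycan relative abundances into motif
abundances by the weighted sum `A[m, s] = Σ_g count(g, m) · A[g, s]`, so a
structure carrying two copies of an epitope contributes twice its
abundance. Motifs with exactly identical abundance vectors are then
collapsed to one representative, prioritized named motif > disaccharide >
terminal > monosaccharide (generalized motifs rank just below their
concrete class), ties broken by longer pattern, then lexicographically;
collapsing happens before the final rescaling so that the output is again
compositional: every sample column sums to 100.

`annotateDataset()` itself does not deduplicate by default: count vectors
over small glycan panels collide easily (every motif of a one-glycan panel
has the same "vector"), and the scientifically meaningful deduplication is
the one performed on the quantified abundances.

# Preprocessing

The pipeline order is fixed: sparsity filter → total normalization →
imputation → (motif quantification) → variance filter → log2 fold changes
→ variance-stabilizing normalization → tests → Benjamini-Hochberg.

**Zeros as missing.** Glycomics tables conflate non-detection with zero;
by default exact zeros are treated as missing marks (`zerosAsMissing`,
default on).

**Sparsity filter.** Features missing in more than half the replicates of
any group are removed; `minSamples` instead requires a minimum number of
nonzero replicates per group.

**Imputation.** `imputeMissForest()` records the missing positions,
initializes them with the sample median, and then iteratively (5 rounds)
trains, per sample, a random-forest regressor on the features observed in
that sample, with the other samples' values as predictors, and predicts
the missing positions. The forests use 100 trees with all predictors
available at every split (the common regression-forest defaults) and run
on the percent scale; negative predictions are clipped at zero and the
constant 1e-6 is added everywhere at the end, so observed values are
unchanged up to that shift and the completed table is strictly positive.

Two design choices deserve emphasis:

* *Within-condition imputation.* The two-group and ANOVA workflows apply
  the imputer separately to each biological condition. Reconstructing a
  test-group value partly from control samples pulls imputed cells of
  genuinely regulated features toward the other condition and measurably
  dilutes true effects in simulation; imputing within a condition leaves
  the cross-group contrast intact while still exploiting the strong
  replicate-to-replicate correlation. Time-series runs, having no groups,
  impute the whole table.
* *Percent (not log) response scale.* Regressing log abundances makes the
  forest predictions strongly shrunken on the scale of the downstream
  t-tests; in simulation this inflates sensitivity above even the
  complete-data arm while tripling the false-positive rate — a variance
  underestimation artifact, not signal — so the raw scale is used.

**Variance filter.** Features with across-sample variance below 0.01 on
the percent scale (essentially constant features) are removed before
testing.

**Variance-stabilizing normalization.** `varianceStabilize()` log2
transforms and standardizes each feature. Without groups, each feature is
scaled to mean 0 / sd 1. With groups — the form used before between-group
testing — each feature is centered at the grand mean of its group means
and scaled by the pooled within-group standard deviation: centering each
group separately would erase exactly the differences being tested, whereas
pooled-within-group scaling equalizes the within-group variance and
preserves between-group location shifts. Constant features (zero scale)
are dropped with a warning. On simulated null data this transform removes
the strong mean-variance dependence of relative abundances (Spearman
correlation of feature mean and sd drops from > 0.8 to ≈ 0).

# Statistical testing

**Two groups** (`getDifferentialExpression()`): two-tailed Welch t-tests
(or paired t-tests) on the variance-stabilized values, with Cohen's *d*
(unpaired; variance `(n1+n2)/(n1·n2) + d²/(2(n1+n2))`) or *d_z* (paired;
variance `1/n + d_z²/(2n)`). Log2 fold changes are computed on the
relative-abundance scale as `log2(mean(group2)/mean(group1))`, group2
being the case; after imputation all values are strictly positive, so fold
changes are always finite. Levene's test (Brown–Forsythe variant: one-way
ANOVA on absolute deviations from the group median) probes variance
differences per feature. The test p values and the Levene p values are
corrected as two separate Benjamini-Hochberg families — they answer
different questions.

**Motif sets** (`sets = TRUE`): a correlation network links two features
iff their Pearson correlation (on the variance-stabilized values — the
scale on which correlation is comparable across features) lies in
[0.9, 1), exact duplicates deliberately excluded; connected components
form sets. Multi-feature sets are tested with Hotelling's T²
(`T² = n1·n2/(n1+n2)·δ'S⁻¹δ`, exact F transform; Moore–Penrose
pseudo-inverse with reduced effective rank when the pooled covariance is
singular, as happens when set size approaches sample size) with the
Mahalanobis distance `√(δ'S⁻¹δ)` as effect size and its variance estimated
by bootstrapping samples within each group (N = 1000). A set's log2 fold
change is the mean of its members'; its Levene summary is the minimum
adjusted value over members (the test is variance-per-feature by nature).
Singleton sets fall back to the univariate path, so every feature appears
in exactly one result row.

**More than two groups** (`getGlycanova()`): per-feature one-way ANOVA on
the variance-stabilized values, BH across features, and Tukey HSD
triggered for features with adjusted p < 0.05; pairwise differences with
family-wise adjusted p < 0.05 are flagged.

**Time series** (`getTimeSeries()`): per feature an OLS fit of abundance
against time (replicates at a timepoint pooled; donor identity is not
modeled — mixed-effects designs are out of scope). Degree 1 tests the
slope with a t test; degree > 1 fits the polynomial and compares it with
the intercept-only model by an F test. BH across features.

# Meta-analysis

`fixedEffectsMeta()` combines per-study effect sizes by inverse-variance
weighting; `randomEffectsMeta()` estimates the between-study variance τ²
by DerSimonian–Laird (clamped at zero) and re-weights by `1/(v_i + τ²)`.
The combined p value uses a normal reference, the standard choice for
inverse-variance combination. `getMetaAnalysis()` matches features across
study result tables by exact canonical name (near-matches with different
linkage ambiguity are *not* merged — motif-level analysis is the remedy
for annotation heterogeneity), reports features present in at least one
study (k = 1 under the fixed model), applies BH across all combined
features, and optionally writes per-study forest-plot data (d, 95% CI,
combined d, adjusted p) as CSV.

# The glycome simulator

`simulateGlycomes()` models a normalized glycomics sample as a draw from a
Dirichlet distribution scaled to 100. The packaged default concentration
vector (`defaultAlpha()`) is a synthetic stand-in shaped like an
experimental N-glycome composition — a handful of dominant structures and
a long tail of trace ones, 118 values summing to 100 as relative
abundances do; users reproducing a particular dataset should pass their
own measured composition. Ground truth is injected by multiplying the
concentration parameters of 10 up-regulated features by `effectScale` and
dividing those of 10 down-regulated features by it (symmetric on the log
scale). Structures from the packaged fixture list (`fixtureGlycans()`,
~120 curated human O- and N-glycans composed from the standard cores with
common sialylation/fucosylation/sulfation patterns; terminal
α2-6-sialylated structures make up a realistic ~15% of the O-glycan list)
are assigned to the features — sialylated structures to up-regulated
features, fucosylated (non-sialylated) ones to down-regulated features.
`injectMissingness()` blanks an exact number of uniformly chosen cells
(re-drawing masks that would empty a feature), and `evaluateRecovery()`
scores sensitivity (significant *and* correct direction), specificity and
direction accuracy against the ground truth; features removed by the
sparsity filter count as not recovered.

What the simulator does *not* emulate: instrument noise and batch
structure, missingness that depends on abundance (real non-detection is
left-censoring, not missing-completely-at-random), annotation uncertainty,
and correlated biosynthetic regulation of related structures. Passing
recovery benchmarks on these simulations therefore demonstrates
calibration and robustness of the statistics under the compositional
model, not performance on any particular instrument's data.

Two quantitative consequences of the compositional model are worth
knowing. First, because the concentration parameters are relative
abundances summing to ~100, per-feature noise is substantial (a feature at
mean share α has log-scale standard deviation ≈ √trigamma(α)); absolute
sensitivity at effect scale 5 with 10+10 replicates plateaus around
0.4–0.6 depending on the composition's tail, and no choice of composition
can push it near 1. All validation claims in this package are therefore
relative (imputed vs complete vs naive arms; motif- vs sequence-level),
not absolute. Second, scaling up-effects by s adds ≈ (s−1)·Σα_up of
concentration mass while down-effects remove only ≈ (1−1/s)·Σα_down, so at
large s every null feature acquires a genuine negative relative shift;
"false positives" at large effect scales partly reflect this real
compositional displacement.

# Problem sizes used in the packaged checks

The test suite and the acceptance script use the study conditions directly
where they are cheap (motif counting on the full fixture panel; 50
simulated experiments of 128 features and 10+10 replicates for the
imputation benchmark; 20 seeded runs of 5+5 replicates for the motif-level
fold-change calibration; ≥ 200 null features for calibration of the raw p
values) and smaller panels for property checks that hold at any size
(round-trips on 50 glycans, brute-force count agreement on 12–20 glycans ×
the motif library).

# Known limitations

* The IUPAC-condensed dialect coverage is deliberately a subset (no WURCS
  or GlycoCT; no repeat units); unknown residue tokens are carried as
  opaque labels so composition-level data still flow through the
  sequence-independent statistics.
* The named-motif library ships ~30 curated epitopes, not an exhaustive
  collection; the TSV format accepts drop-in replacements.
* Correlation sets use a hard threshold; biologically related motifs below
  it are tested separately.
* No covariates, interactions or mixed effects; time series are pooled
  OLS.
* p values from Hotelling's T² with pseudo-inverse fallback are
  approximate when the pooled covariance is singular.
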