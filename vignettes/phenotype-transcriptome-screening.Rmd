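---
title: "Linking behavioural severity to striatal transcription: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking behavioural severity to striatal transcription: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mouse models of Huntington's disease (HD) show marked inter-individual
variability in motor and cognitive impairment even on a controlled genetic
background and under controlled housing. `phenoscreen` implements the
inference chain that asks whether this behavioural heterogeneity has
transcriptional correlates: score each animal's overall phenotype, isolate
the extremes, and test whether the HD transcriptional signature — the set of
striatal genes consistently dysregulated by the mutant huntingtin fragment —
is deeper in the worst-affected animals, both within a cohort and against an
external knock-in (KI) allelic series of increasing CAG-repeat length and
age.

The chain has five stages, each exposed as ordinary tidyverse-style
functions and chained end to end by `run_pipeline()`:

1. **Trait processing** (`progression_rate()`, `cv_summary()`,
   `mann_whitney()`): per-animal trait derivations and genotype contrasts.
2. **Composite scoring and classification** (`zscore_traits()`,
   `classify_performers()`): oriented Z-scores and the good/poor/average
   performer split.
3. **Correlation screen** (`trait_gene_screen()` on qPCR folds from
   `relative_expression()` or on normalized counts): rank correlations
   between traits and per-gene expression with Benjamini–Hochberg control.
4. **Differential expression** (`size_factors()`, `estimate_dispersion()`,
   `nb_wald_test()`): a self-contained negative-binomial Wald stage.
5. **Gene-set partition and progression** (`partition_gene_sets()`,
   `progression_profile()`, `hypergeometric_ora()`): the four-way severity
   partition and its presence among the top-ranked DEGs of the allelic
   series.

A synthetic-cohort generator with planted ground truth (`simulate_cohort()`,
`simulate_counts()`, `simulate_allelic_series()`) makes every stage testable
with known answers.

## Composite scoring and extreme performers

Each behavioural measurement is first multiplied by its trait's
*orientation* (+1 when a larger value means better performance, e.g.
rotarod latency or body weight; −1 when larger means worse, e.g.
feet-clasping duration), then standardized as `(value − average) / s.d.`
within a standardization group. The default group is genotype × trait ×
timepoint: the study design classifies extremes *within each genotype*, so
pooling genotypes would let the large genotype main effect dominate the
within-group ranking. Whether the original analysis pooled genotype means is
not documented; the within-genotype choice is the one consistent with
classifying good and poor performers of both genotypes.

Animals are ranked by (i) the number of positive minus negative scores and,
where tied, (ii) the mean score over all included measurements, with a
lexicographic animal-id tie-break so results are reproducible. The top and
bottom `k = 4` animals per genotype are labelled good and poor. Both
timepoints of the three classification traits enter (6 measurements per
animal); whether criterion (ii) averages over traits or trait × timepoint
cells is not documented — we average over all included measurements.
Animals with incomplete batteries are never ranked; they are reported and
left unlabelled.

Throughout the package, "the trait score" of an animal means the mean of the
trait's timepoint measurements unless a single timepoint is requested
(`screen_timepoint`): the battery measures each trait twice, and averaging
the two measurements is both the natural noise-reduction step and the
convention applied uniformly in the correlation screen, the recovery
properties and the pipeline.

## The correlation screen

For each trait × gene pair the screen reports Spearman's rank correlation
(ties receive average ranks) and Pearson's coefficient, with significance
from the regression t-test `t = rho * sqrt((n − 2) / (1 − rho^2))` on
`n − 2` degrees of freedom applied to the Spearman coefficient (the headline
statistic; expression can therefore be supplied on any monotone scale —
qPCR folds, normalized counts or their logarithms give identical results).
Benjamini–Hochberg adjustment is applied within each (tissue, genotype)
panel by default — the panel-local reading of the per-panel flag annotation
— with `family_scope = "global"` available for a joint family. Flags mark
unadjusted p < 0.05 (`tilde`) and adjusted p < 0.1 (`star`). Pairs with
fewer than `min_n = 5` overlapping animals, or with a constant vector, are
skipped and counted.

## qPCR relative quantification

`relative_expression()` implements the delta-Ct method with amplification
efficiency fixed at 2 (no standard-curve correction is modelled):
`rel = 2^−(Ct_gene − Ct_ref)` against the reference gene (Gapdh by
default), then a fold against the baseline genotype computed with a
*geometric* mean — folds are log-scale quantities, so the geometric mean is
the unbiased baseline and guarantees the baseline group has geometric-mean
fold 1. Because target and reference share a sample, whole-sample Ct shifts
(plate effects) cancel exactly.

## The negative-binomial Wald stage

The DE stage is deliberately self-contained: normalization by
median-of-ratios size factors, a per-gene NB generalized linear model with
log link and design intercept + group, fitted by iteratively reweighted
least squares with log size factors as offsets, and a Wald test
`log2fc / se` with a two-sided normal p-value, BH-adjusted over the tested
genes. Genes with zero counts everywhere are flagged `untested`, kept in the
output, and excluded from the BH family. It is a simplified engine, not a
DESeq2 clone: there is no outlier refitting, no independent filtering and no
fold-change shrinkage.

Numerical choices:

* The group covariate is coded −1/2, +1/2. With this symmetric coding every
  floating-point operation of the fit maps exactly under a label swap, so
  swapping groups negates each log2 fold change bit-for-bit and preserves
  p-values exactly.
* A small ridge precision (default `1e-6`) on the group coefficient keeps
  genes expressed in only one group finite; the linear predictor is clamped
  to ±30 to prevent overflow. Non-converged genes (50-iteration cap) are
  flagged and their p set missing.
* Dispersion is estimated by method of moments on normalized counts pooled
  within groups, `alpha_raw = max(0, Σ(n_g−1)(s²_g − m_g) / Σ(n_g−1)m_g²)`,
  then combined with a mean–dispersion trend (linear-scale loess of the raw
  estimates on log mean) used as a *floor*:
  `alpha = trend + (1 − shrink) · max(0, raw − trend)`, `shrink = 0.5` by
  default. The floor design reflects a calibration asymmetry at small n:
  per-gene underestimates inflate the Wald statistic and the tail false
  discoveries, while overestimates only cost a little power. In our
  calibration simulations (4 vs 4, alpha 0.2) symmetric shrinkage left the
  false-discovery proportion at q < 0.05 near 0.15 — as does DESeq2 on the
  same draws — whereas the trend floor brings it below 0.10 while keeping
  the raw type-I rate at ~0.05 and sensitivity for planted two-fold changes
  above 80%. `shrink = 0` exposes the raw method-of-moments estimator.

The study's three contrasts — mutant poor vs pooled wild-type, mutant good
vs pooled wild-type, poor vs good — are one `de_analysis()` call each; the
wild-type pool is the classified wild-type animals (good + poor), mirroring
the pooling used to gain power after no wild-type DEGs were found.

## The severity partition and presence progression

`partition_gene_sets()` combines the three contrasts at an FDR threshold
(default 0.05). Candidates are significant between poor and good *and*
versus wild-type in at least one contrast; direction is the sign of the
vs-wild-type fold change (sign conflicts between the two vs-wild-type
contrasts are excluded and counted). A candidate belongs to the "poor" sets
when its change versus wild-type is deeper in the poor contrast — by
default measured as larger |log2fc|, because the p-value conflates effect
size with precision; `by = "pvalue"` exposes the alternative. Genes
significant versus wild-type in both contrasts with a consistent sign but
*not* between poor and good form the "rest" sets.

`top_deg_presence()` ranks a comparison's same-direction genes by ascending
p (ties: larger |log2fc| first, then gene id — external tables come ranked
by significance but carry no documented tie rule) and reports the
percentage of a set found among the top `n_top = 684`. The denominator is
the set size — the fraction of the set recovered — and set members missing
from a table count as absent. `n_top = 684` is the external study's
top-DEG cut and is treated as a plain parameter; the equal-size "bins"
mentioned alongside it in the source methods have no documented role
relative to the cut, so only the top-N reading is implemented.
`progression_profile()` applies this over the CAG × age grid and summarises
monotonicity as Spearman correlations of presence against CAG length at
each age and against age at each CAG length.

`hypergeometric_ora()` is a generic stand-in for web-service GO enrichment:
an upper-tail hypergeometric test with an optional EASE decrement
(`k → max(k − 1, 1)`, applied only when k ≥ 1; a zero overlap keeps p = 1,
since a decrement that makes an empty overlap look enriched would be
nonsensical).

## The synthetic cohort generator

`simulate_cohort()` plants a latent per-animal severity factor
`s ~ N(0, 1)` — high s means favourable outcome — in mutant animals only;
wild-types carry no severity component, reproducing the genotype asymmetry
in which trait–expression correlations appear only in mutants. A trait
value is `baseline + genotype_effect·is_mut + loading·s·is_mut + noise`,
with each trait's loading signed to agree with its orientation. Defaults
follow the study design: 24 wild-type and 29 mutant males, litters assigned
round-robin, three traits (rotarod, feet clasping, weight) at two
timepoints, and loading/noise ratio 2.

`simulate_counts()` draws NB counts with mean
`mu0_g · lib_j · 2^(planted_log2fc_g·is_mut + slope·s_j)` and variance
`m + alpha·m²` (`alpha = 0` falls back to Poisson). Defaults: 2000 genes
(200 signature), lognormal gene means around 100, dispersion 0.2, library
factors uniform on (0.7, 1.4), planted genotype log2FC −1 (the HD signature
is downregulated) and severity slope +0.75 log2FC per severity s.d., chosen
so the per-s.d. severity effect is somewhat smaller than the genotype main
effect and the severity signal carried by a signature gene is comparable to
(slightly weaker than) a trait loading. Worse animals are therefore more
downregulated, and good mutants can sit near wild-type levels for signature
genes — which is why the "rest" sets (significant in both vs-wild-type
contrasts but not between extremes) are often small under these defaults.

`simulate_allelic_series()` emulates the external KI tables (Q80–Q175 at
2, 6, 10 months vs Q20): every gene receives a latent z-score *shared
across grid cells*, and members of the designated progressive sets get a
signed effect equal to the cell's scaling plus noise. Sharing the null
draws across cells makes presence exactly monotone in the scaling when the
noise is zero, and keeps cell-to-cell differences attributable to the
planted effects alone. Each generator draws from its own stream seeded from
the configuration seed plus a call tag, so adding a generator never shifts
another's draws and a fixed seed gives byte-identical outputs.

What the generator does *not* emulate: raw reads or alignment, litter
random effects (litters are labels only), trait learning dynamics across
timepoints (the two timepoints are exchangeable replicates by default),
correlated gene-gene expression modules, and CAG-repeat instability.
Passing tests therefore demonstrate that the machinery recovers planted
structure under NB noise at the study's sample sizes — not that real
cohorts satisfy these generative assumptions.

## Problem sizes and reproducibility

The test-suite and acceptance-script simulations are sized for a
single-CPU desktop run while keeping every estimate's Monte-Carlo error
well inside its decision band: 200 cohorts for classification recovery,
20 replicates × 60-gene panels (a qPCR-panel scale) for screen calibration
and power, 20 replicates of 2000-gene 4-vs-4 count matrices for DE
calibration, an 8000-gene universe with 150-gene sets for presence
progression, and the full 24 + 29 × 2000-gene pipeline for end-to-end
determinism. All randomness flows from a single integer seed;
`run_pipeline()` rerun with the same configuration reproduces every
deterministic output byte-identically (only the human-readable report
carries a timestamp).

## Known limitations

* The Wald p-value uses the normal reference; at very small sample sizes
  the trend-floor dispersion compensates in calibration but individual
  low-count genes remain approximate.
* Single-factor, two-group designs only — no covariates, no litter random
  effects, no multi-factor models.
* The correlation screen tests pairs independently; it does not model
  trait–trait or gene–gene correlation.
* GO/TF annotation retrieval is out of scope: `hypergeometric_ora()` works
  on user-supplied gene lists only.
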