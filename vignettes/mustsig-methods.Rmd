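---
title: "Methods: vineyard-site signatures in must microbiomes and fermentation transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vineyard-site signatures in must microbiomes and fermentation transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mustsig)
```

## The scientific question

Grape must arrives at the winery carrying a microbial community shaped by its
vineyard of origin, and inoculated fermentations are dominated by the added
*Saccharomyces cerevisiae* strain almost immediately.  `mustsig` implements a
complete analysis for three linked questions:

1. Do must microbial DNA profiles (16S and ITS amplicon sequence variants) and
   fermentation transcriptomes carry vineyard-site, region, and vintage
   signatures detectable by community statistics and supervised classifiers?
2. Does the DNA abundance of an organism in the must predict its
   transcriptional activity during fermentation?
3. Which genes carry the site/region signal consistently enough to survive an
   intersection across many independently seeded models?

Because the package is developed and tested without access to any sequencing
archive, it ships a first-class synthetic-study generator whose ground-truth
record makes every downstream inference scoreable.

## Compositional analysis

Sequencing counts are compositions: only relative information is meaningful.
All community statistics therefore operate on centered log-ratio (CLR)
transformed data, `clr(x)_i = log(x_i / g(x))` with `g(x)` the geometric mean
of the sample, and on the Aitchison distance (Euclidean distance between CLR
vectors).  Two zero-replacement policies are exposed, because the choice is a
convention rather than an estimate:

* `"multiplicative"` (default): zeros in the relative-abundance matrix are
  replaced by half the smallest nonzero relative abundance in the table and
  the remaining entries are shrunk multiplicatively so each sample still sums
  to one.  This keeps CLR scale-invariance exact.
* `"add_one"`: one pseudo-read per count before closure, for users who prefer
  the count-domain convention.

Shannon diversity is reported in nats (natural log); the base is pinned so
results are deterministic and comparable.  Chao1 uses the bias-corrected form
`S_obs + F1(F1 - 1) / (2 (F2 + 1))`, which remains defined when no doubletons
are observed.  The core microbiome is the set of features at or above 1%
relative abundance in at least 90% of samples; both thresholds are arguments.
The 1% floor is assessed per sample (not on per-site means) — the stricter
and more common reading.

## Permutation statistics

`anosim()`, `permanova()`, and `mantel()` are implemented directly from their
definitions; `vegan`'s implementations are used in the test suite as
independent cross-checks, never as the computational path.

* ANOSIM: `R = (mean rank between - mean rank within) / (M / 2)` over the
  `M = n(n-1)/2` pairwise distances, with average ranks for ties.  The `M/2`
  denominator is the standard one (it bounds `R` in `[-1, 1]`) and matches
  `vegan::anosim` to machine precision.
* PERMANOVA (one grouping factor): `SS_T = sum(d^2)/N` over all pairs,
  `SS_W = sum_g sum(d^2)/n_g` within groups, pseudo-F
  `((SS_T - SS_W)/(a - 1)) / (SS_W/(N - a))`, `R2 = (SS_T - SS_W)/SS_T`.
  Site, region, and vintage are tested separately; multi-factor partitioning
  is out of scope.  When every group collapses onto one point the statistic
  is `Inf` and flagged `"maximal_F"` rather than `NaN`.
* Mantel: Spearman correlation (average ranks) of the strictly-lower-triangle
  vectors, permuting rows and columns of one matrix jointly; missing entries
  are dropped pairwise; constant matrices return a flagged, `NA`-statistic
  result.

All permutation p-values are `(b + 1) / (m + 1)` with `b` the number of
permuted statistics at least as large as the observed one, so `p = 0` is
impossible.  With `n_perm = "exact"` all `n!` label arrangements are
enumerated (via `permute::allPerms`), and the test suite checks statistic and
p-value against brute-force enumeration oracles at `n <= 7`.

NMDS wraps `vegan::monoMDS` (global monotone regression, Kruskal stress-1)
under a best-of-restarts strategy; coordinates are centered, rotated to
principal axes, and sign-fixed so output is orientation-stable.  One
numerical subtlety: under Kruskal's primary (weak) tie treatment a constant
dissimilarity matrix imposes no rank constraints and can reach stress 0, so
"impossible" embeddings are only guaranteed positive stress when their
dissimilarities have distinct ranks.

Geographic distances use the haversine formula (via `geosphere`) with the
IUGG mean Earth radius 6371.0088 km; disparate covariates are standardized
(`scale_center()`, dropping constant columns with a warning) before being
combined into distance matrices; Mantel p-values across covariate pairs are
adjusted by Benjamini-Hochberg FDR with a conventional reporting threshold
of 0.1.

## DNA-RNA concordance

For each organism detected by both assays (pairing on the normalized binomial
species name: lower case, abbreviation dots stripped, whitespace collapsed;
genus-only DNA features are flagged as candidates, not matched), the
organism's RNA relative abundance at one timepoint is regressed by ordinary
least squares on its DNA relative abundance in the paired pre-inoculation
must sample, across fermentations.  Counts are converted to relative
abundances before regression; no log-ratio regression is attempted, matching
the plain-regression convention this analysis follows.  The **adjusted** R² is
reported: it can be negative, and a negative value is a legitimate outcome
that the test suite explicitly exercises under a zero-linkage generator.
DNA samples are paired to every RNA timepoint of the same tank, and the
regression runs separately per timepoint.

## Random-forest signatures

Transcript time series violate the independence assumption of supervised
learning, so each gene's library-size-normalized counts across a
fermentation's timepoints are collapsed to five attributes (mean, min, max,
total, sample sd).  Amplicon models use ASV relative abundances directly.
The model core is `ranger` with 10,000 trees at full scale (tests and the
acceptance script use 200-500 trees for runtime, which only widens
Monte-Carlo noise), permutation importance, casewise (local) importance, and
a fixed seed.  Hyperparameters (`mtry` in {sqrt(p), p/5, p/2},
`sample.fraction` in {0.632, 0.8, 1.0}, `min.node.size` in {1, 5, 10}) can be
tuned by out-of-bag error; ties break toward the first grid point so runs
are reproducible.

Variable selection follows the vita idea: cross-validated *per-tree*
permutation importance on held-out folds (5 folds by default, reduced with a
warning when the smallest class is smaller), with a null distribution formed
by mirroring the non-positive importances and an empirical p-value per
feature (selection threshold 0.05).  Working per tree matters: permuting one
feature barely changes an aggregated forest prediction when thirty correlated
features carry the same signal, and an aggregated-prediction estimator
collapses to zero importance exactly where the signal is strongest.
Selection runs on the training side of each split only, to keep the test set
untouched.

Casewise importance is taken from the fitted ensemble and rescaled by each
training sample's out-of-bag tree count, so entry (i, j) is the mean drop in
correct-vote indicator over the trees where sample i is out-of-bag.  The
per-feature mean of this matrix reconciles with an independently recomputed
per-tree out-of-bag permutation importance (correlation > 0.95 in the
acceptance suite).

The consensus signature repeats selection + fitting under `S` seeds (100 at
full scale; 20 in the recovery tests), averages casewise importance over the
training fermentations of each class, retains features with positive class
averages, maps features to genes (a gene qualifies if *any* of its five
attributes qualifies — the attributes are strongly correlated), and
intersects the per-class gene sets across all `S` models.  Negative casewise
values are kept through the averaging; only the class-average's sign is
thresholded.  An empty intersection is a valid result.  For amplicon models
(one sample per tank, no time series) the class average is simply the mean
over training rows of the class.

Organism attribution truncates negative importances to zero, sums per
organism, and reports percentages of the total.

Two validation schemes: a stratified 70:30 split (per-seed random), and
leave-one-vintage-out, which trains on all samples of the other vintages and
is the stronger claim of vintage-robust signatures.

## What the generator emulates — and what it does not

`scenario_config()` defaults encode the emulated study design: 15 sites in 8
regions (2,2,2,2,2,2,2,1), 4 tanks x vintages {2016, 2017, 2019} sampled for
DNA (180 samples; a `dropped_tanks` argument reproduces irregular designs),
and 2 tanks x {2017, 2019} x 5 timepoints (2, 6, 16, 64, 112 h) for RNA
(60 fermentations, 300 samples).

* **Communities** are hierarchical Dirichlet-multinomial: per-taxon baseline
  log-abundances plus region, site, and vintage Gaussian effects
  (log-scale sds 0.5 / 0.8 / 0.3 by default), a single dominant taxon
  (*Hanseniaspora uvarum* / *Tatumella* analogues) boosted by
  `dominance_alpha` (default 50x), Dirichlet precision 50 for amplicon-level
  overdispersion, and Poisson depths around 5x10^4 reads.  Depths are desk
  scale: they keep the full design generable in about a second while leaving
  multinomial noise negligible relative to the planted effects.
* **Transcriptomes** give the inoculant 90% of reads and a fixed
  *Vitis vinifera* analogue 5%, so organism attribution always has at least
  three classes.  Only `frac_active_taxa` (default 5%, i.e. 4 of 80 fungal
  taxa) of DNA-detected taxa are transcriptionally active; for those, RNA
  share is a linear function of DNA relative abundance with noise calibrated
  so the population R² equals `dna_rna_r2` (the total share sd is held at a
  third of the mean share, keeping clipping at zero rare).  Thirty planted
  inoculant genes carry site effects (log-sd 1.5, rescaled per gene so every
  planted gene carries the full effect), constant across vintages and partly
  shared within regions, so region models and within-region confusion
  structure are both meaningful.
* **Environment**: region centers in a Willamette-Valley-like box, sites
  scattered around them; precipitation and growing degree days combine
  deterministic orographic gradients (west-east for precipitation,
  north-south for heat, 60% of variance), a persistent site climatology, and
  smaller vintage anomalies, with the stochastic parts drawn from a
  squared-exponential Gaussian process of range 100 km over great-circle
  distances.  An earlier all-stochastic exponential field was abandoned
  during generator calibration: a single rough realization over 15 sites
  gave the geography-climate Mantel test well under the intended 90%
  detection rate, which misrepresents how strongly real regional climate
  tracks geography.  Must chemistry (pH, TA, malic acid, NOPA, NH3) has
  site-by-vintage means with per-fermentation noise shared between the DNA
  sample and all RNA timepoints of the same tank.

Determinism: one master seed; each module draws from a sub-stream derived by
a fixed offset, so components are independently reproducible and the whole
study is byte-identical under a repeated seed.

The generator does *not* emulate: read-level artifacts (chimeras, sequencing
error, primer bias), taxonomy misannotation, bacterial transcription (3'
tag chemistry is effectively restricted to polyadenylated eukaryotic mRNA),
compositional interactions between taxa, or fermentation kinetics.  Passing
tests therefore demonstrate that the *statistical machinery* recovers planted
structure under realistic sampling noise — not that any particular real
dataset contains such structure.

## Problem sizes and numerical choices

The recovery and calibration checks run at fixed, recorded sizes chosen as
the package's own test conditions: type-I calibration on 400 null datasets
(2 regions x 3 sites x 2 tanks x 2 vintages, 40 taxa, 999 permutations);
exhaustive oracles at n <= 7; 1,000 fuzzed tables for the compositional
invariants; classifier recovery at the full 15-site design with 500 trees;
signature recovery with 30 planted genes among 200 and S = 20 seeds;
concordance recovery at targets {0, 0.25, 0.9} over 20 replicate studies.
Forest sizes below the 10,000-tree full-scale default trade Monte-Carlo
precision for runtime and are stated wherever used.

Other pinned choices: average ranks for all ties; one-sided permutation
p-values; majority-vote ties in `ranger` resolve by its seeded internal
order; `which.min` tie-breaks in tuning take the first (most conventional)
grid point; NMDS uses 20 restarts, 500 iterations, tolerance 1e-6.

## Known limitations

* PERMANOVA is single-factor; nested or interaction designs need external
  tools.
* The vita null relies on enough genuinely uninformative features; on
  all-signal feature sets it degrades to selecting positive importances,
  with a warning.
* Casewise importance rows are undefined for samples never out-of-bag
  (possible only for tiny forests); they are flagged, not imputed.
* Species-name matching is string-based; it cannot resolve DNA features
  annotated only to genus, which are reported as candidates instead.
* The DNA-RNA linkage is linear on relative abundances by design, mirroring
  the analysis it reproduces; a compositionally coherent (log-ratio)
  regression is deliberately out of scope.
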