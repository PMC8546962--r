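# mustsig

Vineyard-site signatures in grape-must microbiomes and fermentation
transcriptomes.

Wine grapes arrive at the winery with a vineyard-specific microbial load, yet
inoculated fermentations are taken over by the added *Saccharomyces
cerevisiae* strain within hours. `mustsig` is an R package for the analyses
this situation calls for:

* **Do genetic profiles group by site, region, and vintage?**
  Compositional data analysis — centered log-ratio (CLR) transform, Aitchison
  distance `d(x, y) = ||clr(x) − clr(y)||₂` — with ANOSIM
  (`R = (r̄_between − r̄_within) / (M/2)`), one-factor PERMANOVA
  (pseudo-F and R² from the distance sums of squares), Mantel tests
  (Spearman, joint row/column permutation), NMDS ordination, core-microbiome
  detection (≥ 1% abundance in ≥ 90% of samples), and Shannon/Chao1 alpha
  diversity. Permutation p-values are `(b + 1)/(m + 1)` and every test has an
  exhaustive-enumeration mode (`n_perm = "exact"`) for small n.
* **Does DNA abundance predict RNA activity?** Per organism and timepoint,
  ordinary least squares of RNA relative abundance on the paired must
  sample's DNA relative abundance across fermentations, reporting slope and
  *adjusted* R² (negative values are meaningful and preserved), plus
  species-level detection overlap between the two assays.
* **Which genes encode the site signal?** Transcript time series summarized
  to five per-gene attributes (mean/min/max/total/sd of library-size
  normalized counts), vita-style variable selection (cross-validated per-tree
  permutation importance with a mirrored null), seeded `ranger` forests with
  casewise (local) permutation importance, stratified 70:30 and
  leave-one-vintage-out validation, and consensus signatures: the
  intersection, across S independently seeded models, of genes with positive
  class-average casewise importance. Organism-level attribution of importance
  is reported in percent.

A hierarchical Dirichlet-multinomial study generator (`generate_study()`)
produces complete synthetic studies — 16S/ITS ASV tables with taxonomy,
per-timepoint transcript tables with organism labels, metadata with must
chemistry and spatially autocorrelated climate — together with a ground-truth
record (active taxa, planted site-informative genes) so recovery can be
scored without any external data.

## A worked example

```r
library(mustsig)

cfg   <- scenario_config(seed = 42)   # 15 sites, 8 regions, 3 vintages
study <- generate_study(cfg)
study
#> synthetic_study: 180 DNA samples, 60 fermentations x 5 timepoints (RNA)
#>   bacterial: 62 taxa; fungal: 80 taxa; genes: 200; active taxa: 4; planted site genes: 30

# community structure in the fungal must profiles
md <- study$metadata[study$metadata$assay == "DNA", ]
al <- align_samples(study$fungal, md)
d  <- aitchison_distance(al$table)
anosim(d, al$metadata$site, n_perm = 999, seed = 42)
#> ANOSIM: statistic = 0.946, p = 0.001 (999 permutations)
permanova(d, al$metadata$site, n_perm = 999, seed = 42)
#> PERMANOVA: statistic = 7.68, p = 0.001 (999 permutations)
#>   R2: group = 0.3945

# does must DNA abundance predict fermentation activity?
regress_dna_rna(study$fungal, study$transcripts[["h2"]], study$metadata,
                "Hanseniaspora uvarum", timepoint_hours = 2)
#>               organism timepoint_hours      slope r_squared      p_value
#> 1 Hanseniaspora uvarum               2 0.04255307 0.2886044 5.751078e-06

core_microbiome(study$fungal)
#> [1] "fASV0001" "fASV0030"
```

The ANOSIM R of 0.946 says fungal communities are far more similar within a
site than between sites; the PERMANOVA R² attributes ~39% of the Aitchison
variance to site. The concordance regression recovers the configured weak
DNA–RNA linkage (`dna_rna_r2 = 0.25` generated; adjusted R² 0.29 fitted at
2 h): the dominant *Hanseniaspora* DNA signal only weakly predicts its
transcription. The core microbiome contains the planted dominant taxon.

For signature extraction:

```r
ff  <- summarize_timeseries(study$transcripts, study$metadata)
sig <- consensus_signature(ff, target = "site", S = 20, num_trees = 500)
score_signature(sig, study$truth)   # sensitivity / null inclusion vs truth
```

`run_pipeline()` (or `inst/scripts/run_pipeline.R --config run.yaml`) chains
generation, organelle filtering (removing chloroplast/mitochondrial 16S
lineages), community tests, concordance, and signatures, writing every
artifact with an md5-hashed JSON manifest; a rerun under the same seed is
verifiably identical.

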