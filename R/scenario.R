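#' Scenario configuration for synthetic studies
#'
#' Defines the design and statistical structure of a simulated multi-vineyard
#' fermentation study: the region/site/tank/vintage hierarchy sampled for
#' amplicon (DNA) profiling, the reduced tank/vintage design profiled by 3'
#' tag RNA sequencing over fermentation timepoints, hierarchical log-normal
#' compositional effects, single-genus dominance, the DNA-RNA activity
#' linkage, and spatially autocorrelated climate covariates.
#'
#' @param n_regions number of growing regions.
#' @param sites_per_region sites per region; a single count or one count per
#'   region (default `c(2,2,2,2,2,2,2,1)`: 15 sites over 8 regions).
#' @param tanks_per_site replicate fermentation tanks per site and vintage
#'   sampled for DNA (default 4).
#' @param vintages vintage labels sampled for DNA (default 2016/2017/2019).
#' @param rna_vintages,rna_tanks_per_site the subset of vintages (default
#'   2017/2019) and tanks (default 2) followed by RNA sequencing.
#' @param n_bacterial_taxa,n_fungal_taxa,n_genes feature counts.
#' @param timepoints_hours ordered fermentation sampling times in hours
#'   (default `c(2, 6, 16, 64, 112)`).
#' @param effect_sd_region,effect_sd_site,effect_sd_vintage log-scale
#'   standard deviations of the hierarchical compositional effects.
#' @param dominance_alpha multiplicative boost of the designated dominant
#'   taxon's mean relative abundance (Hanseniaspora/Tatumella analogue);
#'   1 disables dominance.
#' @param concentration Dirichlet precision of the per-sample composition
#'   around its mean; smaller values give more overdispersion.
#' @param frac_active_taxa fraction of DNA-detected fungal taxa with any
#'   transcriptional activity (default 0.05).
#' @param dna_rna_r2 target population R2 linking DNA and RNA relative
#'   abundance for active taxa (default 0.25).
#' @param library_size_dna,library_size_rna mean sequencing depths.
#' @param inoculant_share expected fraction of RNA reads from the inoculated
#'   *Saccharomyces cerevisiae* strain (default 0.90).
#' @param grape_share expected fraction of RNA reads from the grape
#'   (*Vitis vinifera* analogue) transcripts (default 0.05).
#' @param n_site_genes number of planted site-informative inoculant genes.
#' @param gene_effect_sd log-scale sd of the planted site effects (constant
#'   across vintages; partly shared within regions).
#' @param gene_noise_sd per-sample log-scale expression noise.
#' @param n_organelle_asvs number of plant chloroplast/mitochondria 16S ASVs
#'   to plant in the bacterial table (default 2).
#' @param env_spatial_range range (km) of the squared-exponential spatial
#'   correlation of the stochastic climate component; climate also carries
#'   deterministic west-east (precipitation) and north-south (growing degree
#'   days) gradients.  `Inf` makes the field constant.
#' @param dropped_tanks optional data frame with columns `site`, `vintage`,
#'   `tank` naming DNA fermentations to drop (irregular designs).
#' @param seed master integer seed; module sub-streams are derived from it by
#'   fixed offsets.
#'
#' @return a validated object of class `scenario_config`.
#' @export
scenario_config <- function(n_regions = 8,
                            sites_per_region = c(2, 2, 2, 2, 2, 2, 2, 1),
                            tanks_per_site = 4,
                            vintages = c("2016", "2017", "2019"),
                            rna_vintages = c("2017", "2019"),
                            rna_tanks_per_site = 2,
                            n_bacterial_taxa = 60,
                            n_fungal_taxa = 80,
                            n_genes = 200,
                            timepoints_hours = c(2, 6, 16, 64, 112),
                            effect_sd_region = 0.5,
                            effect_sd_site = 0.8,
                            effect_sd_vintage = 0.3,
                            dominance_alpha = 50,
                            concentration = 50,
                            frac_active_taxa = 0.05,
                            dna_rna_r2 = 0.25,
                            library_size_dna = 5e4,
                            library_size_rna = 1e5,
                            inoculant_share = 0.90,
                            grape_share = 0.05,
                            n_site_genes = 30,
                            gene_effect_sd = 1.5,
                            gene_noise_sd = 0.3,
                            n_organelle_asvs = 2,
                            env_spatial_range = 100,
                            dropped_tanks = NULL,
                            seed = 1) {
  cfg <- structure(as.list(environment()), class = "scenario_config")
  validate_scenario_config(cfg)
  cfg
}

#' @rdname scenario_config
#' @param cfg a `scenario_config`.
#' @export
validate_scenario_config <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$n_regions < 1) .stopf("all design counts must be >= 1")
  spr <- cfg$sites_per_region
  if (length(spr) == 1) spr <- rep(spr, cfg$n_regions)
  if (length(spr) != cfg$n_regions)
    .stopf("sites_per_region must have length 1 or n_regions")
  counts <- c(spr, cfg$tanks_per_site, cfg$rna_tanks_per_site,
              cfg$n_bacterial_taxa, cfg$n_fungal_taxa)
  if (any(counts < 1)) .stopf("all design counts must be >= 1")
  if (cfg$n_genes < 0) .stopf("n_genes must be >= 0")
  if (cfg$n_organelle_asvs < 0) .stopf("n_organelle_asvs must be >= 0")
  sds <- c(cfg$effect_sd_region, cfg$effect_sd_site, cfg$effect_sd_vintage,
           cfg$gene_effect_sd, cfg$gene_noise_sd)
  if (any(sds < 0)) .stopf("effect standard deviations must be >= 0")
  if (cfg$frac_active_taxa < 0 || cfg$frac_active_taxa > 1)
    .stopf("frac_active_taxa must lie in [0, 1]")
  if (cfg$dna_rna_r2 < 0 || cfg$dna_rna_r2 > 1)
    .stopf("dna_rna_r2 must lie in [0, 1]")
  tp <- cfg$timepoints_hours
  if (length(tp) < 1 || any(diff(tp) <= 0))
    .stopf("timepoints_hours must be strictly increasing")
  if (cfg$dominance_alpha <= 0 || cfg$concentration <= 0)
    .stopf("dominance_alpha and concentration must be > 0")
  if (cfg$inoculant_share + cfg$grape_share >= 1)
    .stopf("inoculant_share + grape_share must be < 1")
  if (!all(cfg$rna_vintages %in% cfg$vintages))
    .stopf("rna_vintages must be a subset of vintages")
  if (cfg$rna_tanks_per_site > cfg$tanks_per_site)
    .stopf("rna_tanks_per_site cannot exceed tanks_per_site")
  invisible(cfg)
}

#' Scenario presets
#'
#' `scenario_null()` removes every site/region/vintage effect, dominance
#' boost, and planted gene effect (at a reduced design size) and anchors the
#' type-I-error calibration of all permutation tests.
#' `scenario_large_effect()` keeps the full study design but uses strong,
#' clearly separated site/region effects; it anchors the power, classifier
#' recovery, and signature recovery checks.
#'
#' @param seed master seed.
#' @param ... overrides passed to [scenario_config()].
#' @return a `scenario_config`.
#' @export
scenario_null <- function(seed = 1, ...) {
  args <- modifyList(list(
    n_regions = 2, sites_per_region = 3, tanks_per_site = 2,
    vintages = c("2017", "2019"), rna_vintages = c("2017", "2019"),
    rna_tanks_per_site = 2, n_bacterial_taxa = 40, n_fungal_taxa = 40,
    n_genes = 40, effect_sd_region = 0, effect_sd_site = 0,
    effect_sd_vintage = 0, dominance_alpha = 1, gene_effect_sd = 0,
    n_site_genes = 0, seed = seed
  ), list(...))
  do.call(scenario_config, args)
}

#' @rdname scenario_null
#' @export
scenario_large_effect <- function(seed = 1, ...) {
  args <- modifyList(list(
    effect_sd_site = 2, effect_sd_region = 1, effect_sd_vintage = 0.3,
    gene_effect_sd = 1.5, seed = seed
  ), list(...))
  do.call(scenario_config, args)
}

# Expand the region/site hierarchy and the DNA / RNA sample designs.
study_design <- function(cfg) {
  spr <- cfg$sites_per_region
  if (length(spr) == 1) spr <- rep(spr, cfg$n_regions)
  regions <- sprintf("R%d", seq_len(cfg$n_regions))
  site_region <- rep(regions, spr)
  sites <- sprintf("S%02d", seq_along(site_region))
  tanks <- sprintf("T%d", seq_len(cfg$tanks_per_site))
  dna <- expand.grid(tank = tanks, vintage = cfg$vintages, site = sites,
                     stringsAsFactors = FALSE)[, c("site", "vintage", "tank")]
  dna$region <- site_region[match(dna$site, sites)]
  if (!is.null(cfg$dropped_tanks)) {
    drop_key <- with(cfg$dropped_tanks, paste(site, vintage, tank))
    dna <- dna[!paste(dna$site, dna$vintage, dna$tank) %in% drop_key, ,
               drop = FALSE]
  }
  dna$sample_id <- sprintf("dna_%s_%s_%s", dna$site, dna$vintage, dna$tank)
  rna_tanks <- tanks[seq_len(cfg$rna_tanks_per_site)]
  ferm <- expand.grid(tank = rna_tanks, vintage = cfg$rna_vintages,
                      site = sites,
                      stringsAsFactors = FALSE)[, c("site", "vintage", "tank")]
  ferm$region <- site_region[match(ferm$site, sites)]
  ferm$fermentation_id <- sprintf("%s_%s_%s", ferm$site, ferm$vintage, ferm$tank)
  ferm$dna_sample_id <- sprintf("dna_%s", ferm$fermentation_id)
  list(sites = data.frame(site = sites, region = site_region,
                          stringsAsFactors = FALSE),
       dna = dna, fermentations = ferm)
}
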