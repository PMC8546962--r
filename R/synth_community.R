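#' Simulate an amplicon community count table
#'
#' Hierarchical Dirichlet-multinomial simulator for 16S (bacterial) or ITS
#' (fungal) ASV counts over the full DNA sampling design.  Per-taxon baseline
#' log-abundances receive additive region, site, and vintage effects drawn
#' with the configured log-scale standard deviations; the designated dominant
#' taxon (a *Tatumella* / *Hanseniaspora uvarum* analogue) has its mean
#' relative abundance multiplied by `dominance_alpha`.  Each sample's
#' composition is drawn from a Dirichlet distribution with mean equal to the
#' softmax of its effect vector and precision `concentration` (giving the
#' overdispersion real amplicon data show), and counts are multinomial at a
#' Poisson-distributed depth around `library_size_dna`.  For 16S tables,
#' `n_organelle_asvs` plant chloroplast/mitochondria ASVs are planted so the
#' organelle filter has work to do.
#'
#' @param cfg a [scenario_config()].
#' @param marker `"16S"` or `"ITS"`.
#' @return a [count_table()] with taxonomy, samples = the DNA design.
#' @export
generate_community_counts <- function(cfg, marker) {
  validate_scenario_config(cfg)
  if (!marker %in% c("16S", "ITS"))
    .stopf("invalid marker '%s' for community simulation: use '16S' or 'ITS'",
           paste(marker, collapse = ","))
  if (cfg$library_size_dna <= 0)
    .stopf("library_size_dna = %g would produce an all-zero table",
           cfg$library_size_dna)
  des <- study_design(cfg)
  stream <- if (marker == "16S") "bacterial" else "fungal"
  set.seed(.substream(cfg$seed, stream))
  n_taxa <- if (marker == "16S") cfg$n_bacterial_taxa else cfg$n_fungal_taxa
  tax <- .community_taxonomy(marker, n_taxa,
                             if (marker == "16S") cfg$n_organelle_asvs else 0L)
  p <- length(tax$lineage)
  base <- rnorm(p, 0, 1)
  base[1] <- base[1] + log(cfg$dominance_alpha)
  if (tax$n_organelle > 0) {
    # plant-derived sequences amplify strongly in must
    base[seq.int(n_taxa + 1, p)] <- 1.5
  }
  sites <- des$sites$site
  regions <- unique(des$sites$region)
  eff_region <- matrix(rnorm(p * length(regions), 0, cfg$effect_sd_region),
                       p, length(regions), dimnames = list(NULL, regions))
  eff_site <- matrix(rnorm(p * length(sites), 0, cfg$effect_sd_site),
                     p, length(sites), dimnames = list(NULL, sites))
  eff_vintage <- matrix(rnorm(p * length(cfg$vintages), 0, cfg$effect_sd_vintage),
                        p, length(cfg$vintages),
                        dimnames = list(NULL, cfg$vintages))
  dna <- des$dna
  counts <- matrix(0L, p, nrow(dna),
                   dimnames = list(tax$feature_id, dna$sample_id))
  for (j in seq_len(nrow(dna))) {
    eta <- base + eff_region[, dna$region[j]] + eff_site[, dna$site[j]] +
      eff_vintage[, dna$vintage[j]]
    pm <- exp(eta - max(eta))
    pm <- pm / sum(pm)
    g <- rgamma(p, shape = cfg$concentration * pm, rate = 1)
    if (sum(g) == 0) g[which.max(pm)] <- 1
    pi_s <- g / sum(g)
    depth <- max(1L, rpois(1, cfg$library_size_dna))
    counts[, j] <- rmultinom(1, depth, pi_s)[, 1]
  }
  count_table(counts, marker, taxonomy = tax$lineage)
}

# Taxonomy strings with a handful of literature-motivated names (dominant
# Hanseniaspora uvarum / Tatumella, plus organisms detectable by both assays)
# and generic placeholders for the remainder.
.community_taxonomy <- function(marker, n_taxa, n_organelle = 0L) {
  if (marker == "16S") {
    named <- c(
      "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Erwiniaceae;Tatumella;Tatumella ptyseos",
      "Bacteria;Proteobacteria;Alphaproteobacteria;Acetobacterales;Acetobacteraceae;Gluconobacter;Gluconobacter oxydans",
      "Bacteria;Proteobacteria;Alphaproteobacteria;Acetobacterales;Acetobacteraceae;Gluconobacter;Gluconobacter cerinus",
      "Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus;Lactobacillus plantarum"
    )
    generic <- sprintf(
      "Bacteria;Phylum%02d;Class%02d;Order%02d;Family%02d;Bactium%03d;Bactium%03d muston",
      (seq_len(n_taxa) %% 6) + 1, (seq_len(n_taxa) %% 6) + 1,
      (seq_len(n_taxa) %% 9) + 1, (seq_len(n_taxa) %% 12) + 1,
      seq_len(n_taxa), seq_len(n_taxa))
    prefix <- "bASV"
    organelle <- rep(gsub(",", ";", .organelle_prefixes),
                     length.out = max(n_organelle, 0L))
  } else {
    named <- c(
      "Fungi;Ascomycota;Saccharomycetes;Saccharomycetales;Saccharomycodaceae;Hanseniaspora;Hanseniaspora uvarum",
      "Fungi;Ascomycota;Saccharomycetes;Saccharomycetales;Saccharomycodaceae;Hanseniaspora;Hanseniaspora vineae",
      "Fungi;Ascomycota;Dothideomycetes;Dothideales;Saccotheciaceae;Aureobasidium;Aureobasidium pullulans",
      "Fungi;Ascomycota;Saccharomycetes;Saccharomycetales;Saccharomycetaceae;Saccharomyces;Saccharomyces cerevisiae",
      "Fungi;Ascomycota;Leotiomycetes;Helotiales;Sclerotiniaceae;Botrytis;Botrytis cinerea"
    )
    generic <- sprintf(
      "Fungi;Ascomycota;Class%02d;Order%02d;Family%02d;Fungium%03d;Fungium%03d vineae",
      (seq_len(n_taxa) %% 5) + 1, (seq_len(n_taxa) %% 8) + 1,
      (seq_len(n_taxa) %% 11) + 1, seq_len(n_taxa), seq_len(n_taxa))
    prefix <- "fASV"
    organelle <- character(0)
  }
  k <- min(length(named), n_taxa)
  lineage <- c(named[seq_len(k)], generic[seq_len(n_taxa - k)])
  n_org <- length(organelle)
  lineage <- c(lineage, organelle)
  list(feature_id = sprintf("%s%04d", prefix, seq_along(lineage)),
       lineage = lineage, n_organelle = n_org)
}
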