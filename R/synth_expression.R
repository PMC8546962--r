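#' Simulate fermentation transcriptomes over timepoints
#'
#' Generates 3'-tag style per-gene transcript counts for every RNA-profiled
#' fermentation at every configured timepoint.  The inoculated
#' *Saccharomyces cerevisiae* strain contributes an `inoculant_share`
#' (default 90%) of reads at every timepoint and a fixed *Vitis vinifera*
#' grape analogue contributes `grape_share`, so organism attribution always
#' has at least three organism classes.  Only a fraction
#' `frac_active_taxa` of the DNA-detected fungal taxa receive any expression;
#' for those active taxa the RNA relative abundance is a linear function of
#' the taxon's DNA relative abundance in the paired must sample plus Gaussian
#' noise calibrated so the population coefficient of determination is
#' `dna_rna_r2`.  Planted site-informative inoculant genes carry
#' site-specific log-fold effects that are constant across vintages and
#' partly shared within regions.
#'
#' @param cfg a [scenario_config()].
#' @param fungal the ITS [count_table()] generated first with the same
#'   config (activity is assigned to a subset of its taxa).
#' @return a named list of mRNA [count_table()]s, one per timepoint
#'   (`"h2"`, `"h6"`, ...), with per-feature `organism` labels; the ground
#'   truth (active taxa, planted genes, gene-organism map) is attached as
#'   attribute `"truth"`.
#' @export
generate_expression_timeseries <- function(cfg, fungal) {
  validate_scenario_config(cfg)
  stopifnot(inherits(fungal, "count_table"), fungal$marker == "ITS")
  des <- study_design(cfg)
  ferm <- des$fermentations
  set.seed(.substream(cfg$seed, "expression"))

  # --- active taxa and their DNA relative abundances per fermentation -----
  n_active <- round(cfg$frac_active_taxa * cfg$n_fungal_taxa)
  species <- vapply(strsplit(fungal$taxonomy, ";"), function(x) x[length(x)], "")
  candidates <- seq_len(nrow(fungal$counts))
  active_idx <- integer(0)
  if (n_active >= 1) {
    active_idx <- 1L  # the dominant taxon (H. uvarum analogue) is active
    if (n_active > 1)
      active_idx <- c(active_idx,
                      sample(setdiff(candidates, 1L), n_active - 1L))
  }
  rel <- relative_abundance(fungal)
  x_dna <- matrix(0, length(active_idx), nrow(ferm),
                  dimnames = list(rownames(fungal$counts)[active_idx],
                                  ferm$fermentation_id))
  for (j in seq_len(nrow(ferm))) {
    sid <- ferm$dna_sample_id[j]
    if (sid %in% colnames(rel)) {
      x_dna[, j] <- rel[active_idx, sid]
    } else {
      # DNA sample dropped from the design: fall back to the site-vintage mean
      sel <- des$dna$site == ferm$site[j] & des$dna$vintage == ferm$vintage[j]
      x_dna[, j] <- rowMeans(rel[active_idx, des$dna$sample_id[sel],
                                 drop = FALSE])
    }
  }

  # --- organism shares per fermentation x timepoint -----------------------
  active_slice <- 1 - cfg$inoculant_share - cfg$grape_share
  n_tp <- length(cfg$timepoints_hours)
  shares_active <- array(0, dim = c(length(active_idx), nrow(ferm), n_tp))
  if (length(active_idx) > 0) {
    xbar <- rowMeans(x_dna)
    w <- pmax(xbar, 1e-4)
    m_t <- active_slice * 0.8 * w / sum(w)   # mean RNA share per active taxon
    tau <- m_t / 3                           # total sd across fermentations
    sx <- apply(x_dna, 1, sd)
    a_t <- ifelse(sx > 0, tau * sqrt(cfg$dna_rna_r2) / sx, 0)
    sig_e <- ifelse(sx > 0, tau * sqrt(1 - cfg$dna_rna_r2), tau)
    for (t in seq_len(n_tp)) {
      y <- m_t + a_t * (x_dna - xbar) +
        matrix(rnorm(length(active_idx) * nrow(ferm), 0, sig_e),
               length(active_idx), nrow(ferm))
      shares_active[, , t] <- pmax(y, 1e-8)
    }
  }

  # --- gene setup ---------------------------------------------------------
  n_genes <- cfg$n_genes
  genes <- .allocate_genes(n_genes, species[active_idx])
  truth <- list(
    active_taxa = data.frame(
      feature_id = rownames(fungal$counts)[active_idx],
      species = species[active_idx], stringsAsFactors = FALSE),
    site_genes = character(0),
    null_genes = genes$gene_id,
    gene_organism = setNames(genes$organism, genes$gene_id)
  )
  tables <- vector("list", n_tp)
  names(tables) <- paste0("h", cfg$timepoints_hours)
  if (n_genes == 0) {
    for (t in seq_len(n_tp)) {
      sample_ids <- sprintf("rna_%s_h%s", ferm$fermentation_id,
                            cfg$timepoints_hours[t])
      tables[[t]] <- count_table(
        matrix(0L, 0, nrow(ferm), dimnames = list(NULL, sample_ids)),
        "mRNA", organism = character(0))
    }
    attr(tables, "truth") <- truth
    return(tables)
  }

  base_w <- rnorm(n_genes, 0, 1)
  n_site_genes <- min(cfg$n_site_genes, sum(genes$organism == genes$inoculant))
  site_gene_idx <- which(genes$organism == genes$inoculant)[seq_len(n_site_genes)]
  sites <- des$sites$site
  site_region <- des$sites$region
  eff <- matrix(0, n_genes, length(sites), dimnames = list(NULL, sites))
  if (n_site_genes > 0 && cfg$gene_effect_sd > 0) {
    for (g in site_gene_idx) {
      reg_part <- rnorm(length(unique(site_region)), 0, 1)
      names(reg_part) <- unique(site_region)
      raw <- sqrt(0.5) * reg_part[site_region] + sqrt(0.5) * rnorm(length(sites))
      # rescale so every planted gene carries the full configured effect size
      raw <- raw - mean(raw)
      s <- sd(raw)
      eff[g, ] <- if (s > 0) raw / s * cfg$gene_effect_sd else 0
    }
    truth$site_genes <- genes$gene_id[site_gene_idx]
    truth$null_genes <- setdiff(genes$gene_id, truth$site_genes)
  }
  traj <- rnorm(n_genes, 0, 0.5)
  zt <- as.numeric(scale(log(cfg$timepoints_hours)))
  if (any(is.na(zt))) zt <- rep(0, n_tp)

  org_of_active <- genes$organism %in% species[active_idx]
  for (t in seq_len(n_tp)) {
    sample_ids <- sprintf("rna_%s_h%s", ferm$fermentation_id,
                          cfg$timepoints_hours[t])
    counts <- matrix(0L, n_genes, nrow(ferm),
                     dimnames = list(genes$gene_id, sample_ids))
    for (j in seq_len(nrow(ferm))) {
      share <- numeric(n_genes)
      org_share <- c(setNames(cfg$inoculant_share, genes$inoculant),
                     setNames(cfg$grape_share, genes$grape))
      if (length(active_idx) > 0) {
        sh <- shares_active[, j, t]
        tot <- sum(sh)
        # keep the inoculant majority even if noise inflates the active slice
        if (tot > active_slice * 2) sh <- sh * (active_slice * 2) / tot
        org_share[species[active_idx]] <- sh
        org_share[genes$inoculant] <- 1 - sum(sh) - cfg$grape_share
      } else {
        org_share[genes$inoculant] <- 1 - cfg$grape_share
      }
      lw <- base_w + eff[, ferm$site[j]] + traj * zt[t] +
        rnorm(n_genes, 0, cfg$gene_noise_sd)
      for (org in names(org_share)) {
        gi <- which(genes$organism == org)
        if (length(gi) == 0) next
        pw <- exp(lw[gi] - max(lw[gi]))
        share[gi] <- org_share[[org]] * pw / sum(pw)
      }
      share <- share / sum(share)
      depth <- max(1L, rpois(1, cfg$library_size_rna))
      counts[, j] <- rmultinom(1, depth, share)[, 1]
    }
    tables[[t]] <- count_table(counts, "mRNA", organism = genes$organism)
  }
  attr(tables, "truth") <- truth
  tables
}

# Assign genes to organisms: ~10% grape, 3 genes per active taxon, the rest
# to the inoculant strain.
.allocate_genes <- function(n_genes, active_species) {
  inoculant <- "Saccharomyces cerevisiae"
  grape <- "Vitis vinifera"
  if (n_genes == 0)
    return(list(gene_id = character(0), organism = character(0),
                inoculant = inoculant, grape = grape))
  active_species <- setdiff(active_species, inoculant)
  n_grape <- max(1L, round(0.1 * n_genes))
  n_per_active <- if (length(active_species) > 0) 3L else 0L
  n_active_total <- min(n_per_active * length(active_species),
                        max(0L, n_genes - n_grape - 1L))
  n_ino <- n_genes - n_grape - n_active_total
  if (n_ino < 1) { n_ino <- 1L; n_grape <- n_genes - n_ino - n_active_total }
  organism <- c(rep(inoculant, n_ino), rep(grape, n_grape),
                rep(active_species,
                    length.out = n_active_total))
  gene_id <- character(n_genes)
  gene_id[organism == inoculant] <- sprintf("SC_G%04d", seq_len(n_ino))
  gene_id[organism == grape] <- sprintf("VV_G%04d", seq_len(n_grape))
  oth <- which(!organism %in% c(inoculant, grape))
  if (length(oth) > 0) {
    ab <- abbreviate(gsub(" ", "_", organism[oth]), 6)
    gene_id[oth] <- sprintf("%s_G%04d", toupper(ab), seq_along(oth))
  }
  list(gene_id = gene_id, organism = organism,
       inoculant = inoculant, grape = grape)
}
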