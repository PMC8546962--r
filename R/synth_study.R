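#' Generate a complete synthetic study
#'
#' Runs all sub-generators ([generate_community_counts()] for 16S and ITS,
#' [generate_expression_timeseries()], [generate_environment()]) under the
#' configured design and assembles one coherent study object: count tables,
#' a single sample-metadata table covering every DNA and RNA sample, and a
#' ground-truth record (which fungal taxa are transcriptionally active,
#' which genes carry planted site effects) sufficient to score signature
#' recovery without inspecting generator internals.  Deterministic given
#' `cfg$seed`: module sub-streams are derived from the master seed by fixed
#' offsets, so every component is independently reproducible.
#'
#' @param cfg a [scenario_config()].
#' @return an object of class `synthetic_study` with elements `config`,
#'   `metadata`, `bacterial`, `fungal`, `transcripts` (named list of
#'   per-timepoint tables), `environment`, `truth`.
#' @export
generate_study <- function(cfg) {
  validate_scenario_config(cfg)
  des <- study_design(cfg)
  env <- generate_environment(cfg)
  bacterial <- generate_community_counts(cfg, "16S")
  fungal <- generate_community_counts(cfg, "ITS")
  transcripts <- generate_expression_timeseries(cfg, fungal)
  truth <- attr(transcripts, "truth")
  attr(transcripts, "truth") <- NULL

  # per-fermentation chemistry noise shared by the DNA sample and every RNA
  # timepoint of the same tank (chemistry describes the must, not the read-out)
  set.seed(.substream(cfg$seed, "design"))
  dna <- des$dna
  dna$fermentation_id <- sprintf("%s_%s_%s", dna$site, dna$vintage, dna$tank)
  ferm_all <- unique(rbind(
    dna[, c("fermentation_id", "site", "region", "vintage", "tank")],
    des$fermentations[, c("fermentation_id", "site", "region", "vintage", "tank")]
  ))
  chem_cols <- c("pH", "titratable_acidity", "malic_acid", "NOPA", "NH3")
  chem_sd <- c(pH = 0.03, titratable_acidity = 0.25, malic_acid = 0.2,
               NOPA = 10, NH3 = 5)
  key_sv <- paste(env$covariates$site, env$covariates$vintage)
  chem <- env$covariates[match(paste(ferm_all$site, ferm_all$vintage), key_sv),
                         chem_cols, drop = FALSE]
  for (cc in chem_cols)
    chem[[cc]] <- chem[[cc]] + rnorm(nrow(ferm_all), 0, chem_sd[[cc]])
  rownames(chem) <- ferm_all$fermentation_id

  site_cols <- c("latitude_deg", "longitude_deg")
  site_geo <- env$sites[match(ferm_all$site, env$sites$site), site_cols]
  clim <- env$covariates[match(paste(ferm_all$site, ferm_all$vintage), key_sv),
                         c("precipitation_mm", "gdd")]

  ferm_meta <- cbind(ferm_all, chem, site_geo, clim)
  rownames(ferm_meta) <- ferm_meta$fermentation_id

  meta_dna <- data.frame(
    sample_id = dna$sample_id, assay = "DNA",
    ferm_meta[dna$fermentation_id, setdiff(names(ferm_meta), "fermentation_id")],
    fermentation_id = dna$fermentation_id,
    timepoint_hours = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  rna_rows <- list()
  for (t in cfg$timepoints_hours) {
    fm <- des$fermentations
    rna_rows[[as.character(t)]] <- data.frame(
      sample_id = sprintf("rna_%s_h%s", fm$fermentation_id, t), assay = "RNA",
      ferm_meta[fm$fermentation_id, setdiff(names(ferm_meta), "fermentation_id")],
      fermentation_id = fm$fermentation_id,
      timepoint_hours = as.numeric(t),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  metadata <- rbind(meta_dna, do.call(rbind, rna_rows))
  rownames(metadata) <- NULL
  validate_metadata(metadata)

  study <- structure(
    list(config = cfg, metadata = metadata, bacterial = bacterial,
         fungal = fungal, transcripts = transcripts, environment = env,
         truth = truth),
    class = "synthetic_study"
  )
  validate_study(study)
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic_study: %d DNA samples, %d fermentations x %d timepoints (RNA)\n",
    "  bacterial: %d taxa; fungal: %d taxa; genes: %d; active taxa: %d; planted site genes: %d\n"),
    sum(x$metadata$assay == "DNA"),
    length(unique(x$metadata$fermentation_id[x$metadata$assay == "RNA"])),
    length(x$transcripts),
    nrow(x$bacterial$counts), nrow(x$fungal$counts),
    if (length(x$transcripts)) nrow(x$transcripts[[1]]$counts) else 0,
    nrow(x$truth$active_taxa), length(x$truth$site_genes)))
  invisible(x)
}

#' Validate a synthetic study's cross-references
#'
#' Every sample in every count table must appear in the metadata, and the
#' truth record's feature lists must be subsets of the generated feature ids.
#'
#' @param study a `synthetic_study`.
#' @return `study`, invisibly.
#' @export
validate_study <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  ids <- study$metadata$sample_id
  for (tab in c(list(study$bacterial, study$fungal), study$transcripts)) {
    miss <- setdiff(colnames(tab$counts), ids)
    if (length(miss) > 0)
      .stopf("sample '%s' missing from metadata", miss[1])
  }
  if (length(study$transcripts) > 0) {
    gene_ids <- rownames(study$transcripts[[1]]$counts)
    if (!all(study$truth$site_genes %in% gene_ids))
      .stopf("truth site_genes are not a subset of gene ids")
  }
  if (!all(study$truth$active_taxa$feature_id %in%
           rownames(study$fungal$counts)))
    .stopf("truth active taxa are not a subset of fungal feature ids")
  invisible(study)
}

#' Write a synthetic study to a directory
#'
#' Writes the count tables and metadata as TSV, the configuration as YAML,
#' and the truth record as JSON.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return character vector of written file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    bacterial = file.path(dir, "bacterial_16S.tsv"),
    fungal = file.path(dir, "fungal_ITS.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    config = file.path(dir, "scenario.yaml"),
    truth = file.path(dir, "truth.json")
  )
  write_count_table(study$bacterial, paths[["bacterial"]])
  write_count_table(study$fungal, paths[["fungal"]])
  write_metadata(study$metadata, paths[["metadata"]])
  for (nm in names(study$transcripts)) {
    p <- file.path(dir, sprintf("transcripts_%s.tsv", nm))
    write_count_table(study$transcripts[[nm]], p)
    paths[[paste0("transcripts_", nm)]] <- p
  }
  cfg <- study$config
  cfg_list <- unclass(cfg)
  cfg_list <- lapply(cfg_list, function(v) if (is.null(v)) NULL else v)
  yaml::write_yaml(cfg_list, paths[["config"]])
  jsonlite::write_json(study$truth, paths[["truth"]],
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(paths)
}
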