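#' Match taxa between DNA and RNA assays
#'
#' Pairs DNA features (ITS ASVs with species-level taxonomy where resolvable)
#' with RNA features (organism labels) on the normalized binomial species
#' name: lower case, abbreviation dots stripped, whitespace collapsed.  DNA
#' features resolved only to genus are not matched at species level but are
#' reported as genus-level candidates when an RNA organism shares the genus.
#'
#' @param dna an ITS [count_table()] with taxonomy.
#' @param rna an mRNA [count_table()] with organism labels (or a list of
#'   per-timepoint tables, in which case the first is used — organism sets
#'   are constant across timepoints).
#' @return list with data frame `matched` (dna feature, species, organism),
#'   `dna_only`, `rna_only`, and `genus_candidates`.
#' @export
match_taxa <- function(dna, rna) {
  if (is.list(rna) && !inherits(rna, "count_table")) rna <- rna[[1]]
  stopifnot(inherits(dna, "count_table"), inherits(rna, "count_table"))
  if (is.null(dna$taxonomy)) .stopf("DNA table has no taxonomy")
  if (is.null(rna$organism)) .stopf("RNA table has no organism labels")
  dna_last <- vapply(strsplit(normalize_lineage(dna$taxonomy), ","),
                     function(x) x[length(x)], "")
  dna_norm <- normalize_species(dna_last)
  dna_is_species <- vapply(strsplit(dna_norm, " "), length, 0L) >= 2
  rna_orgs <- unique(rna$organism)
  rna_norm <- normalize_species(rna_orgs)
  matched_idx <- which(dna_is_species & dna_norm %in% rna_norm)
  matched <- data.frame(
    feature_id = rownames(dna$counts)[matched_idx],
    species = dna_norm[matched_idx],
    organism = rna_orgs[match(dna_norm[matched_idx], rna_norm)],
    stringsAsFactors = FALSE
  )
  dna_only <- setdiff(unique(dna_norm[dna_is_species]), matched$species)
  rna_only <- rna_orgs[!rna_norm %in% dna_norm[dna_is_species]]
  genus_rna <- vapply(strsplit(rna_norm, " "), `[`, "", 1)
  genus_dna <- vapply(strsplit(dna_norm, " "), `[`, "", 1)
  cand <- which(!dna_is_species & genus_dna %in% genus_rna)
  genus_candidates <- data.frame(
    feature_id = rownames(dna$counts)[cand],
    genus = genus_dna[cand],
    stringsAsFactors = FALSE
  )
  list(matched = matched, dna_only = dna_only, rna_only = rna_only,
       genus_candidates = genus_candidates)
}

#' @noRd
normalize_species <- function(x) {
  x <- tolower(x)
  x <- gsub(".", "", x, fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Regress RNA relative abundance on DNA relative abundance
#'
#' For one organism at one timepoint, ordinary least squares of the
#' organism's RNA relative abundance (organism transcript counts over total
#' reads) on its DNA relative abundance in the paired pre-inoculation must
#' sample, across fermentations.  Counts are transformed to relative
#' abundances before regression.  Reports slope, intercept, adjusted R2
#' (which may be negative), and the slope p-value.
#'
#' @param dna an ITS [count_table()].
#' @param rna_timepoint an mRNA [count_table()] for one timepoint.
#' @param metadata study metadata (maps samples to fermentations; DNA and RNA
#'   samples of the same tank share a `fermentation_id`).
#' @param organism organism label as used in the RNA table.
#' @param dna_feature the DNA feature id to use for the organism (defaults to
#'   the feature matched by [match_taxa()]).
#' @param timepoint_hours timepoint annotation carried into the result.
#' @return an object of class `concordance_result` (also a one-row data
#'   frame): organism, timepoint, n fermentations, slope, intercept,
#'   adjusted R2, p-value, flag.
#' @export
regress_dna_rna <- function(dna, rna_timepoint, metadata, organism,
                            dna_feature = NULL, timepoint_hours = NA) {
  stopifnot(inherits(dna, "count_table"), inherits(rna_timepoint, "count_table"))
  if (is.null(dna_feature)) {
    mt <- match_taxa(dna, rna_timepoint)
    hit <- mt$matched[mt$matched$organism == organism, , drop = FALSE]
    if (nrow(hit) == 0)
      .stopf("organism '%s' has no species-level DNA match", organism)
    dna_feature <- hit$feature_id[1]
  }
  rel_dna <- relative_abundance(dna)[dna_feature, ]
  rel_rna_all <- relative_abundance(rna_timepoint)
  org_rows <- which(rna_timepoint$organism == organism)
  if (length(org_rows) == 0) .stopf("organism '%s' absent from RNA table", organism)
  rel_rna <- colSums(rel_rna_all[org_rows, , drop = FALSE])

  md <- metadata
  dna_ferm <- md$fermentation_id[match(names(rel_dna), md$sample_id)]
  rna_ferm <- md$fermentation_id[match(names(rel_rna), md$sample_id)]
  common <- intersect(dna_ferm[!is.na(dna_ferm)], rna_ferm[!is.na(rna_ferm)])
  if (length(common) < 3)
    .stopf("need >= 3 fermentations with both assays, have %d", length(common))
  x <- rel_dna[match(common, dna_ferm)]
  y <- rel_rna[match(common, rna_ferm)]
  flag <- NULL
  if (sd(x) == 0) {
    res <- data.frame(organism = organism, timepoint_hours = timepoint_hours,
                      n_fermentations = length(common), slope = NA_real_,
                      intercept = mean(y), r_squared = NA_real_,
                      p_value = NA_real_, flag = "zero_variance_predictor",
                      stringsAsFactors = FALSE)
    class(res) <- c("concordance_result", class(res))
    return(res)
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  res <- data.frame(
    organism = organism, timepoint_hours = timepoint_hours,
    n_fermentations = length(common),
    slope = coef(fit)[["x"]], intercept = coef(fit)[["(Intercept)"]],
    r_squared = sm$adj.r.squared,
    p_value = sm$coefficients["x", "Pr(>|t|)"],
    flag = NA_character_, stringsAsFactors = FALSE
  )
  class(res) <- c("concordance_result", class(res))
  res
}

#' Concordance over organisms and timepoints
#'
#' Convenience wrapper running [regress_dna_rna()] for each matched organism
#' at each timepoint of a study's transcript tables.
#'
#' @param dna ITS [count_table()].
#' @param transcripts named list of per-timepoint mRNA tables (names like
#'   `"h2"`).
#' @param metadata study metadata.
#' @param organisms organisms to test (default: all species-level matches).
#' @return data frame with one row per organism x timepoint.
#' @export
concordance_table <- function(dna, transcripts, metadata, organisms = NULL) {
  mt <- match_taxa(dna, transcripts)
  if (is.null(organisms)) organisms <- unique(mt$matched$organism)
  rows <- list()
  for (nm in names(transcripts)) {
    tp <- as.numeric(sub("^h", "", nm))
    for (org in organisms) {
      rows[[paste(nm, org)]] <- regress_dna_rna(
        dna, transcripts[[nm]], metadata, org, timepoint_hours = tp)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detection overlap between assays
#'
#' Which species are detected by DNA profiling, by RNA profiling, or both.
#' Detection means a count above `abundance_floor` (on relative abundance) in
#' at least one sample of the assay.
#'
#' @param dna ITS [count_table()].
#' @param rna mRNA [count_table()] or list of per-timepoint tables (pooled).
#' @param abundance_floor minimum within-sample relative abundance counted as
#'   detection (default 0: any nonzero count).
#' @return list with counts `n_shared`, `n_dna_only`, `n_rna_only` and the
#'   corresponding species sets.
#' @export
detection_overlap <- function(dna, rna, abundance_floor = 0) {
  if (is.list(rna) && !inherits(rna, "count_table")) {
    counts <- do.call(cbind, lapply(rna, function(t) t$counts))
    rna <- count_table(counts, "mRNA", organism = rna[[1]]$organism,
                       sample_ids = make.unique(colnames(counts)))
  }
  detect <- function(tab, labels) {
    if (nrow(tab$counts) == 0) return(character(0))
    rel <- relative_abundance(tab$counts[, colSums(tab$counts) > 0, drop = FALSE])
    hit <- apply(rel, 1, function(r) any(r > abundance_floor & r > 0))
    unique(labels[hit])
  }
  dna_last <- vapply(strsplit(normalize_lineage(dna$taxonomy), ","),
                     function(x) x[length(x)], "")
  dna_sp <- normalize_species(dna_last)
  keep <- vapply(strsplit(dna_sp, " "), length, 0L) >= 2
  dna_det <- detect(dna, ifelse(keep, dna_sp, NA))
  dna_det <- dna_det[!is.na(dna_det)]
  rna_det <- detect(rna, normalize_species(rna$organism))
  shared <- intersect(dna_det, rna_det)
  list(n_shared = length(shared),
       n_dna_only = length(setdiff(dna_det, rna_det)),
       n_rna_only = length(setdiff(rna_det, dna_det)),
       shared = shared,
       dna_only = setdiff(dna_det, rna_det),
       rna_only = setdiff(rna_det, dna_det))
}
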