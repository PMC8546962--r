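#' Sample metadata
#'
#' Per-sample design labels and covariates: `sample_id`, `site`, `region`,
#' `vintage`, `tank`, optional `timepoint_hours`, must chemistry (`pH`,
#' `titratable_acidity`, `malic_acid`, `NOPA`, `NH3`) and environment
#' (`precipitation_mm`, `gdd`, `latitude_deg`, `longitude_deg`).  Stored as a
#' plain data frame; `validate_metadata()` checks the design invariants:
#' each site belongs to exactly one region, and (site, vintage, tank
#' \[, timepoint\]) identifies a sample uniquely.
#'
#' @param meta a data frame with at least `sample_id`, `site`, `region`,
#'   `vintage`, `tank`.
#' @return `meta`, invisibly, if valid.
#' @export
validate_metadata <- function(meta) {
  need <- c("sample_id", "site", "region", "vintage", "tank")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0)
    .stopf("metadata missing column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    .stopf("duplicate sample_id: '%s'",
           meta$sample_id[duplicated(meta$sample_id)][1])
  s2r <- unique(meta[, c("site", "region")])
  if (anyDuplicated(s2r$site))
    .stopf("site '%s' maps to more than one region",
           s2r$site[duplicated(s2r$site)][1])
  key <- paste(meta$site, meta$vintage, meta$tank,
               if ("timepoint_hours" %in% names(meta)) meta$timepoint_hours else "")
  if ("assay" %in% names(meta)) key <- paste(key, meta$assay)
  if (anyDuplicated(key))
    .stopf("(site, vintage, tank, timepoint) does not uniquely identify samples")
  invisible(meta)
}

#' Read / write sample metadata as TSV
#' @param path file path.
#' @return `read_metadata` returns a validated metadata data frame.
#' @export
read_metadata <- function(path) {
  meta <- read.delim(path, check.names = FALSE, quote = "",
                     stringsAsFactors = FALSE)
  validate_metadata(meta)
  meta
}

#' @param meta metadata data frame.
#' @rdname read_metadata
#' @export
write_metadata <- function(meta, path) {
  validate_metadata(meta)
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a count table and metadata on their common samples
#'
#' Restricts both objects to the intersection of their sample ids, in a single
#' consistent order (the table's order filtered to the intersection).  Samples
#' present on only one side are reported via `message()`.
#'
#' @param x a `count_table`.
#' @param meta a metadata data frame.
#' @return `list(table = , metadata = )` with identical sample order.
#' @export
align_samples <- function(x, meta) {
  validate_count_table(x)
  validate_metadata(meta)
  common <- intersect(colnames(x$counts), meta$sample_id)
  if (length(common) == 0L)
    .stopf("no samples shared between count table and metadata")
  drop_tab <- setdiff(colnames(x$counts), common)
  drop_meta <- setdiff(meta$sample_id, common)
  if (length(drop_tab) > 0)
    message(sprintf("align_samples: %d table sample(s) absent from metadata",
                    length(drop_tab)))
  if (length(drop_meta) > 0)
    message(sprintf("align_samples: %d metadata sample(s) absent from table",
                    length(drop_meta)))
  ord <- colnames(x$counts)[colnames(x$counts) %in% common]
  out <- subset_samples(x, ord)
  meta2 <- meta[match(ord, meta$sample_id), , drop = FALSE]
  rownames(meta2) <- NULL
  list(table = out, metadata = meta2)
}
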