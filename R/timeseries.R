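#' Summarize transcript time series per fermentation
#'
#' Random forests expect independent rows, but fermentation transcriptomes
#' are time series.  Each gene's library-size-normalized counts across a
#' fermentation's timepoints are therefore collapsed to five attributes:
#' mean, minimum, maximum, total, and standard deviation (sample sd, n-1
#' denominator).  Genes absent at a timepoint contribute 0 at that timepoint.
#' Features are named `<gene>|<attribute>`.
#'
#' @param transcripts named list of per-timepoint mRNA [count_table()]s.
#' @param metadata study metadata mapping RNA samples to fermentations.
#' @return an object of class `fermentation_features`: `x` (fermentations x
#'   gene-attribute matrix), `gene` and `attribute` per column, `organism`
#'   per gene, `fermentations` (site/region/vintage/tank per row).
#' @export
summarize_timeseries <- function(transcripts, metadata) {
  if (length(transcripts) == 0 || nrow(transcripts[[1]]$counts) == 0)
    .stopf("no transcript features: cannot build fermentation features")
  genes <- rownames(transcripts[[1]]$counts)
  organism <- transcripts[[1]]$organism
  norm <- lapply(transcripts, function(tab) {
    stopifnot(identical(rownames(tab$counts), genes))
    relative_abundance(tab)
  })
  all_samples <- unlist(lapply(norm, colnames), use.names = FALSE)
  ferm_of <- metadata$fermentation_id[match(all_samples, metadata$sample_id)]
  if (anyNA(ferm_of)) .stopf("RNA sample missing from metadata")
  ferms <- unique(ferm_of)
  n_tp_per <- table(ferm_of)
  if (any(n_tp_per < 2))
    .stopf("fermentation '%s' has a single timepoint: sd undefined",
           names(n_tp_per)[n_tp_per < 2][1])
  attrs <- c("mean", "min", "max", "total", "sd")
  x <- matrix(0, length(ferms), length(genes) * length(attrs),
              dimnames = list(ferms, paste(rep(genes, each = length(attrs)),
                                           rep(attrs, length(genes)),
                                           sep = "|")))
  flat <- do.call(cbind, norm)  # genes x (samples over all timepoints)
  colnames(flat) <- all_samples
  for (f in ferms) {
    v <- flat[, ferm_of == f, drop = FALSE]
    s <- cbind(rowMeans(v), apply(v, 1, min), apply(v, 1, max),
               rowSums(v), apply(v, 1, sd))
    x[f, ] <- as.numeric(t(s))
  }
  md <- metadata[metadata$fermentation_id %in% ferms &
                   metadata$assay == "RNA", , drop = FALSE]
  fm <- unique(md[, c("fermentation_id", "site", "region", "vintage", "tank")])
  fm <- fm[match(ferms, fm$fermentation_id), , drop = FALSE]
  rownames(fm) <- NULL
  structure(list(
    x = x,
    gene = rep(genes, each = length(attrs)),
    attribute = rep(attrs, length(genes)),
    organism = if (is.null(organism)) NULL else setNames(organism, genes),
    fermentations = fm
  ), class = "fermentation_features")
}

#' @export
print.fermentation_features <- function(x, ...) {
  cat(sprintf("fermentation_features: %d fermentations x %d features (%d genes x 5 attributes)\n",
              nrow(x$x), ncol(x$x), length(unique(x$gene))))
  invisible(x)
}
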