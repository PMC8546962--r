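#' Feature-by-sample count tables
#'
#' A `count_table` holds a non-negative integer matrix of marker-gene (16S or
#' ITS amplicon sequence variants) or transcript (mRNA) counts with features in
#' rows and samples in columns, together with optional per-feature taxonomy
#' strings (semicolon-delimited ranks) and organism labels.  This is the single
#' container every statistical stage accepts; constructors validate dimensions,
#' uniqueness of identifiers, and integrality of counts.
#'
#' @param counts numeric matrix, features x samples; must be non-negative
#'   integers.  Row and column names are used as feature and sample ids unless
#'   `feature_ids` / `sample_ids` are given.
#' @param marker one of `"16S"`, `"ITS"`, `"mRNA"`.
#' @param taxonomy optional character vector, one semicolon- (or comma-)
#'   delimited lineage per feature.
#' @param organism optional character vector, one organism label per feature
#'   (used for mRNA tables).
#' @param feature_ids,sample_ids optional explicit identifiers.
#'
#' @return an object of class `count_table` with elements `counts`, `marker`,
#'   `taxonomy`, `organism`.
#' @export
count_table <- function(counts, marker, taxonomy = NULL, organism = NULL,
                        feature_ids = NULL, sample_ids = NULL) {
  marker <- match_marker(marker)
  counts <- as.matrix(counts)
  if (!is.null(feature_ids)) rownames(counts) <- feature_ids
  if (!is.null(sample_ids)) colnames(counts) <- sample_ids
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("f%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%04d", seq_len(ncol(counts)))
  x <- structure(
    list(counts = counts, marker = marker,
         taxonomy = taxonomy, organism = organism),
    class = "count_table"
  )
  validate_count_table(x)
  x
}

match_marker <- function(marker) {
  ok <- c("16S", "ITS", "mRNA")
  if (length(marker) != 1L || !marker %in% ok)
    .stopf("invalid marker '%s': must be one of %s",
           paste(marker, collapse = ","), paste(ok, collapse = ", "))
  marker
}

#' Validate a count table
#'
#' Checks the invariants every downstream module relies on: integral
#' non-negative counts, unique feature and sample ids, and annotation vectors
#' matching the number of features.  Called by the constructor and the reader;
#' exported so user-supplied objects can be checked explicitly.
#'
#' @param x a `count_table`.
#' @return `x`, invisibly, if valid; otherwise an error naming the offending
#'   row or column.
#' @export
validate_count_table <- function(x) {
  stopifnot(inherits(x, "count_table"))
  m <- x$counts
  if (!is.numeric(m)) .stopf("counts must be numeric")
  if (anyNA(m)) .stopf("counts contain missing values")
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    .stopf("negative count for feature '%s' in sample '%s'",
           rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]])
  nonint <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(nonint) > 0)
    .stopf("non-integer count for feature '%s' in sample '%s'",
           rownames(m)[nonint[1, 1]], colnames(m)[nonint[1, 2]])
  if (anyDuplicated(rownames(m)))
    .stopf("duplicate feature id: '%s'", rownames(m)[duplicated(rownames(m))][1])
  if (anyDuplicated(colnames(m)))
    .stopf("duplicate sample id: '%s'", colnames(m)[duplicated(colnames(m))][1])
  for (ann in c("taxonomy", "organism")) {
    if (!is.null(x[[ann]]) && length(x[[ann]]) != nrow(m))
      .stopf("%s must have one entry per feature (%d != %d)",
             ann, length(x[[ann]]), nrow(m))
  }
  invisible(x)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table [%s]: %d features x %d samples; taxonomy: %s; organism: %s\n",
              x$marker, nrow(x$counts), ncol(x$counts),
              if (is.null(x$taxonomy)) "no" else "yes",
              if (is.null(x$organism)) "no" else "yes"))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read / write count tables as TSV
#'
#' On disk a count table is tab-separated text with features in rows and
#' samples in columns: first column `feature_id`, optional `taxonomy` and
#' `organism` columns, then one column of integer counts per sample.
#' `read_count_table(write_count_table(x, path), marker)` is the identity.
#'
#' @param path file path.
#' @param marker marker kind of the table being read (`"16S"`, `"ITS"`,
#'   `"mRNA"`).
#' @return `read_count_table` returns a validated [count_table()];
#'   `write_count_table` returns `path` invisibly.
#' @export
read_count_table <- function(path, marker) {
  marker <- match_marker(marker)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    .stopf("ragged TSV '%s': rows have %s fields", path,
           paste(unique(nf), collapse = "/"))
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   quote = "")
  if (names(df)[1] != "feature_id")
    .stopf("first column of '%s' must be 'feature_id'", path)
  taxonomy <- if ("taxonomy" %in% names(df)) df$taxonomy else NULL
  organism <- if ("organism" %in% names(df)) df$organism else NULL
  samp_cols <- setdiff(names(df), c("feature_id", "taxonomy", "organism"))
  if (length(samp_cols) == 0L) .stopf("no sample columns in '%s'", path)
  m <- suppressWarnings(
    vapply(df[samp_cols], as.numeric, numeric(nrow(df)))
  )
  m <- matrix(m, nrow = nrow(df),
              dimnames = list(df$feature_id, samp_cols))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    .stopf("non-numeric count for feature '%s' in sample '%s'",
           rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]])
  }
  count_table(m, marker, taxonomy = taxonomy, organism = organism)
}

#' @param x a `count_table`.
#' @rdname read_count_table
#' @export
write_count_table <- function(x, path) {
  validate_count_table(x)
  df <- data.frame(feature_id = rownames(x$counts),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(x$taxonomy)) df$taxonomy <- x$taxonomy
  if (!is.null(x$organism)) df$organism <- x$organism
  df <- cbind(df, as.data.frame(x$counts, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Organelle 16S lineages carried by plant material rather than bacteria.
# Matching is a case-sensitive prefix match on the comma-normalized lineage.
.organelle_prefixes <- c(
  "Bacteria,Cyanobacteria,Cyanobacteriia,Chloroplast",
  "Bacteria,Proteobacteria,Alphaproteobacteria,Rickettsiales,Mitochondria"
)

normalize_lineage <- function(lineage) {
  x <- gsub(";", ",", lineage, fixed = TRUE)
  x <- gsub("[[:space:]]*,[[:space:]]*", ",", x)
  trimws(x)
}

#' Remove organelle-derived 16S ASVs
#'
#' Grape must contains plant chloroplast and mitochondrial 16S sequences that
#' amplify alongside bacterial rDNA.  Features whose (comma- or semicolon-
#' delimited) taxonomy begins with the chloroplast lineage
#' `Bacteria,Cyanobacteria,Cyanobacteriia,Chloroplast` or the mitochondrial
#' lineage `Bacteria,Proteobacteria,Alphaproteobacteria,Rickettsiales,Mitochondria`
#' are removed before any statistics.  All other features are untouched.
#'
#' @param x a 16S `count_table` with taxonomy.
#' @return the filtered `count_table`; the number of removed features is
#'   attached as attribute `"n_removed"` and reported via `message()`.
#' @export
filter_organelle_asvs <- function(x) {
  validate_count_table(x)
  if (is.null(x$taxonomy))
    .stopf("organelle filtering requires taxonomy annotation")
  lin <- normalize_lineage(x$taxonomy)
  hit <- Reduce(`|`, lapply(.organelle_prefixes, function(p) startsWith(lin, p)))
  out <- x
  out$counts <- x$counts[!hit, , drop = FALSE]
  out$taxonomy <- x$taxonomy[!hit]
  if (!is.null(x$organism)) out$organism <- x$organism[!hit]
  attr(out, "n_removed") <- sum(hit)
  if (all(hit)) .warnf("all %d features matched organelle lineages", sum(hit))
  message(sprintf("filter_organelle_asvs: removed %d of %d features",
                  sum(hit), length(hit)))
  out
}

#' Subset a count table to given samples (internal convenience)
#' @noRd
subset_samples <- function(x, sample_ids) {
  out <- x
  out$counts <- x$counts[, sample_ids, drop = FALSE]
  out
}
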