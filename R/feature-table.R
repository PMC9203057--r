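#' Construct an ASV feature table
#'
#' A feature table is the pipeline's universal currency: a non-negative
#' integer count matrix with samples as rows and ASVs (amplicon sequence
#' variants) as columns, optionally annotated with per-ASV taxonomy labels.
#'
#' @param counts numeric matrix of non-negative integer counts, samples in
#'   rows, ASVs in columns. Dimnames are used as sample/ASV ids when
#'   `sample_ids`/`asv_ids` are not given.
#' @param sample_ids character vector of unique sample identifiers.
#' @param asv_ids character vector of unique ASV identifiers.
#' @param taxonomy optional named character vector mapping ASV ids to
#'   taxonomic label strings.
#' @return An object of class `feature_table`: a list with elements
#'   `counts` (integer matrix with dimnames), and `taxonomy` (or `NULL`).
#' @examples
#' ft <- feature_table(matrix(c(3, 0, 1, 2), 2, byrow = TRUE,
#'                            dimnames = list(c("s1", "s2"), c("a1", "a2"))))
#' sample_depths(ft)
#' @export
feature_table <- function(counts, sample_ids = rownames(counts),
                          asv_ids = colnames(counts), taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(asv_ids))
    stop("counts must carry sample and ASV identifiers", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(asv_ids))
    stop("duplicate ASV ids: ",
         paste(unique(asv_ids[duplicated(asv_ids)]), collapse = ", "),
         call. = FALSE)
  if (length(sample_ids) != nrow(counts) || length(asv_ids) != ncol(counts))
    stop("id lengths do not match count matrix dimensions", call. = FALSE)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing", call. = FALSE)
  if (any(counts != round(counts)))
    stop("counts must be integral (use round = TRUE when reading)",
         call. = FALSE)
  storage.mode(counts) <- "double"   # doubles hold integral counts > .Machine$integer.max
  dimnames(counts) <- list(as.character(sample_ids), as.character(asv_ids))
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[intersect(names(taxonomy), asv_ids)]
    if (length(taxonomy) == 0L) taxonomy <- NULL
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d ASVs\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  total reads: %s; depth range: %s-%s\n",
              format(sum(x$counts), big.mark = ","),
              min(sample_depths(x)), max(sample_depths(x))))
  if (!is.null(x$taxonomy))
    cat(sprintf("  taxonomy labels for %d ASVs\n", length(x$taxonomy)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Sample and ASV identifiers of a feature table
#' @param table a `feature_table`.
#' @return character vector of ids.
#' @export
sample_ids <- function(table) rownames(table$counts)

#' @rdname sample_ids
#' @export
asv_ids <- function(table) colnames(table$counts)

#' Per-sample total read depth
#' @param table a `feature_table`.
#' @return named numeric vector of row sums.
#' @export
sample_depths <- function(table) rowSums(table$counts)

#' Subset a feature table by sample and/or ASV ids
#'
#' @param table a `feature_table`.
#' @param samples sample ids to keep (default all, original order kept).
#' @param asvs ASV ids to keep.
#' @param drop_empty drop ASV columns that are all-zero after subsetting.
#'   Off by default so that ASV id spaces stay aligned across analyses.
#' @return a `feature_table`.
#' @export
subset_samples <- function(table, samples = sample_ids(table),
                           asvs = asv_ids(table), drop_empty = FALSE) {
  missing_s <- setdiff(samples, sample_ids(table))
  if (length(missing_s))
    stop("unknown sample ids: ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  missing_a <- setdiff(asvs, asv_ids(table))
  if (length(missing_a))
    stop("unknown ASV ids: ", paste(missing_a, collapse = ", "),
         call. = FALSE)
  counts <- table$counts[samples, asvs, drop = FALSE]
  if (drop_empty) counts <- counts[, colSums(counts) > 0, drop = FALSE]
  feature_table(counts, taxonomy = table$taxonomy)
}

#' Read a feature table from a tab-delimited file
#'
#' Accepts plain TSV (samples in rows by default) and the BIOM-style TSV
#' orientation with ASVs in rows, flagged by a first header cell of
#' `#ASV_ID` (any `#OTU ID`-style alias beginning with `#` other than
#' `#SampleID` is treated the same way). A first cell of `sample_id` or
#' `#SampleID` marks samples-in-rows explicitly.
#'
#' @param path file path.
#' @param format `"tsv"` (samples in rows) or `"biom-tsv"` (ASVs in rows);
#'   `"auto"` (default) inspects the first header cell.
#' @param round round fractional cells to integers instead of rejecting
#'   them (relative-abundance exports rescaled upstream sometimes carry
#'   float noise).
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path, format = c("auto", "tsv", "biom-tsv"),
                               round = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L,
                          comment.char = "", stringsAsFactors = FALSE)
  first <- header[1]
  asvs_in_rows <- switch(format,
    "tsv" = FALSE,
    "biom-tsv" = TRUE,
    "auto" = startsWith(first, "#") && !identical(first, "#SampleID"))
  mat <- as.matrix(df)
  if (!is.numeric(mat))
    stop("non-numeric cells in ", path, call. = FALSE)
  if (asvs_in_rows) mat <- t(mat)
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat)))
    stop("duplicate identifiers in ", path, call. = FALSE)
  if (any(mat < 0)) stop("negative counts in ", path, call. = FALSE)
  if (round) mat <- base::round(mat)
  feature_table(mat)
}

#' Write a feature table as TSV (samples in rows)
#'
#' @param table a `feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample_id = sample_ids(table), table$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Required columns: `sample_id` (alias `#SampleID`, QIIME mapping-file
#' compatible), `host_species`, `population`, `urban_status`,
#' `source_dataset`. `urban_status` is validated against the closed
#' vocabulary urban / semiurban / rural.
#'
#' @param path TSV file path.
#' @return data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  names(df)[names(df) == "#SampleID"] <- "sample_id"
  validate_metadata(df)
}

#' Validate a sample metadata data.frame
#' @param meta data.frame of per-sample metadata.
#' @return `meta`, with `sample_id` coerced to character, invisibly valid.
#' @export
validate_metadata <- function(meta) {
  required <- c("sample_id", "host_species", "population", "urban_status",
                "source_dataset")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("metadata lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  bad <- setdiff(unique(meta$urban_status), c("urban", "semiurban", "rural"))
  if (length(bad))
    stop("urban_status outside {urban, semiurban, rural}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  meta
}

#' Write sample metadata as TSV
#' @param meta metadata data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Align metadata rows to a table's samples; error if any sample lacks
# exactly one metadata row.
align_metadata <- function(table, meta) {
  meta <- validate_metadata(meta)
  idx <- match(sample_ids(table), meta$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(sample_ids(table)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  meta[idx, , drop = FALSE]
}
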