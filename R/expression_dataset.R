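#' Construct an expression dataset
#'
#' Bundles a gene x sample expression matrix with per-sample metadata
#' (sample id, species, age in years). This is the container every other
#' function in the package operates on.
#'
#' @param values Numeric matrix, genes in rows (unique rownames = gene ids),
#'   samples in columns. Column names must equal `meta$sample_id`, in order.
#' @param meta Data frame with columns `sample_id`, `species`, `age_years`.
#' @param normalized Logical; `TRUE` only if `values` holds rank-uniform
#'   scores in (0, 1) (see [normalize_uniform()]).
#' @param raw Optional numeric matrix with the pre-normalization values;
#'   retained because fold changes must be computed on the raw scale.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values`, `meta`, `normalized` and `raw`.
#' @export
expression_dataset <- function(values, meta, normalized = FALSE, raw = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  needed <- c("sample_id", "species", "age_years")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols)) {
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$species <- as.character(meta$species)
  meta$age_years <- as.numeric(meta$age_years)
  if (nrow(meta) != ncol(values)) {
    stop("metadata rows (", nrow(meta), ") != matrix columns (", ncol(values), ")")
  }
  if (is.null(rownames(values))) stop("`values` must carry gene ids as rownames")
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate gene id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  if (is.null(colnames(values)) || !identical(colnames(values), meta$sample_id)) {
    stop("matrix column names must match meta$sample_id in order")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite with no missing entries")
  }
  if (any(!is.finite(meta$age_years)) || any(meta$age_years < 0)) {
    stop("`age_years` must be finite and >= 0")
  }
  if (normalized && (any(values <= 0) || any(values >= 1))) {
    stop("normalized values must lie strictly in (0, 1)")
  }
  rownames(meta) <- NULL
  structure(
    list(values = values, meta = meta, normalized = normalized, raw = raw),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf(
    "ExpressionDataset: %d genes x %d samples (%s)\n",
    nrow(x$values), ncol(x$values),
    if (x$normalized) "rank-uniform normalized" else "raw"
  ))
  sp <- table(x$meta$species)
  cat("  samples per species:",
      paste(sprintf("%s=%d", names(sp), as.integer(sp)), collapse = ", "), "\n")
  cat(sprintf("  age range: %.3g - %.3g years\n",
              min(x$meta$age_years), max(x$meta$age_years)))
  invisible(x)
}

#' Gene identifiers of a dataset
#' @param ds An `ExpressionDataset`.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(ds) rownames(ds$values)

#' Raw (pre-transformation) expression values
#'
#' Returns the raw matrix: the `raw` slot when the dataset has been
#' normalized or standardized, otherwise `values` itself. Fold changes
#' and ANOVA operate on this scale.
#'
#' @param ds An `ExpressionDataset`.
#' @return Numeric matrix.
#' @export
raw_values <- function(ds) {
  if (!is.null(ds$raw)) ds$raw else ds$values
}

#' Subset the samples of a dataset
#'
#' Keeps the samples at positions `idx` (or with the given sample ids),
#' carrying the metadata and any retained raw matrix along.
#'
#' @param ds An `ExpressionDataset`.
#' @param idx Integer positions or character sample ids.
#' @return The subset `ExpressionDataset`.
#' @export
subset_samples <- function(ds, idx) {
  if (is.character(idx)) {
    idx <- match(idx, ds$meta$sample_id)
    if (anyNA(idx)) stop("unknown sample id(s)")
  }
  ds$values <- ds$values[, idx, drop = FALSE]
  if (!is.null(ds$raw)) ds$raw <- ds$raw[, idx, drop = FALSE]
  ds$meta <- ds$meta[idx, , drop = FALSE]
  rownames(ds$meta) <- NULL
  ds
}
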