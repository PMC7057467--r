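#' Load an expression matrix and sample metadata from disk
#'
#' Reads a tab-separated gene x sample table (first column gene ids, header
#' row sample ids) together with a metadata table holding `sample_id`,
#' `species` and `age_years`. Lines beginning with `!` are skipped, so a
#' GEO series-matrix-style table can be ingested directly. Rows containing
#' missing or non-numeric entries are dropped (and counted in the load
#' report); samples are reordered to ascending age within species.
#'
#' @param matrix_path Path to the TSV expression table.
#' @param meta_path Path to the metadata table (TSV, or CSV if the file name
#'   ends in `.csv`).
#' @param quiet Suppress the load-report messages.
#'
#' @return An [expression_dataset()] with `normalized = FALSE`. The load
#'   report (genes kept/dropped, samples per species) is attached as
#'   attribute `"load_report"`.
#' @export
load_expression <- function(matrix_path, meta_path, quiet = FALSE) {
  if (!file.exists(matrix_path)) stop("expression matrix not found: ", matrix_path)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)

  tab <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           comment.char = "!", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0 || ncol(tab) < 2) stop("expression matrix is empty")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate gene id(s) in matrix: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  vals <- suppressWarnings(
    vapply(tab[-1], function(col) as.numeric(col), numeric(nrow(tab)))
  )
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(tab), dimnames = list(NULL, names(tab)[-1]))
  rownames(vals) <- ids

  meta <- if (grepl("\\.csv$", meta_path, ignore.case = TRUE)) {
    utils::read.csv(meta_path, stringsAsFactors = FALSE)
  } else {
    utils::read.delim(meta_path, sep = "\t", stringsAsFactors = FALSE)
  }
  needed <- c("sample_id", "species", "age_years")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols)) {
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  meta$sample_id <- as.character(meta$sample_id)

  only_matrix <- setdiff(colnames(vals), meta$sample_id)
  only_meta <- setdiff(meta$sample_id, colnames(vals))
  if (length(only_matrix)) {
    stop("sample id(s) in matrix but not metadata: ",
         paste(only_matrix, collapse = ", "))
  }
  if (length(only_meta)) {
    stop("sample id(s) in metadata but not matrix: ",
         paste(only_meta, collapse = ", "))
  }

  bad <- rowSums(!is.finite(vals)) > 0
  n_dropped <- sum(bad)
  vals <- vals[!bad, , drop = FALSE]
  if (nrow(vals) == 0) stop("no genes left after dropping rows with missing values")

  ord <- order(meta$species, meta$age_years)
  meta <- meta[ord, , drop = FALSE]
  vals <- vals[, meta$sample_id, drop = FALSE]

  ds <- expression_dataset(vals, meta, normalized = FALSE)
  report <- list(
    genes_input = length(ids),
    genes_kept = nrow(vals),
    genes_dropped = n_dropped,
    samples_per_species = as.list(table(meta$species))
  )
  attr(ds, "load_report") <- report
  if (!quiet) {
    message(sprintf("loaded %d genes (%d dropped for missing values), %d samples",
                    report$genes_kept, report$genes_dropped, ncol(vals)))
    sp <- table(meta$species)
    message("samples per species: ",
            paste(sprintf("%s=%d", names(sp), as.integer(sp)), collapse = ", "))
  }
  ds
}

#' Rank-uniform normalization of each sample
#'
#' Maps every sample (column) independently to the uniform distribution on
#' (0, 1): each value is replaced by `rank / (G + 1)` where `G` is the
#' number of genes and ties get average ranks. After this transform every
#' sample has the same marginal distribution, so window correlations and
#' standard deviations are comparable across samples and ages.
#'
#' The raw matrix is retained in the `raw` slot because fold changes
#' (see [fold_changes()]) are meaningless on rank scores.
#'
#' @param ds An `ExpressionDataset` with `normalized = FALSE`.
#' @return The dataset with rank-uniform `values`, `normalized = TRUE`, and
#'   the input matrix preserved in `raw`.
#' @export
normalize_uniform <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (ds$normalized) {
    stop("dataset is already normalized; refusing to normalize twice")
  }
  G <- nrow(ds$values)
  ranks <- apply(ds$values, 2, rank, ties.method = "average") / (G + 1)
  if (!is.matrix(ranks)) ranks <- matrix(ranks, nrow = G)
  dimnames(ranks) <- dimnames(ds$values)
  out <- ds
  out$raw <- ds$values
  out$values <- ranks
  out$normalized <- TRUE
  out
}

#' Standardize each gene across the course
#'
#' Centers and scales every gene (row) of the raw matrix to mean 0 and
#' standard deviation 1 across the dataset's samples. Pearson
#' correlations are unchanged, and a window's per-gene standard deviation
#' becomes the share of the gene's course-wide variability realized in
#' that window — the scale-free form the DNB statistics require. Genes
#' that are constant across the course are left at 0 (with a warning).
#'
#' @param ds An `ExpressionDataset`; raw values are used (see
#'   [raw_values()]).
#' @return An `ExpressionDataset` whose `values` are per-gene z-scores
#'   (`normalized = FALSE`; the raw matrix is kept in `raw`).
#' @export
standardize_genes <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  raw <- raw_values(ds)
  mu <- rowMeans(raw)
  s <- apply(raw, 1, stats::sd)
  flat <- s == 0
  if (any(flat)) {
    warning(sum(flat), " constant gene(s) left at 0 after standardization")
    s[flat] <- 1
  }
  z <- (raw - mu) / s
  out <- ds
  out$values <- z
  out$raw <- raw
  out$normalized <- FALSE
  out
}

#' Subset a dataset to one species up to a maximum age
#'
#' Keeps samples of `species` with `age_years <= max_age`, preserving the
#' ascending-age order. Fewer than three surviving samples is an error:
#' window correlations downstream are undefined below three samples.
#'
#' @param ds An `ExpressionDataset`.
#' @param species Species label to keep.
#' @param max_age Maximum age in years (inclusive); must be positive.
#' @return The filtered `ExpressionDataset`.
#' @export
filter_by_age <- function(ds, species, max_age) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (!is.numeric(max_age) || length(max_age) != 1 || max_age <= 0) {
    stop("`max_age` must be a single positive number")
  }
  keep <- which(ds$meta$species == species & ds$meta$age_years <= max_age)
  if (length(keep) < 3) {
    stop(sprintf("only %d sample(s) of species '%s' with age <= %g; need >= 3",
                 length(keep), species, max_age))
  }
  keep <- keep[order(ds$meta$age_years[keep])]
  subset_samples(ds, keep)
}

#' Write an expression dataset to a TSV file
#'
#' @param ds An `ExpressionDataset`.
#' @param path Output file path.
#' @param raw Write the raw matrix instead of the (possibly normalized)
#'   `values` slot.
#' @return `path`, invisibly.
#' @export
write_expression <- function(ds, path, raw = FALSE) {
  m <- if (raw) raw_values(ds) else ds$values
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
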