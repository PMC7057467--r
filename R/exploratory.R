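#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of samples on either Euclidean distance or the
#' correlation distance `1 - r` between expression profiles, with average,
#' complete or Ward linkage. Useful to confirm that samples group by
#' species before any time-course analysis.
#'
#' @param ds An `ExpressionDataset`.
#' @param linkage One of `"average"`, `"complete"`, `"ward"` (Ward.D2).
#' @param metric One of `"euclidean"`, `"correlation"`.
#' @param k Optional number of flat clusters to cut the tree into.
#' @return List with the `hclust` object (`tree`) and, when `k` is given,
#'   integer `labels` named by sample id.
#' @export
cluster_samples <- function(ds, linkage = c("average", "complete", "ward"),
                            metric = c("euclidean", "correlation"), k = NULL) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  S <- ncol(ds$values)
  if (S < 2) stop("need at least 2 samples to cluster")
  d <- switch(metric,
    euclidean = stats::dist(t(ds$values)),
    correlation = stats::as.dist(1 - stats::cor(ds$values))
  )
  method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- stats::hclust(d, method = method)
  out <- list(tree = tree)
  if (!is.null(k)) {
    if (k > S) stop(sprintf("k = %d exceeds the number of samples (%d)", k, S))
    out$labels <- stats::cutree(tree, k = k)
  }
  out
}

# Internal: orient each ordination axis so its largest-magnitude gene
# loading is positive, for reproducible signs.
orient_by_loading <- function(scores, loadings) {
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  scores
}

#' Principal-component scores of samples
#'
#' Projects samples onto the top `k` principal components of the
#' gene-centered expression matrix. Each axis is oriented so that its
#' largest-magnitude gene loading is positive.
#'
#' @param ds An `ExpressionDataset`.
#' @param k Number of components, `1 <= k <= min(G, S)`.
#' @return List of class `ordination` with `sample_ids`, `coordinates`
#'   (S x k), `variance_explained` and `method = "pca"`.
#' @export
pca_scores <- function(ds, k = 2) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (k <= 0) stop("`k` must be positive")
  G <- nrow(ds$values); S <- ncol(ds$values)
  if (k > min(G, S)) stop(sprintf("k = %d exceeds min(G, S) = %d", k, min(G, S)))
  pc <- stats::prcomp(t(ds$values), center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- orient_by_loading(pc$x[, seq_len(k), drop = FALSE],
                              pc$rotation[, seq_len(k), drop = FALSE])
  structure(list(
    sample_ids = ds$meta$sample_id,
    coordinates = unname(scores),
    variance_explained = ve[seq_len(k)],
    method = "pca"
  ), class = "ordination")
}

#' Classical MDS first axis as a 1-D expression summary
#'
#' Classical (Torgerson) multidimensional scaling on Euclidean inter-sample
#' distances; for Euclidean distances this equals PCA up to sign, so the
#' first axis is a principled one-dimensional summary of global expression,
#' to be plotted against age. The axis is oriented so the youngest sample
#' has the smaller coordinate.
#'
#' @param ds An `ExpressionDataset` with at least 3 samples.
#' @return List of class `ordination` with `sample_ids`, `coordinates`
#'   (S x 1), `variance_explained` (share of positive eigenvalue mass) and
#'   `method = "cmds"`.
#' @export
mds_axis <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  S <- ncol(ds$values)
  if (S < 3) stop("need at least 3 samples")
  d <- stats::dist(t(ds$values))
  if (max(d) == 0) {
    warning("all samples identical; MDS axis is all zero")
    coords <- matrix(0, nrow = S, ncol = 1)
    ve <- NA_real_
  } else {
    fit <- stats::cmdscale(d, k = 1, eig = TRUE)
    coords <- matrix(fit$points[, 1], ncol = 1)
    pos <- pmax(fit$eig, 0)
    ve <- pos[1] / sum(pos)
    youngest <- which.min(ds$meta$age_years)
    oldest <- which.max(ds$meta$age_years)
    if (coords[youngest, 1] > coords[oldest, 1]) coords <- -coords
  }
  structure(list(
    sample_ids = ds$meta$sample_id,
    coordinates = coords,
    variance_explained = ve,
    method = "cmds"
  ), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d samples x %d axes\n",
              toupper(x$method), nrow(x$coordinates), ncol(x$coordinates)))
  if (!all(is.na(x$variance_explained))) {
    cat("  variance explained:",
        paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fraction of global expression change accrued by a cutoff age
#'
#' Operationalizes "how much of the total change happened before age x":
#' the range of the 1-D ordination coordinate among samples with
#' `age <= cutoff_age`, divided by the coordinate range over all samples.
#' Returns 1 with a warning when no sample lies beyond the cutoff.
#'
#' @param axis A 1-D `ordination` (see [mds_axis()]).
#' @param ages Numeric vector of ages aligned with the axis's samples.
#' @param cutoff_age Cutoff in years.
#' @return A number in `[0, 1]`.
#' @export
fraction_change_by_age <- function(axis, ages, cutoff_age) {
  if (!inherits(axis, "ordination") || ncol(axis$coordinates) != 1) {
    stop("`axis` must be a 1-D ordination")
  }
  coords <- axis$coordinates[, 1]
  if (length(ages) != length(coords)) stop("`ages` must align with the axis samples")
  left <- ages <= cutoff_age
  if (!any(left)) stop("no sample at or below `cutoff_age`")
  if (all(left)) {
    warning("no sample beyond `cutoff_age`; fraction is 1 by definition")
    return(1)
  }
  total <- diff(range(coords))
  if (total == 0) {
    warning("axis has zero range; returning 0")
    return(0)
  }
  diff(range(coords[left])) / total
}
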