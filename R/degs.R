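#' Per-gene one-way ANOVA p-values
#'
#' Fixed-effects one-way ANOVA F-test per gene on `log2(raw + 1)` values
#' (the log stabilizes the variance of expression intensities). Genes with
#' no variance at all (zero within- and between-group) get `p = 1`.
#'
#' @param ds An `ExpressionDataset`; the raw (pre-normalization) matrix is
#'   used, see [raw_values()].
#' @param groups Group labels, one per sample, either in column order or
#'   named by sample id. At least two groups with at least two samples each.
#' @return Named numeric vector of p-values, one per gene.
#' @export
anova_pvalues <- function(ds, groups) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  ids <- ds$meta$sample_id
  if (!is.null(names(groups))) {
    if (!all(ids %in% names(groups))) stop("`groups` names must cover all sample ids")
    groups <- groups[ids]
  }
  if (length(groups) != length(ids)) stop("`groups` must have one label per sample")
  f <- factor(groups)
  if (nlevels(f) < 2) stop("need at least 2 groups")
  if (any(table(f) < 2)) {
    small <- names(which(table(f) < 2))
    stop("group(s) with fewer than 2 samples: ", paste(small, collapse = ", "))
  }

  Y <- log2(raw_values(ds) + 1)
  p <- apply(Y, 1, function(y) {
    if (stats::var(y) == 0) return(1)
    res <- suppressWarnings(stats::oneway.test(y ~ f, var.equal = TRUE))
    pv <- res$p.value
    if (!is.finite(pv)) {
      # zero within-group variance with distinct means: infinitely strong F
      gm <- tapply(y, f, mean)
      pv <- if (stats::var(as.numeric(gm)) > 0) 0 else 1
    }
    pv
  })
  names(p) <- rownames(Y)
  p
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: `q_(i) = min_{j >= i}
#' p_(j) * m / j`, capped at 1, reported in the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-gene fold change between two sample sets
#'
#' Linear-scale ratio of raw group means, `(mean_after + pseudocount) /
#' (mean_before + pseudocount)`. The pseudocount defaults to the smallest
#' positive value in the raw matrix and guards against division by zero.
#'
#' @param ds An `ExpressionDataset`; raw values are used.
#' @param before,after Nonempty character vectors of sample ids.
#' @param pseudocount Stabilizing constant; `NULL` = smallest positive
#'   raw value.
#' @return Named numeric vector of fold changes (after / before).
#' @export
fold_changes <- function(ds, before, after, pseudocount = NULL) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (length(before) == 0 || length(after) == 0) {
    stop("`before` and `after` must both be nonempty")
  }
  raw <- raw_values(ds)
  unknown <- setdiff(c(before, after), colnames(raw))
  if (length(unknown)) stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  if (is.null(pseudocount)) {
    pos <- raw[raw > 0]
    pseudocount <- if (length(pos)) min(pos) else 1
  }
  mb <- rowMeans(raw[, before, drop = FALSE])
  ma <- rowMeans(raw[, after, drop = FALSE])
  (ma + pseudocount) / (mb + pseudocount)
}

#' Call differentially expressed genes
#'
#' Combines ANOVA p-values and fold changes into DEG calls: a gene is a
#' DEG when its Benjamini-Hochberg q-value is below `fdr_threshold` and
#' its direction-symmetric fold change `max(FC, 1/FC)` exceeds
#' `fc_threshold` (so 2-fold down counts like 2-fold up).
#'
#' @param p_values Named numeric vector of per-gene p-values.
#' @param fold_change Named numeric vector of per-gene fold changes,
#'   aligned with `p_values`.
#' @param fdr_threshold FDR threshold (default 0.01).
#' @param fc_threshold Fold-change threshold (default 2).
#' @return Data frame with columns `gene_id`, `p_value`, `q_value`,
#'   `fold_change`, `is_deg`.
#' @export
call_degs <- function(p_values, fold_change, fdr_threshold = 0.01,
                      fc_threshold = 2) {
  if (fdr_threshold <= 0 || fc_threshold <= 0) stop("thresholds must be positive")
  if (length(p_values) != length(fold_change)) {
    stop("`p_values` and `fold_change` must have equal length")
  }
  q <- bh_fdr(p_values)
  fc_sym <- pmax(fold_change, 1 / fold_change)
  data.frame(
    gene_id = if (is.null(names(p_values))) seq_along(p_values) else names(p_values),
    p_value = unname(p_values),
    q_value = unname(q),
    fold_change = unname(fold_change),
    is_deg = unname(q < fdr_threshold & fc_sym > fc_threshold),
    stringsAsFactors = FALSE
  )
}

#' Differential expression around a tipping point
#'
#' Convenience wrapper: splits samples into before (`age <= split_age`)
#' and after (`age > split_age`), runs [anova_pvalues()] on that two-group
#' partition (or on a caller-supplied multi-period `groups` labelling),
#' computes before/after [fold_changes()], and calls DEGs.
#'
#' @param ds An `ExpressionDataset`.
#' @param split_age Age in years separating "before" from "after"; the
#'   tipping window's age label is the natural choice.
#' @param groups Optional alternative group labelling for the ANOVA
#'   (e.g. one label per sampling period); fold changes still use the
#'   `split_age` split.
#' @param fdr_threshold,fc_threshold Calling thresholds, see [call_degs()].
#' @param pseudocount See [fold_changes()].
#' @return The [call_degs()] data frame.
#' @export
differential_expression <- function(ds, split_age, groups = NULL,
                                    fdr_threshold = 0.01, fc_threshold = 2,
                                    pseudocount = NULL) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  ages <- ds$meta$age_years
  before <- ds$meta$sample_id[ages <= split_age]
  after <- ds$meta$sample_id[ages > split_age]
  if (length(before) < 2 || length(after) < 2) {
    stop(sprintf("split at %g years leaves %d/%d samples; need >= 2 per side",
                 split_age, length(before), length(after)))
  }
  if (is.null(groups)) {
    groups <- ifelse(ages <= split_age, "before", "after")
  }
  p <- anova_pvalues(ds, groups)
  fc <- fold_changes(ds, before, after, pseudocount)
  call_degs(p, fc, fdr_threshold, fc_threshold)
}

#' Overlap of two gene sets
#'
#' @param a,b Character vectors of gene ids.
#' @return List with sorted `intersection`, `a_only`, `b_only` and a named
#'   integer vector `sizes`.
#' @export
overlap_sets <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  out <- list(
    intersection = sort(intersect(a, b)),
    a_only = sort(setdiff(a, b)),
    b_only = sort(setdiff(b, a))
  )
  out$sizes <- c(
    intersection = length(out$intersection),
    a_only = length(out$a_only),
    b_only = length(out$b_only)
  )
  out
}
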