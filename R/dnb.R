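#' DNB statistics for one gene group in one window
#'
#' Computes the three dynamic-network-biomarker criteria for a candidate
#' dominant group within a sample window, and their composite index:
#'
#' * `sd_d` — mean, over group genes, of the sample standard deviation
#'   (n-1 denominator) across the window's samples;
#' * `pcc_d` — mean absolute Pearson correlation over all unordered pairs
#'   of group genes (defined as 1 for a singleton group);
#' * `pcc_o` — mean absolute Pearson correlation over all pairs of one
#'   group gene and one non-group gene;
#' * `ci = sd_d * pcc_d / pcc_o`.
#'
#' A group whose correlations surge, whose variance surges, and whose
#' coupling to the rest of the system drops — a CI peak — marks an
#' imminent critical transition. Pairs involving a gene that is constant
#' within the window contribute an absolute correlation of 0. When
#' `pcc_o` is exactly 0 the composite index is reported as `Inf` with a
#' warning.
#'
#' @param ds An `ExpressionDataset`.
#' @param group Character vector of gene ids; must be a nonempty strict
#'   subset of the dataset's genes.
#' @param window A window from [build_windows()] or a character vector of
#'   at least three sample ids.
#' @return An object of class `dnb_score`: list with `sd_d`, `pcc_d`,
#'   `pcc_o`, `ci`.
#' @export
dnb_statistics <- function(ds, group, window) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  ids <- rownames(ds$values)
  group <- unique(as.character(group))
  if (length(group) == 0) stop("`group` must be nonempty")
  unknown <- setdiff(group, ids)
  if (length(unknown)) {
    stop("group gene(s) not in dataset: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (length(group) >= length(ids)) {
    stop("`group` must be a strict subset of the dataset's genes")
  }
  sid <- window_sample_ids(window)
  if (length(sid) < 3) stop("window must contain at least 3 samples")
  if (!all(sid %in% ds$meta$sample_id)) stop("window sample id(s) not in dataset")

  X <- ds$values[, sid, drop = FALSE]
  gi <- match(group, ids)
  oi <- setdiff(seq_along(ids), gi)

  Xg <- X[gi, , drop = FALSE]
  sds <- apply(Xg, 1, stats::sd)
  sd_d <- mean(sds)

  # |r| between each group gene and every gene; NA (constant gene) -> 0
  C <- suppressWarnings(stats::cor(t(Xg), t(X)))
  C[!is.finite(C)] <- 0
  C <- abs(C)

  g <- length(gi)
  if (g == 1) {
    pcc_d <- 1.0
  } else {
    sub <- C[, gi, drop = FALSE]
    pcc_d <- (sum(sub) - sum(diag(sub))) / (g * (g - 1))
  }
  pcc_o <- mean(C[, oi, drop = FALSE])

  if (pcc_o > 0) {
    ci <- sd_d * pcc_d / pcc_o
  } else {
    warning("pcc_o is 0; composite index reported as Inf")
    ci <- Inf
  }
  structure(list(sd_d = sd_d, pcc_d = pcc_d, pcc_o = pcc_o, ci = ci),
            class = "dnb_score")
}

#' @export
print.dnb_score <- function(x, ...) {
  cat(sprintf("DNB score: sd_d=%.4g  pcc_d=%.4g  pcc_o=%.4g  CI=%.4g\n",
              x$sd_d, x$pcc_d, x$pcc_o, x$ci))
  invisible(x)
}

# Internal workhorse shared by select_dominant_group() and dnb_scan().
# X: gene x sample matrix for one window (rownames = gene ids).
# Two stages: (1) enumerate every cluster of the average-linkage
# dendrogram on 1 - |r|, score clusters in the [min_size, max_size] band,
# and take the candidate with maximal finite CI (ties: smaller cluster,
# then lexicographically smallest member id) as the SEED; (2) extend the
# seed to the full module: genes whose |cor| with the seed's mean profile
# reaches kme_threshold. Stage 2 corrects the selection bias of stage 1
# (the max-CI node is the most collinear, highest-variance fragment of
# its module, not the module itself). Returns the extended group with its
# recomputed score.
window_dominant_group <- function(X, min_size, max_size, kme_threshold = 0.8) {
  G <- nrow(X)
  n <- ncol(X)
  mu <- rowMeans(X)
  sds <- sqrt(rowSums((X - mu)^2) / (n - 1))
  nc <- which(sds > 0)
  empty <- list(genes = character(0),
                score = list(sd_d = NA_real_, pcc_d = NA_real_,
                             pcc_o = NA_real_, ci = NA_real_))
  if (length(nc) < max(min_size, 2)) {
    warning(sprintf("only %d non-constant genes in window; no candidate group",
                    length(nc)))
    return(empty)
  }
  if (max_size < min_size) {
    warning("empty candidate size band (max_size < min_size)")
    return(empty)
  }

  A <- suppressWarnings(stats::cor(t(X)))
  A[!is.finite(A)] <- 0
  A <- abs(A)
  diag(A) <- 0
  rowtot <- rowSums(A)  # per gene, sum of |r| to all other genes

  hc <- stats::hclust(stats::as.dist(1 - A[nc, nc, drop = FALSE]),
                      method = "average")
  merges <- hc$merge
  n_nodes <- nrow(merges)
  members <- vector("list", n_nodes)
  wsum <- numeric(n_nodes)  # ordered within-cluster |r| sum

  best <- NULL
  for (k in seq_len(n_nodes)) {
    a <- merges[k, 1]; b <- merges[k, 2]
    ma <- if (a < 0) nc[-a] else members[[a]]
    mb <- if (b < 0) nc[-b] else members[[b]]
    wa <- if (a < 0) 0 else wsum[a]
    wb <- if (b < 0) 0 else wsum[b]
    cross <- sum(A[ma, mb])
    mem <- c(ma, mb)
    W <- wa + wb + 2 * cross
    members[[k]] <- mem
    wsum[k] <- W
    sz <- length(mem)
    if (sz < min_size || sz > max_size || sz >= G) next
    pcc_d <- W / (sz * (sz - 1))
    pcc_o <- (sum(rowtot[mem]) - W) / (sz * (G - sz))
    if (pcc_o <= 0) next  # infinite CI: not a finite candidate
    sd_d <- mean(sds[mem])
    ci <- sd_d * pcc_d / pcc_o
    if (!is.finite(ci)) next
    if (is.null(best) || ci > best$ci ||
        (ci == best$ci && (sz < length(best$mem) ||
          (sz == length(best$mem) &&
           min(rownames(X)[mem]) < min(rownames(X)[best$mem]))))) {
      best <- list(mem = mem, ci = ci, sd_d = sd_d, pcc_d = pcc_d, pcc_o = pcc_o)
    }
  }
  if (is.null(best)) {
    warning("no candidate cluster in the requested size band")
    return(empty)
  }

  # stage 2: module membership by correlation with the seed profile
  profile <- colMeans(X[best$mem, , drop = FALSE])
  kme <- abs(suppressWarnings(stats::cor(t(X), profile)))[, 1]
  kme[!is.finite(kme)] <- 0
  mem <- which(kme >= kme_threshold)
  if (length(mem) > max_size) {
    mem <- mem[order(kme[mem], decreasing = TRUE)[seq_len(max_size)]]
  }
  if (length(mem) < min_size || length(mem) >= G) mem <- best$mem

  sz <- length(mem)
  W <- sum(A[mem, mem])
  pcc_d <- if (sz == 1) 1 else W / (sz * (sz - 1))
  pcc_o <- (sum(rowtot[mem]) - W) / (sz * (G - sz))
  sd_d <- mean(sds[mem])
  ci <- if (pcc_o > 0) sd_d * pcc_d / pcc_o else Inf
  list(genes = sort(rownames(X)[mem]),
       score = list(sd_d = sd_d, pcc_d = pcc_d, pcc_o = pcc_o, ci = ci))
}

#' Select the dominant (DNB candidate) gene group in one window
#'
#' Genes are hierarchically clustered (average linkage) on the distance
#' `1 - |Pearson r|` computed within the window; every cluster of the
#' dendrogram with size in `[min_size, max_size]` is scored by
#' [dnb_statistics()], and the cluster with the largest finite composite
#' index is returned. Ties are broken toward the smaller cluster, then the
#' lexicographically smallest member gene id. Returns an empty set with a
#' warning when no cluster falls in the size band or fewer than `min_size`
#' genes vary within the window.
#'
#' @param ds An `ExpressionDataset` whose `values` are on a comparable
#'   per-gene scale (see [standardize_genes()]); [dnb_scan()] handles this
#'   automatically.
#' @param window A window from [build_windows()] or a vector of sample ids.
#' @param min_size Smallest admissible group (>= 2).
#' @param max_size Largest admissible group; default `floor(G / 5)`.
#' @param kme_threshold Membership threshold for the extension stage:
#'   minimum absolute correlation with the seed's mean profile.
#' @return Character vector of gene ids (possibly empty), with the winning
#'   score attached as attribute `"score"`.
#' @export
select_dominant_group <- function(ds, window, min_size = 5, max_size = NULL,
                                  kme_threshold = 0.9) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  min_size <- as.integer(min_size)
  if (min_size < 2) stop("`min_size` must be >= 2")
  G <- nrow(ds$values)
  if (is.null(max_size)) max_size <- max(min_size, floor(G / 5))
  sid <- window_sample_ids(window)
  if (length(sid) < 3) stop("window must contain at least 3 samples")
  X <- ds$values[, sid, drop = FALSE]
  res <- window_dominant_group(X, min_size, as.integer(max_size), kme_threshold)
  structure(res$genes, score = res$score)
}

#' Significance of the peak of a composite-index trajectory
#'
#' Leave-peak-out z-score: `z = (max CI - mean(rest)) / sd(rest)`, where
#' "rest" are the remaining windows' CI values. The peak is called
#' significant when `z >= z_threshold`. Because the peak is the maximum
#' over `n` windows, a fixed threshold is anti-conservative (the expected
#' maximum of `n` exchangeable scores is about `sqrt(2 log n)` standard
#' deviations); the default threshold is therefore calibrated for
#' multiplicity, `qt(1 - alpha / n, n - 2)`, which holds the familywise
#' false-peak rate near `alpha` under an exchangeable null. Pass a fixed
#' `z_threshold` (e.g. 2) to override. When the remaining values have
#' zero spread the peak is significant iff it strictly exceeds them
#' (`z = Inf` sentinel; `z = 0` for a flat trajectory). Fewer than three
#' finite values cannot support the test: `significant = FALSE`, `z = NA`,
#' with a warning.
#'
#' @param ci_trajectory Numeric vector of per-window composite indices.
#' @param z_threshold Significance threshold on `z`; `NULL` (default)
#'   uses the multiplicity-calibrated threshold.
#' @param alpha Familywise false-peak rate for the calibrated threshold.
#' @return List with `significant` (logical), `z` and the `threshold`
#'   used.
#' @export
peak_significance <- function(ci_trajectory, z_threshold = NULL, alpha = 0.05) {
  x <- ci_trajectory[is.finite(ci_trajectory)]
  n <- length(x)
  if (is.null(z_threshold)) {
    z_threshold <- if (n >= 3) stats::qt(1 - alpha / n, df = n - 2) else Inf
  }
  if (any(is.infinite(ci_trajectory) & ci_trajectory > 0)) {
    # an Inf CI (pcc_o = 0) dominates every finite window
    return(list(significant = TRUE, z = Inf, threshold = z_threshold))
  }
  if (n < 3) {
    warning("need at least 3 finite CI values for the peak test")
    return(list(significant = FALSE, z = NA_real_, threshold = z_threshold))
  }
  i <- which.max(x)
  rest <- x[-i]
  s <- stats::sd(rest)
  if (s == 0) {
    if (x[i] > rest[1]) {
      return(list(significant = TRUE, z = Inf, threshold = z_threshold))
    }
    return(list(significant = FALSE, z = 0, threshold = z_threshold))
  }
  z <- (x[i] - mean(rest)) / s
  list(significant = z >= z_threshold, z = z, threshold = z_threshold)
}

#' Scan a time course for a tipping point with the DNB composite index
#'
#' Runs the full dynamic-network-biomarker analysis on an age-sorted,
#' normalized expression dataset: builds sliding windows, selects the
#' dominant gene group in each window ([select_dominant_group()]), records
#' the per-window statistics (`sd_d`, `pcc_d`, `pcc_o`, `ci`), takes the
#' window of maximal CI as the tipping point (ties resolved to the
#' earliest window), and assesses the peak with [peak_significance()] and,
#' optionally, a permutation test that shuffles sample ages, rebuilds the
#' windows and rescans.
#'
#' @param ds An `ExpressionDataset`, samples sorted by age (use
#'   [filter_by_age()] / [load_expression()]). Genes are standardized
#'   across the course ([standardize_genes()]) before any window
#'   statistic, so the scan is invariant to per-gene scale.
#' @param window_size,step Window parameters, see [build_windows()].
#' @param min_size,max_size Dominant-group size band, see
#'   [select_dominant_group()].
#' @param kme_threshold Module-membership threshold, see
#'   [select_dominant_group()].
#' @param z_threshold Peak z-score threshold; `NULL` (default) uses the
#'   multiplicity-calibrated threshold of [peak_significance()].
#' @param permutations Number of age permutations for the optional
#'   permutation test (0 = skip).
#' @param seed Seed for the permutation test.
#' @return An object of class `dnb_result`: list with `windows`, `scores`
#'   (one row per window), `groups` (list of gene-id vectors),
#'   `tipping_index`, `tipping_age`, `dnb_genes`, `z`, `significant`, and
#'   `perm_p` when permutations were requested.
#' @export
dnb_scan <- function(ds, window_size = 4, step = 1, min_size = 5,
                     max_size = NULL, kme_threshold = 0.9, z_threshold = NULL,
                     permutations = 0, seed = NULL) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  ds_std <- standardize_genes(ds)
  G <- nrow(ds_std$values)
  if (is.null(max_size)) max_size <- max(as.integer(min_size), floor(G / 5))

  windows <- build_windows(ds_std, window_size, step)
  groups <- vector("list", length(windows))
  score_rows <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    X <- ds_std$values[, windows[[i]]$sample_ids, drop = FALSE]
    res <- window_dominant_group(X, as.integer(min_size), as.integer(max_size),
                                 kme_threshold)
    groups[[i]] <- res$genes
    score_rows[[i]] <- data.frame(
      window_index = i,
      age_label = windows[[i]]$age_label,
      group_size = length(res$genes),
      sd_d = res$score$sd_d,
      pcc_d = res$score$pcc_d,
      pcc_o = res$score$pcc_o,
      ci = res$score$ci
    )
  }
  scores <- do.call(rbind, score_rows)
  if (all(lengths(groups) == 0)) stop("no DNB candidates in any window")

  ci <- scores$ci
  tipping_index <- which.max(ifelse(is.na(ci), -Inf, ci))  # earliest max
  sig <- peak_significance(ci, z_threshold)

  out <- list(
    windows = windows,
    scores = scores,
    groups = groups,
    tipping_index = tipping_index,
    tipping_age = windows[[tipping_index]]$age_label,
    dnb_genes = groups[[tipping_index]],
    z = sig$z,
    z_threshold_used = sig$threshold,
    significant = sig$significant,
    params = list(window_size = window_size, step = step,
                  min_size = min_size, max_size = max_size,
                  kme_threshold = kme_threshold, z_threshold = z_threshold)
  )

  if (permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    obs <- max(ci[is.finite(ci)])
    perm_peaks <- vapply(seq_len(permutations), function(b) {
      perm <- sample.int(ncol(ds$values))
      dsb <- ds
      dsb$meta$age_years <- ds$meta$age_years[perm]
      dsb <- subset_samples(dsb, order(dsb$meta$age_years))
      rb <- dnb_scan(dsb, window_size, step, min_size, max_size,
                     kme_threshold, z_threshold, permutations = 0)
      cib <- rb$scores$ci
      max(cib[is.finite(cib)], -Inf)
    }, numeric(1))
    out$perm_p <- (1 + sum(perm_peaks >= obs)) / (permutations + 1)
  }
  class(out) <- "dnb_result"
  out
}

#' @export
print.dnb_result <- function(x, ...) {
  cat(sprintf(
    "DNB scan: %d windows; tipping at window %d (age %.3g y), CI=%.4g\n",
    nrow(x$scores), x$tipping_index, x$tipping_age,
    x$scores$ci[x$tipping_index]
  ))
  cat(sprintf("  peak z = %.3g -> %ssignificant (threshold %.3g)\n",
              x$z, if (x$significant) "" else "NOT ", x$z_threshold_used))
  if (!is.null(x$perm_p)) cat(sprintf("  permutation p = %.4g\n", x$perm_p))
  cat(sprintf("  DNB genes at tipping window: %d\n", length(x$dnb_genes)))
  invisible(x)
}
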