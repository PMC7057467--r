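# Independent brute-force oracles and small fixture builders.
# The oracles use only definitional formulas (explicit loops, textbook
# Pearson / sum-of-squares arithmetic) so they stay independent of the
# package's vectorized implementations.

# Textbook Pearson correlation; 0 when either vector is constant
# (matching the package's convention for degenerate pairs).
pearson_def <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) return(0)
  sum((x - mx) * (y - my)) / den
}

# Definitional DNB statistics via explicit double loops over pairs.
dnb_oracle <- function(X, group_idx) {
  other_idx <- setdiff(seq_len(nrow(X)), group_idx)
  n <- ncol(X)
  sds <- vapply(group_idx, function(i) {
    m <- mean(X[i, ])
    sqrt(sum((X[i, ] - m)^2) / (n - 1))
  }, numeric(1))
  sd_d <- mean(sds)
  if (length(group_idx) == 1) {
    pcc_d <- 1
  } else {
    acc <- 0; np <- 0
    for (i in seq_along(group_idx)) {
      for (j in seq_along(group_idx)) {
        if (j <= i) next
        acc <- acc + abs(pearson_def(X[group_idx[i], ], X[group_idx[j], ]))
        np <- np + 1
      }
    }
    pcc_d <- acc / np
  }
  acc <- 0
  for (i in group_idx) for (j in other_idx) {
    acc <- acc + abs(pearson_def(X[i, ], X[j, ]))
  }
  pcc_o <- acc / (length(group_idx) * length(other_idx))
  ci <- if (pcc_o > 0) sd_d * pcc_d / pcc_o else Inf
  list(sd_d = sd_d, pcc_d = pcc_d, pcc_o = pcc_o, ci = ci)
}

# One-way ANOVA p-value by explicit sum-of-squares arithmetic.
anova_oracle <- function(y, groups) {
  f <- factor(groups)
  k <- nlevels(f); N <- length(y)
  gm <- mean(y)
  ssb <- sum(tapply(y, f, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(unlist(tapply(y, f, function(v) (v - mean(v))^2)))
  if (ssb == 0 && ssw == 0) return(1)
  if (ssw == 0) return(0)
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  stats::pf(F, k - 1, N - k, lower.tail = FALSE)
}

# Build an ExpressionDataset from a bare matrix.
make_ds <- function(mat, ages = seq_len(ncol(mat)), species = "synthetic",
                    normalized = FALSE) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%03d", seq_len(ncol(mat)))
  expression_dataset(
    mat,
    data.frame(sample_id = colnames(mat), species = species,
               age_years = ages, stringsAsFactors = FALSE),
    normalized = normalized
  )
}

# Write a dataset's matrix + metadata as the TSV pair load_expression() reads.
write_fixture <- function(ds, dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(dir, "matrix.tsv")
  dpath <- file.path(dir, "meta.tsv")
  write_expression(ds, mpath, raw = TRUE)
  utils::write.table(ds$meta, dpath, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mpath, meta = dpath, dir = dir)
}

# Scan settings used throughout the synthetic evaluation: windows of two
# sampling periods advancing one period, so the planted period is fully
# covered by exactly two windows and "+-1 window" means "+-1 period".
eval_scan <- function(ds, ...) {
  suppressWarnings(dnb_scan(ds, window_size = 6, step = 3, ...))
}
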