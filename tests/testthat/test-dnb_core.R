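test_that("build_windows enumerates sliding windows with an anchored tail", {
  ds13 <- make_ds(matrix(rnorm(13 * 2), 2, 13))
  w <- build_windows(ds13, window_size = 4, step = 1)
  expect_length(w, 10)
  expect_equal(w[[1]]$sample_ids, ds13$meta$sample_id[1:4])

  ds4 <- make_ds(matrix(rnorm(8), 2, 4))
  expect_length(build_windows(ds4, 4, 1), 1)

  ds9 <- make_ds(matrix(rnorm(18), 2, 9))
  w9 <- build_windows(ds9, window_size = 4, step = 2)
  expect_equal(vapply(w9, `[[`, integer(1), "start"), c(1L, 3L, 5L, 6L))

  expect_error(build_windows(ds4, 5, 1), "at least 5 samples")
  expect_error(build_windows(ds4, 2, 1), ">= 3")
  expect_error(build_windows(ds4, 4, 5), "step")
  unsorted <- make_ds(matrix(rnorm(8), 2, 4), ages = c(2, 1, 3, 4))
  expect_error(build_windows(unsorted, 3, 1), "sorted")
})

test_that("window age labels are the median member age", {
  ds <- make_ds(matrix(rnorm(12), 2, 6), ages = c(0, 0.1, 0.2, 0.4, 0.8, 1.6))
  w <- build_windows(ds, 4, 2)
  expect_equal(w[[1]]$age_label, median(c(0, 0.1, 0.2, 0.4)))
  expect_equal(w[[2]]$age_label, median(c(0.2, 0.4, 0.8, 1.6)))
})

test_that("dnb_statistics reproduces hand-computed collinear examples", {
  X <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6), o = c(3, 2, 1))
  ds <- make_ds(X)
  s <- dnb_statistics(ds, c("g1", "g2"), ds$meta$sample_id)
  expect_equal(s$sd_d, 1.5)
  expect_equal(s$pcc_d, 1.0)
  expect_equal(s$pcc_o, 1.0)
  expect_equal(s$ci, 1.5)

  ds2 <- make_ds(rbind(g1 = c(1, 2, 3), o = c(1, 2, 3)))
  s2 <- dnb_statistics(ds2, "g1", ds2$meta$sample_id)
  expect_equal(s2$pcc_d, 1.0)  # singleton convention
  expect_equal(s2$ci, 1.0)
})

test_that("dnb_statistics contract errors fire", {
  ds <- make_ds(matrix(rnorm(20), 4, 5))
  w <- ds$meta$sample_id
  expect_error(dnb_statistics(ds, "nope", w), "not in dataset")
  expect_error(dnb_statistics(ds, gene_ids(ds), w), "strict subset")
  expect_error(dnb_statistics(ds, "g001", w[1:2]), "at least 3")
  expect_warning(
    s <- dnb_statistics(make_ds(rbind(a = c(1, 2, 3), b = c(5, 5, 5))), "a",
                        c("s001", "s002", "s003")),
    "pcc_o is 0"
  )
  expect_identical(s$ci, Inf)
})

test_that("dnb_statistics agrees with the brute-force pair-loop oracle", {
  set.seed(101)
  for (rep in 1:12) {
    G <- sample(4:12, 1); n <- sample(3:8, 1)
    X <- matrix(rnorm(G * n), G, n)
    ds <- make_ds(X)
    gidx <- sort(sample(G, sample(seq_len(G - 1), 1)))
    s <- dnb_statistics(ds, gene_ids(ds)[gidx], ds$meta$sample_id)
    o <- dnb_oracle(ds$values, gidx)
    expect_equal(s$sd_d, o$sd_d, tolerance = 1e-12)
    expect_equal(s$pcc_d, o$pcc_d, tolerance = 1e-12)
    expect_equal(s$pcc_o, o$pcc_o, tolerance = 1e-12)
    expect_equal(s$ci, o$ci, tolerance = 1e-12)
  }
})

test_that("scaling a group multiplies sd_d and ci by k, leaving correlations fixed", {
  set.seed(5)
  X <- matrix(rnorm(8 * 6), 8, 6)
  ds <- make_ds(X)
  grp <- gene_ids(ds)[1:3]
  s1 <- dnb_statistics(ds, grp, ds$meta$sample_id)
  for (k in c(0.5, 3, 10)) {
    X2 <- X; X2[1:3, ] <- k * X2[1:3, ]
    s2 <- dnb_statistics(make_ds(X2), grp, ds$meta$sample_id)
    expect_equal(s2$sd_d, k * s1$sd_d)
    expect_equal(s2$pcc_d, s1$pcc_d)
    expect_equal(s2$pcc_o, s1$pcc_o)
    expect_equal(s2$ci, k * s1$ci)
  }
})

test_that("statistics are invariant to permuting gene rows", {
  set.seed(6)
  X <- matrix(rnorm(10 * 5), 10, 5,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:5)))
  ds <- make_ds(X)
  perm <- sample(10)
  dsp <- make_ds(X[perm, ])
  grp <- c("g02", "g05", "g09")
  s1 <- dnb_statistics(ds, grp, ds$meta$sample_id)
  s2 <- dnb_statistics(dsp, grp, dsp$meta$sample_id)
  expect_equal(unclass(s1), unclass(s2))
})

test_that("select_dominant_group finds a planted collinear trio among noise", {
  set.seed(13)
  n <- 10
  latent <- rnorm(n)
  noise <- matrix(rnorm(20 * n), 20, n)
  X <- rbind(a = 2 * latent, b = latent + 5, c = -latent, noise)
  rownames(X)[4:23] <- sprintf("n%02d", 1:20)
  ds <- make_ds(X)
  g <- select_dominant_group(ds, ds$meta$sample_id, min_size = 2, max_size = 5)
  expect_setequal(g, c("a", "b", "c"))
  sc <- attr(g, "score")
  expect_gt(sc$pcc_d, 0.99)
})

test_that("select_dominant_group returns empty with a warning when no size band fits", {
  ds <- make_ds(matrix(rnorm(4 * 5), 4, 5))
  expect_warning(g <- select_dominant_group(ds, ds$meta$sample_id, min_size = 5),
                 "size band|non-constant")
  expect_length(g, 0)
})

test_that("on pure noise the selected group is no better than 2x the best random group", {
  set.seed(21)
  G <- 40; n <- 8
  ds <- make_ds(matrix(rnorm(G * n), G, n))
  g <- select_dominant_group(ds, ds$meta$sample_id, min_size = 5, max_size = 8)
  ci_sel <- attr(g, "score")$ci
  best_rand <- max(vapply(1:100, function(i) {
    grp <- sample(gene_ids(ds), 5)
    dnb_statistics(ds, grp, ds$meta$sample_id)$ci
  }, numeric(1)))
  expect_lt(ci_sel, 2 * best_rand)
})

test_that("peak_significance handles the documented edge cases", {
  r1 <- peak_significance(c(1, 1, 1, 5))
  expect_true(r1$significant)
  expect_identical(r1$z, Inf)

  r2 <- peak_significance(c(1, 1.1, 0.9, 1.05), z_threshold = 2)
  expect_equal(r2$z, 1.5275252, tolerance = 1e-6)  # hand-computed leave-peak-out z
  expect_false(r2$significant)

  r3 <- peak_significance(c(2, 2, 2, 2))
  expect_false(r3$significant)

  expect_warning(r4 <- peak_significance(c(1, 2)), "at least 3")
  expect_false(r4$significant)
  expect_true(is.na(r4$z))
})

test_that("default peak threshold carries the multiplicity correction", {
  t9 <- peak_significance(rnorm(9) + c(rep(0, 8), 10))$threshold
  expect_equal(t9, qt(1 - 0.05 / 9, df = 7))
  expect_gt(t9, 2)
  # stricter alpha -> stricter threshold
  t9b <- peak_significance(rnorm(9) + c(rep(0, 8), 10), alpha = 0.01)$threshold
  expect_gt(t9b, t9)
})

test_that("dnb_scan on a single window degenerates gracefully", {
  ds <- make_ds(matrix(rnorm(30 * 4), 30, 4))
  expect_warning(r <- dnb_scan(ds, window_size = 4, min_size = 3), "at least 3 finite")
  expect_equal(r$tipping_index, 1L)
  expect_false(r$significant)
})

test_that("dnb_scan recovers the planted transition and its gene module", {
  sim <- generate_dataset(sim_config(seed = 2))
  r <- eval_scan(sim$dataset)
  ev <- evaluate_recovery(r, sim$truth)
  expect_true(ev$hit)
  expect_lt(abs(r$tipping_age - sim$truth$tipping_age), 0.06)  # within one period
  expect_gt(ev$jaccard, 0.5)
})

test_that("at the planted window the module's sd and within-correlation beat their medians, pcc_o falls below", {
  # median-based direction check over a handful of seeds
  ok <- 0; n_seeds <- 6
  for (s in seq_len(n_seeds)) {
    sim <- generate_dataset(sim_config(seed = 100 + s))
    ds <- standardize_genes(sim$dataset)
    wins <- build_windows(ds, 6, 3)
    labs <- vapply(wins, `[[`, numeric(1), "age_label")
    d <- abs(labs - sim$truth$tipping_age)
    tied <- which(d == min(d))  # windows fully covering the planted period
    st <- t(vapply(wins, function(w) {
      x <- dnb_statistics(ds, sim$truth$dnb_gene_ids, w)
      c(x$sd_d, x$pcc_d, x$pcc_o)
    }, numeric(3)))
    ok <- ok + any(vapply(tied, function(tip) {
      st[tip, 1] > median(st[, 1]) && st[tip, 2] > median(st[, 2]) &&
        st[tip, 3] < median(st[, 3])
    }, logical(1)))
  }
  expect_gte(ok, n_seeds - 1)
})

test_that("permutation test is reproducible under a seed and calibrated-ish on null data", {
  sim <- generate_dataset(sim_config(n_genes = 120, n_dnb = 10, n_de = 0, seed = 3))
  r1 <- eval_scan(sim$dataset, permutations = 9, seed = 77)
  r2 <- eval_scan(sim$dataset, permutations = 9, seed = 77)
  expect_equal(r1$perm_p, r2$perm_p)
  expect_true(r1$perm_p >= 1 / 10 || r1$perm_p <= 1)
})
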