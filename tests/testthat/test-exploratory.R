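test_that("cluster_samples merges duplicated samples first and honors k", {
  set.seed(41)
  X <- matrix(rnorm(10 * 5), 10, 5)
  X[, 5] <- X[, 2]  # exact duplicate pair
  ds <- make_ds(X)
  cl <- cluster_samples(ds, "average", "euclidean", k = 4)
  expect_equal(cl$tree$height[1], 0)
  first_pair <- sort(-cl$tree$merge[1, ])
  expect_equal(first_pair, c(2, 5))
  expect_equal(unname(cl$labels[2]), unname(cl$labels[5]))
  # k = S: every sample its own cluster
  clS <- cluster_samples(ds, k = 5)
  expect_equal(length(unique(clS$labels)), 5L)
  expect_error(cluster_samples(ds, k = 6), "exceeds")
})

test_that("clustering separates two species with distinct mean shifts", {
  set.seed(43)
  G <- 60
  a <- matrix(rnorm(G * 6, mean = 0), G, 6)
  b <- matrix(rnorm(G * 5, mean = 3), G, 5)
  sp <- c(rep("human", 6), rep("chimpanzee", 5))
  ds <- make_ds(cbind(a, b), species = sp)
  cl <- cluster_samples(ds, "average", "euclidean", k = 2)
  expect_equal(length(unique(cl$labels[sp == "human"])), 1L)
  expect_equal(length(unique(cl$labels[sp == "chimpanzee"])), 1L)
  expect_false(cl$labels[1] == cl$labels[11])
})

test_that("pca_scores: collinear samples load entirely on PC1", {
  line <- seq(0, 5, length.out = 6)
  X <- outer(rnorm(12), line)  # samples on a line through the origin
  ds <- make_ds(X)
  p <- pca_scores(ds, k = 2)
  expect_equal(p$variance_explained[1], 1.0, tolerance = 1e-12)
  # duplicated sample -> identical score rows
  X2 <- cbind(X, X[, 3])
  p2 <- pca_scores(make_ds(X2), k = 2)
  expect_equal(p2$coordinates[3, ], p2$coordinates[7, ], tolerance = 1e-10)
  expect_error(pca_scores(ds, k = 0), "positive")
  expect_error(pca_scores(ds, k = 50), "exceeds")
})

test_that("pca_scores matches a dense eigendecomposition oracle up to sign", {
  set.seed(47)
  X <- matrix(rnorm(20 * 8), 20, 8)
  ds <- make_ds(X)
  p <- pca_scores(ds, k = 3)
  Xc <- t(X) - colMeans(t(X))[col(t(X))]  # center genes
  Xc <- scale(t(X), center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE)
  oracle <- Xc %*% ev$vectors[, 1:3]
  for (j in 1:3) {
    expect_lt(min(max(abs(p$coordinates[, j] - oracle[, j])),
                  max(abs(p$coordinates[, j] + oracle[, j]))), 1e-8)
  }
  expect_equal(p$variance_explained[1:3],
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-10)
})

test_that("mds_axis places three collinear points equally spaced", {
  # samples at positions 0, 1, 2 on a line: mutual distances 1, 1, 2
  X <- rbind(c(0, 1, 2), c(0, 0, 0))
  ds <- make_ds(X, ages = c(0.1, 0.5, 1))
  m <- mds_axis(ds)
  coords <- m$coordinates[, 1]
  expect_equal(diff(coords), c(1, 1), tolerance = 1e-10)
  expect_lt(coords[1], coords[3])  # youngest has the smaller coordinate
})

test_that("mds_axis equals PCA's first axis up to sign and handles degeneracy", {
  set.seed(53)
  for (rep in 1:5) {
    X <- matrix(rnorm(15 * 7), 15, 7)
    ds <- make_ds(X)
    m <- mds_axis(ds)$coordinates[, 1]
    p <- pca_scores(ds, 1)$coordinates[, 1]
    expect_lt(min(max(abs(m - p)), max(abs(m + p))), 1e-8)
  }
  # duplicated samples get identical coordinates
  X <- matrix(rnorm(10 * 4), 10, 4); X[, 4] <- X[, 1]
  m <- mds_axis(make_ds(X))
  expect_equal(m$coordinates[1, 1], m$coordinates[4, 1], tolerance = 1e-10)
  # all-identical samples: zero axis with warning
  Xf <- matrix(1, 5, 4)
  expect_warning(mz <- mds_axis(make_ds(Xf)), "identical")
  expect_equal(unname(mz$coordinates[, 1]), rep(0, 4))
})

test_that("fraction_change_by_age reads linear, step and sigmoid trajectories", {
  ages <- 0:10
  lin <- make_ds(rbind(ages, 0 * ages), ages = ages)
  axis <- mds_axis(lin)
  expect_equal(fraction_change_by_age(axis, ages, 1), 0.1, tolerance = 1e-10)

  step <- make_ds(rbind(c(0, 5, 5, 5, 5), rep(0, 5)), ages = c(0, 0.5, 2, 3, 4))
  expect_equal(fraction_change_by_age(mds_axis(step), c(0, 0.5, 2, 3, 4), 1), 1.0)

  # sigmoid with inflection at 0.5: fraction by 1.0 matches the closed form
  ages2 <- seq(0, 3, by = 0.25)
  sig <- function(a) 1 / (1 + exp(-8 * (a - 0.5)))
  dsig <- make_ds(rbind(10 * sig(ages2), rep(0, length(ages2))), ages = ages2)
  expected <- (sig(1) - sig(0)) / (sig(3) - sig(0))
  expect_equal(fraction_change_by_age(mds_axis(dsig), ages2, 1), expected,
               tolerance = 1e-8)

  expect_warning(f1 <- fraction_change_by_age(axis, ages, 99), "beyond")
  expect_equal(f1, 1)
})

test_that("fraction_change_by_age is monotone in the cutoff", {
  set.seed(59)
  ages <- sort(runif(12, 0, 5))
  ds <- make_ds(matrix(rnorm(8 * 12), 8, 12), ages = ages)
  axis <- mds_axis(ds)
  cuts <- seq(min(ages), max(ages) - 0.01, length.out = 8)
  fr <- vapply(cuts, function(ct) fraction_change_by_age(axis, ages, ct), numeric(1))
  expect_true(all(diff(fr) >= -1e-12))
})

test_that("ordination is invariant to gene-row permutation", {
  set.seed(61)
  X <- matrix(rnorm(30 * 6), 30, 6,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:6)))
  perm <- sample(30)
  m1 <- mds_axis(make_ds(X))
  m2 <- mds_axis(make_ds(X[perm, ]))
  expect_equal(m1$coordinates, m2$coordinates, tolerance = 1e-10)
})
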