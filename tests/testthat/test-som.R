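# small Gaussian-cluster matrix: k well-separated centers in d dims
gaussian_clusters <- function(n, k = 2, d = 8, sep = 10, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(k * d), k, d)
    centers <- centers / sqrt(rowSums(centers^2)) * sep * (1:k)
    lab <- rep(seq_len(k), length.out = n)
    x <- centers[lab, ] + matrix(rnorm(n * d, sd = sd), n, d)
    rownames(x) <- sprintf("s%03d", seq_len(n))
    list(x = x, labels = lab)
  })
}

test_that("training is deterministic and reduces quantization error", {
  g <- gaussian_clusters(60, k = 2)
  m1 <- som_train(g$x, rows = 6, cols = 10, epochs = 5, seed = 9)
  m2 <- som_train(g$x, rows = 6, cols = 10, epochs = 5, seed = 9)
  expect_identical(m1$weights, m2$weights)
  m3 <- som_train(g$x, rows = 6, cols = 10, epochs = 5, seed = 10)
  expect_false(identical(m1$weights, m3$weights))
  expect_lte(m1$qe[length(m1$qe)], m1$qe[1])
  # quantization error non-increasing at epoch boundaries (<=1% jitter)
  expect_true(all(diff(m1$qe[-1]) <= 0.01 * m1$qe[2:(length(m1$qe) - 1)]))
})

test_that("identical inputs collapse onto a single BMU", {
  x <- matrix(rep(c(0.2, 0.8, 0.5), each = 20), nrow = 20)
  m <- som_train(x, rows = 4, cols = 5, epochs = 3, seed = 2)
  bmus <- apply(x, 1, function(v) paste(som_bmu(m, v), collapse = ","))
  expect_equal(length(unique(bmus)), 1)
})

test_that("bmu agrees with an exhaustive scan and breaks ties lexicographically", {
  g <- gaussian_clusters(40, k = 3, seed = 5)
  m <- som_train(g$x, rows = 5, cols = 7, epochs = 4, seed = 5)
  set.seed(6)
  for (i in 1:100) {
    v <- rnorm(ncol(g$x), sd = 5)
    got <- som_bmu(m, v)
    d2 <- apply(m$weights, 1, function(w) sum((w - v)^2))
    best <- which.min(d2)
    expect_equal(unname(got),
                 c((best - 1) %/% m$cols + 1, (best - 1) %% m$cols + 1))
  }
  # vector equal to a unique node weight maps onto that node
  got <- som_bmu(m, m$weights[17, ])
  expect_equal(unname(got), c((17 - 1) %/% m$cols + 1, (17 - 1) %% m$cols + 1))
  # engineered tie: equidistant nodes resolve to the smaller (row, col)
  mt <- m
  mt$weights[] <- 0
  mt$weights[3, 1] <- 1; mt$weights[10, 1] <- -1
  expect_equal(unname(som_bmu(mt, rep(0, ncol(mt$weights)))), c(1, 1))
  expect_error(som_bmu(m, 1:3), "dimension")
})

test_that("the U-matrix reflects weight-space topography", {
  g <- gaussian_clusters(30, k = 2, seed = 3)
  m <- som_train(g$x, rows = 5, cols = 6, epochs = 3, seed = 3)
  # identical weights -> all-zero U-matrix
  m0 <- m; m0$weights[] <- 1
  expect_true(all(som_umatrix(m0) == 0))
  # homogeneity: scaling the weights scales the U-matrix
  mc <- m; mc$weights <- m$weights * -2.5
  expect_equal(som_umatrix(mc), 2.5 * som_umatrix(m), tolerance = 1e-12)
  expect_true(all(som_umatrix(m) >= 0))
  expect_true(all(som_umatrix(m, connectivity = 4) >= 0))
  # a single discordant node carries the local U-matrix maximum
  md <- m; md$weights[] <- 0; md$weights[8, ] <- 5  # node (2, 2)
  u <- som_umatrix(md)
  expect_equal(unname(which(u == max(u), arr.ind = TRUE)[1, ]), c(2, 2))
})

test_that("two separated clusters occupy disjoint map regions and bins", {
  g <- gaussian_clusters(200, k = 2, d = 8, sep = 10, seed = 7)
  m <- som_train(g$x, epochs = 8, seed = 7)
  bmu <- apply(g$x, 1, function(v) {
    b <- som_bmu(m, v); (b[1] - 1) * m$cols + b[2]
  })
  # BMU node sets of the two classes do not overlap
  expect_length(intersect(unique(bmu[g$labels == 1]),
                          unique(bmu[g$labels == 2])), 0)
  # segmentation recovers the two clusters exactly
  prof <- tibble::tibble(window_id = rownames(g$x),
                         contig_id = rownames(g$x))
  prof <- dplyr::bind_cols(prof, tibble::as_tibble(as.data.frame(g$x)))
  attr(prof, "features") <- colnames(g$x)
  bins <- som_bins(m, prof, quantile = 0.6)
  truth <- tibble::tibble(contig_id = rownames(g$x),
                          genome_id = as.character(g$labels))
  expect_equal(bin_ari(bins, truth), 1.0)
  expect_equal(dplyr::n_distinct(bins$contigs$bin_id), 2)
})

test_that("threshold quantile 1 yields a single bin spanning the torus", {
  g <- gaussian_clusters(50, k = 2, seed = 8)
  m <- som_train(g$x, rows = 5, cols = 8, epochs = 3, seed = 8)
  prof <- tibble::tibble(window_id = rownames(g$x), contig_id = rownames(g$x))
  prof <- dplyr::bind_cols(prof, tibble::as_tibble(as.data.frame(g$x)))
  attr(prof, "features") <- colnames(g$x)
  bins <- som_bins(m, prof, quantile = 1)
  expect_equal(dplyr::n_distinct(bins$windows$bin_id), 1)
  expect_true(all(!is.na(bins$windows$bin_id)))
})

test_that("training is invariant to row permutation up to bin labels", {
  g <- gaussian_clusters(80, k = 2, seed = 12)
  perm <- sample(nrow(g$x))
  m1 <- som_train(g$x, rows = 6, cols = 8, epochs = 4, seed = 4)
  m2 <- som_train(g$x[perm, ], rows = 6, cols = 8, epochs = 4, seed = 4)
  expect_equal(m1$weights, m2$weights)
  b1 <- apply(g$x, 1, function(v) paste(som_bmu(m1, v), collapse = ","))
  b2 <- apply(g$x[perm, ], 1, function(v) paste(som_bmu(m2, v), collapse = ","))
  expect_equal(mclust::adjustedRandIndex(b1, b2[order(perm)]), 1.0)
})

test_that("small-instance bins agree with a k-means oracle", {
  g <- gaussian_clusters(150, k = 3, d = 10, sep = 8, seed = 15)
  m <- som_train(g$x, epochs = 8, seed = 15)
  prof <- tibble::tibble(window_id = rownames(g$x), contig_id = rownames(g$x))
  prof <- dplyr::bind_cols(prof, tibble::as_tibble(as.data.frame(g$x)))
  attr(prof, "features") <- colnames(g$x)
  bins <- som_bins(m, prof)
  km <- withr::with_seed(15, kmeans(g$x, centers = 3, nstart = 10))
  joined <- dplyr::filter(bins$contigs, !is.na(bin_id))
  ari <- mclust::adjustedRandIndex(joined$bin_id,
                                   km$cluster[joined$contig_id])
  expect_gte(ari, 0.9)
})

test_that("degenerate and invalid inputs are handled explicitly", {
  expect_error(som_train(matrix(c(1, NA), 1, 2)), "non-finite")
  expect_warning(m <- som_train(matrix(1:4 / 4, 1, 4), rows = 3, cols = 3,
                                epochs = 2, seed = 1), "single sample")
  expect_s3_class(m, "som_grid")
  gs <- som_grid_size(400)
  expect_gte(gs[1] * gs[2], 160)
})
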