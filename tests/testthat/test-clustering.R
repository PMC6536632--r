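blob_matrix <- function(centers, n = 10, sd = 0.3, seed = 1, dim = 3) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n * dim, rep(centers[i, ], each = n), sd), nrow = n)
  }))
}

test_that("standardization z-scores columns and drops constants", {
  df <- tibble::tibble(id = c("a", "b", "c"), f1 = c(2, 4, 6),
                       f2 = c(1, 1, 1))
  expect_warning(z <- standardize_features(df), "constant")
  expect_equal(z$f1, c(-1, 0, 1), tolerance = 1e-6)
  expect_false("f2" %in% names(z))
  expect_equal(attr(z, "feature_cols"), "f1")

  z2 <- standardize_features(z["f1"])
  expect_equal(z2$f1, z$f1, tolerance = 1e-12) # idempotent
  expect_error(standardize_features(tibble::tibble(a = c(1, 1))), "constant")
})

test_that("PCA by SVD is exact on collinear data and orthonormal in general", {
  line <- cbind(1:10, 2 * (1:10))
  p <- pca_svd(scale(line), n_components = 1)
  expect_equal(p$explained[1], 1, tolerance = 1e-12)

  set.seed(3)
  x <- matrix(rnorm(240), 20, 12)
  p2 <- pca_svd(x, n_components = 5)
  g <- crossprod(p2$loadings)
  expect_lt(max(abs(g - diag(5))), 1e-10)
  # variance fractions against an independent eigen-decomposition
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(p2$explained, ev / sum(ev), tolerance = 1e-10)
  # deterministic sign: largest loading of each component positive
  expect_true(all(apply(p2$loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))
  expect_error(pca_svd(x, n_components = 13), "exceeds")
})

test_that("PCA truncation never increases pairwise distances", {
  set.seed(8)
  x <- matrix(rnorm(15 * 12), 15, 12)
  p <- pca_svd(x, n_components = 3)
  d_full <- as.matrix(dist(x))
  d_proj <- as.matrix(dist(p$scores))
  expect_true(all(d_proj <= d_full + 1e-10))
})

test_that("Ward linkage merges tight pairs first and duplicates at zero", {
  pts <- rbind(c(0, 0), c(0, 0.1), c(10, 10), c(10, 10.1))
  hc <- ward_linkage(pts)
  expect_true(all(hc$merge[1, ] < 0) && all(hc$merge[2, ] < 0))
  expect_true(all(diff(hc$height) >= -1e-12)) # monotone heights

  dup <- rbind(c(1, 1), c(1, 1), c(5, 5))
  expect_equal(ward_linkage(dup)$height[1], 0)
})

test_that("Ward merge heights and partitions match exhaustive enumeration", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(5:8, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    hc <- ward_linkage(x)
    o <- oracle_ward(x)
    expect_equal(sort(hc$height), sort(o$heights), tolerance = 1e-8)
    for (k in 2:(n - 1)) {
      expect_true(same_partition(cutree(hc, k),
                                 o$memberships[[n - k]]),
                  label = sprintf("seed %d k %d", s, k))
    }
  }
})

test_that("silhouette selects the generating number of blobs", {
  x2 <- blob_matrix(rbind(c(0, 0, 0), c(8, 8, 8)), seed = 2)
  r2 <- silhouette_select_k(x2, ward_linkage(x2))
  expect_equal(r2$chosen_k, 2)

  x3 <- blob_matrix(rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 8)), seed = 3)
  r3 <- silhouette_select_k(x3, ward_linkage(x3))
  expect_equal(r3$chosen_k, 3)
  expect_true(all(r3$cell_sil >= -1 & r3$cell_sil <= 1))

  # one diffuse blob split at k = 2 scores below two separated blobs
  x1 <- blob_matrix(rbind(c(0, 0, 0)), n = 20, sd = 1, seed = 4)
  r1 <- silhouette_select_k(x1, ward_linkage(x1), k_range = 2)
  expect_lt(r1$silhouette$mean_sil_width,
            r2$silhouette$mean_sil_width[r2$silhouette$k == 2])
})

test_that("per-cell silhouettes match the direct O(n^2) formula", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(8:12, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    hc <- ward_linkage(x)
    res <- silhouette_select_k(x, hc, k_range = 2:(n - 1))
    for (i in seq_along(res$silhouette$k)) {
      k <- res$silhouette$k[i]
      direct <- oracle_silhouette(cutree(hc, k), x)
      expect_equal(res$silhouette$mean_sil_width[i], mean(direct),
                   tolerance = 1e-10)
    }
  }
})

test_that("correlation-distance Ward equals the update rule on 1 - r", {
  set.seed(11)
  x <- matrix(rnorm(6 * 5), 6, 5)
  hc <- ward_linkage(x, metric = "correlation")
  ref <- hclust(stats::as.dist(1 - cor(t(x))), method = "ward.D2")
  expect_equal(hc$height, ref$height)
  expect_equal(hc$merge, ref$merge)
})

test_that("radar normalization maps cluster means onto [0, 1]", {
  m <- tibble::tibble(cluster = 1:3, f1 = c(2, 4, 6), f2 = c(9, 9, 9),
                      f3 = c(5, 1, 3))
  r <- radar_normalize(m[-1])
  expect_equal(r$f1, c(0, 0.5, 1))
  expect_equal(r$f2, rep(0.5, 3)) # constant-across-clusters convention
  expect_equal(order(r$f3), order(m$f3)) # monotone

  two <- radar_normalize(tibble::tibble(f = c(3, 7)))
  expect_setequal(two$f, c(0, 1))
  expect_error(radar_normalize(tibble::tibble(f = 1)), "two clusters")
})

test_that("cluster_features drops incomplete cells by default and can impute", {
  cohort <- sample_feature_table("three_types", n_per_type = 8, seed = 5)
  cohort$cm_pF[1] <- NA
  res <- cluster_features(cohort)
  expect_equal(res$dropped_cells, cohort$cell_id[1])
  expect_equal(length(res$labels), nrow(cohort) - 1)

  res2 <- cluster_features(cohort, impute = "median")
  expect_equal(length(res2$labels), nrow(cohort))
  expect_s3_class(tidy(res2), "tbl_df")
  expect_named(glance(res2),
               c("n_cells", "chosen_k", "mean_sil_width", "var_explained"))
})
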