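#' Standardize a feature table
#'
#' Scales every numeric feature column to mean 0, SD 1 (z-scores).
#' Constant columns carry no information on this scale and are dropped with
#' a warning. Non-numeric columns (ids, labels) pass through untouched.
#'
#' @param data data frame of cells by features.
#' @param feature_cols columns to standardize; default: all numeric.
#' @return Tibble with standardized feature columns; the selected feature
#'   names are kept in attribute `"feature_cols"`.
#' @export
standardize_features <- function(data, feature_cols = NULL) {
  data <- tibble::as_tibble(data)
  if (nrow(data) < 2) abort("at least two rows are required.")
  feature_cols <- feature_cols %||%
    names(data)[vapply(data, is.numeric, logical(1))]
  sds <- vapply(data[feature_cols], sd, numeric(1))
  const <- feature_cols[sds == 0 | !is.finite(sds)]
  if (length(const) == length(feature_cols)) {
    abort("all feature columns are constant.")
  }
  if (length(const) > 0) {
    warn(paste("dropping constant feature(s):", paste(const, collapse = ", ")))
    data <- data[setdiff(names(data), const)]
    feature_cols <- setdiff(feature_cols, const)
  }
  data[feature_cols] <- lapply(data[feature_cols], function(v) {
    as.numeric(scale(v))
  })
  attr(data, "feature_cols") <- feature_cols
  data
}

#' Principal components by singular value decomposition
#'
#' Centred (not rescaled) PCA of the supplied matrix; standardize first with
#' [standardize_features()] when features live on different scales.
#' Components are ordered by decreasing variance and signs are fixed so the
#' largest-magnitude loading of each component is positive, making scores
#' reproducible bit for bit.
#'
#' @param x numeric matrix or data frame (cells by features).
#' @param n_components number of components to retain.
#' @return A `pca_result`: `scores`, `loadings`, `explained` (variance
#'   fractions over all components), `n_components`.
#' @export
pca_svd <- function(x, n_components = 3) {
  x <- as.matrix(x)
  if (!is.numeric(x)) abort("`x` must be numeric.")
  kmax <- min(nrow(x) - 1, ncol(x))
  if (n_components > kmax) {
    abort(sprintf("n_components = %d exceeds the available %d components.",
                  n_components, kmax))
  }
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  # deterministic sign: largest |loading| positive per component
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  ev <- p$sdev^2
  structure(
    list(scores = p$x[, seq_len(n_components), drop = FALSE],
         loadings = p$rotation[, seq_len(n_components), drop = FALSE],
         explained = ev / sum(ev),
         n_components = n_components),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components, %.1f%% of total variance\n",
              x$n_components,
              100 * sum(x$explained[seq_len(x$n_components)])))
  invisible(x)
}

#' Ward agglomerative clustering
#'
#' Ward's minimum-variance criterion via the Lance-Williams update on
#' squared distances (`hclust` method `"ward.D2"`). The distance is either
#' Euclidean or the correlation distance `1 - Pearson r` between item
#' vectors; the correlation variant is formally non-Euclidean but is applied
#' with the same update rule, as is common in expression-style heatmap
#' pipelines.
#'
#' @param x numeric matrix (items by variables) or a `dist` object.
#' @param metric `"euclidean"` or `"correlation"` (ignored for `dist` input).
#' @param method `hclust` agglomeration variant.
#' @return An `hclust` object.
#' @export
ward_linkage <- function(x, metric = c("euclidean", "correlation"),
                         method = "ward.D2") {
  metric <- match.arg(metric)
  d <- if (inherits(x, "dist")) x else {
    x <- as.matrix(x)
    if (nrow(x) < 2) abort("at least two items are required.")
    if (metric == "euclidean") dist(x) else stats::as.dist(1 - cor(t(x)))
  }
  if (anyNA(d)) abort("distances contain NA.")
  hclust(d, method = method)
}

#' Choose the number of clusters by silhouette analysis
#'
#' Cuts the dendrogram at every k in `k_range`, computes per-cell silhouette
#' widths `s(i) = (b - a) / max(a, b)` with Euclidean distance on the
#' supplied scores (singletons score 0), and picks the k with the largest
#' mean width, breaking ties toward the smaller k.
#'
#' @param scores numeric matrix used for the silhouette distance (typically
#'   the retained PC scores).
#' @param linkage an `hclust` object over the same items.
#' @param k_range candidate cluster numbers.
#' @return A `cluster_result`: `linkage`, `silhouette` table (k, mean
#'   width), `chosen_k`, `labels` (at chosen k), `labels_by_k` matrix,
#'   `cell_sil` per-cell widths at chosen k, and `scores`.
#' @export
silhouette_select_k <- function(scores, linkage, k_range = 2:8) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) abort("empty usable k range.")
  d <- dist(scores)
  labs <- vapply(k_range, function(k) cutree(linkage, k), integer(n))
  sil_mean <- numeric(length(k_range))
  sil_cells <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    s <- cluster::silhouette(labs[, i], d)
    sw <- s[, "sil_width"]
    sil_cells[[i]] <- sw
    sil_mean[i] <- mean(sw)
  }
  best <- which.max(sil_mean) # which.max takes the first maximum: smaller k
  structure(
    list(linkage = linkage,
         silhouette = tibble::tibble(k = k_range, mean_sil_width = sil_mean),
         chosen_k = k_range[best],
         labels = labs[, best],
         labels_by_k = labs,
         cell_sil = sil_cells[[best]],
         scores = scores),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> n = %d, chosen k = %d (mean silhouette %.3f)\n",
              nrow(x$scores), x$chosen_k,
              x$silhouette$mean_sil_width[x$silhouette$k == x$chosen_k]))
  invisible(x)
}

#' Cluster a feature table end to end
#'
#' The full unsupervised classification stage: z-score the features, project
#' on the first `n_pcs` principal components (SVD), Ward-cluster the scores
#' (Euclidean or correlation distance) and choose k by silhouette. Cells
#' with missing features are dropped (default) or median-imputed first.
#'
#' @param data feature table, e.g. from [sample_feature_table()] or
#'   [extract_features()].
#' @param feature_cols feature columns; default: all numeric except obvious
#'   auxiliaries.
#' @param metric clustering distance, `"euclidean"` or `"correlation"`.
#' @param n_pcs retained principal components.
#' @param k_range candidate numbers of clusters.
#' @param impute `"drop"` cells with missing features, or `"median"`.
#' @return A `cluster_result` with extra fields `pca`, `feature_cols`,
#'   `cell_ids`, `dropped_cells`, `data`.
#' @examples
#' cohort <- sample_feature_table("three_types", n_per_type = 10, seed = 1)
#' res <- cluster_features(cohort)
#' glance(res)
#' @export
cluster_features <- function(data, feature_cols = NULL,
                             metric = c("euclidean", "correlation"),
                             n_pcs = 3, k_range = 2:8,
                             impute = c("drop", "median")) {
  metric <- match.arg(metric)
  impute <- match.arg(impute)
  data <- tibble::as_tibble(data)
  feature_cols <- feature_cols %||%
    setdiff(names(data)[vapply(data, is.numeric, logical(1))],
            c("seed", "qc_pass"))
  ids <- if ("cell_id" %in% names(data)) data$cell_id else
    sprintf("cell_%03d", seq_len(nrow(data)))

  complete <- stats::complete.cases(data[feature_cols])
  dropped <- character(0)
  if (impute == "drop") {
    dropped <- ids[!complete]
    data <- data[complete, ]
    ids <- ids[complete]
  } else {
    for (f in feature_cols) {
      v <- data[[f]]
      v[is.na(v)] <- median(v, na.rm = TRUE)
      data[[f]] <- v
    }
  }
  if (nrow(data) < 4) abort("fewer than 4 usable cells.")

  z <- standardize_features(data, feature_cols)
  fc <- attr(z, "feature_cols")
  pca <- pca_svd(as.matrix(z[fc]), n_components = min(n_pcs, nrow(z) - 1,
                                                      length(fc)))
  hc <- ward_linkage(pca$scores, metric = metric)
  res <- silhouette_select_k(pca$scores, hc, k_range)
  res$pca <- pca
  res$feature_cols <- fc
  res$cell_ids <- ids
  res$dropped_cells <- dropped
  res$data <- data
  res
}

#' Broom-style accessors for cluster results
#'
#' `tidy()` gives one row per cell (`cell_id`, `cluster`,
#' `sil_width`); `glance()` the one-row summary (chosen k, mean silhouette,
#' variance explained by the retained components).
#'
#' @param x a `cluster_result`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble::tibble(
    cell_id = x$cell_ids %||% sprintf("cell_%03d", seq_along(x$labels)),
    cluster = x$labels,
    sil_width = x$cell_sil
  )
}

#' @rdname tidy.cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_cells = length(x$labels),
    chosen_k = x$chosen_k,
    mean_sil_width = x$silhouette$mean_sil_width[x$silhouette$k == x$chosen_k],
    var_explained = if (!is.null(x$pca))
      sum(x$pca$explained[seq_len(x$pca$n_components)]) else NA_real_
  )
}

#' @export
autoplot.cluster_result <- function(object, ...) {
  ggplot2::ggplot(object$silhouette,
                  ggplot2::aes(.data$k, .data$mean_sil_width)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 2) +
    ggplot2::labs(x = "number of clusters k", y = "mean silhouette width") +
    ggplot2::theme_minimal()
}

#' Normalize cluster feature means to the 0-1 range
#'
#' Per feature, the smallest cluster mean maps to 0 and the largest to 1
#' (the scaling used for radar displays of cluster profiles); a feature that
#' is constant across clusters maps to 0.5 by convention.
#'
#' @param means data frame of cluster feature means: one row per cluster,
#'   one numeric column per feature (non-numeric columns pass through).
#' @return Tibble of the same shape with features rescaled to `[0, 1]`.
#' @export
radar_normalize <- function(means) {
  means <- tibble::as_tibble(means)
  if (nrow(means) < 2) abort("at least two clusters are required.")
  num <- names(means)[vapply(means, is.numeric, logical(1))]
  means[num] <- lapply(means[num], function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(0.5, length(v)) else (v - rng[1]) / diff(rng)
  })
  means
}

#' Export a dendrogram as Newick text
#'
#' @param linkage an `hclust` object.
#' @param path output file.
#' @param labels optional tip labels.
#' @return The path, invisibly.
#' @export
write_dendrogram_newick <- function(linkage, path, labels = NULL) {
  if (!is.null(labels)) linkage$labels <- labels
  phy <- ape::as.phylo(linkage)
  ape::write.tree(phy, file = path)
  invisible(path)
}
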