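#' Run the electrophysiological classification pipeline
#'
#' End-to-end cohort analysis: quality control, extraction of the 12
#' intrinsic properties per cell, z-scoring, PCA (3 components by default),
#' Ward clustering with Euclidean distance on the PC scores, and
#' silhouette-based choice of the number of cell classes. QC-failed cells
#' stay in the report with their exclusion reasons.
#'
#' @param cells list of [trace_set()] objects, or a directory containing
#'   sweep-table CSVs (see [read_sweep_csv()]).
#' @param criterion_policy criterion-sweep policy for adaptation features.
#' @param k_range candidate numbers of clusters.
#' @param n_pcs retained principal components.
#' @param feature_cols feature columns to cluster on; default: the 12
#'   canonical properties.
#' @param output_dir optional directory; when given, the feature table,
#'   labels, silhouette table and a Newick dendrogram are written there.
#' @param true_types optional named vector (cell_id -> type) of ground
#'   truth; adds a confusion matrix and adjusted Rand index to the report.
#' @return A `cohort_report` list: `features`, `adaptation`, `clustering`
#'   (a `cluster_result`), `assignments`, `qc_failed`, `ari`, `confusion`.
#' @export
run_ephys_pipeline <- function(cells, criterion_policy = "plus50",
                               k_range = 2:8, n_pcs = 3,
                               feature_cols = NULL, output_dir = NULL,
                               true_types = NULL) {
  if (is.character(cells)) {
    paths <- list.files(cells, pattern = "\\.csv$", full.names = TRUE)
    cells <- lapply(paths, read_sweep_csv)
  }
  if (is.null(true_types)) {
    # accept truth carried by synthetic trace sets
    tt <- vapply(cells, function(ts) ts$truth$archetype %||% NA_character_,
                 character(1))
    if (!all(is.na(tt))) {
      true_types <- setNames(tt, vapply(cells, `[[`, "", "cell_id"))
    }
  }
  features <- extract_features(cells, criterion_policy = criterion_policy)
  passing <- dplyr::filter(features, .data$qc_pass)
  if (nrow(passing) < 4) {
    abort(sprintf(
      "fewer than 4 cells passed QC (%d of %d); reasons: %s",
      nrow(passing), nrow(features),
      paste(unique(features$qc_reasons[features$qc_reasons != ""]),
            collapse = "; ")))
  }
  adaptation <- purrr::map_dfr(
    cells[match(passing$cell_id, vapply(cells, `[[`, "", "cell_id"))],
    adaptation_report, criterion_policy = criterion_policy)

  feature_cols <- feature_cols %||% ephys_feature_names()
  feature_cols <- intersect(feature_cols, names(passing))
  res <- cluster_features(passing, feature_cols = feature_cols,
                          metric = "euclidean", n_pcs = n_pcs,
                          k_range = k_range)
  if (glance(res)$mean_sil_width < 0.45) {
    warn(sprintf(
      "weak cluster separation (mean silhouette %.2f at k = %d); the cohort may hold a single population",
      glance(res)$mean_sil_width, res$chosen_k))
  }
  report <- build_report(features, adaptation, res, true_types)
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' Run the morphological classification pipeline
#'
#' Computes the 23 global features per reconstruction, then clusters with
#' the morphology conventions: PCA (3 components) and Ward linkage with
#' correlation distance on the scores; silhouette (Euclidean) selects k.
#' Unreadable SWC files are collected as errors and the run continues while
#' at least 4 trees remain.
#'
#' @param trees list of [neuron_tree()] objects, or paths to SWC files.
#' @param k_range,n_pcs as in [run_ephys_pipeline()].
#' @param output_dir optional output directory.
#' @param true_types optional named vector of ground-truth type labels.
#' @return A `cohort_report`; `$errors` lists unreadable files.
#' @export
run_morph_pipeline <- function(trees, k_range = 2:8, n_pcs = 3,
                               output_dir = NULL, true_types = NULL) {
  errors <- character(0)
  if (is.character(trees)) {
    paths <- trees
    trees <- list()
    for (p in paths) {
      t <- tryCatch(read_swc(p), error = function(e) conditionMessage(e))
      if (is.character(t)) errors[p] <- t else trees[[length(trees) + 1]] <- t
    }
  }
  if (length(trees) < 4) abort("fewer than 4 readable reconstructions.")
  ids <- names(trees) %||% sprintf("tree_%03d", seq_along(trees))
  if (is.null(names(trees))) names(trees) <- ids
  features <- purrr::imap_dfr(trees, function(tr, id) {
    dplyr::bind_cols(tibble::tibble(cell_id = id, qc_pass = TRUE,
                                    qc_reasons = ""),
                     global_morph_features(tr))
  })
  res <- cluster_features(features,
                          feature_cols = intersect(morph_feature_names(),
                                                   names(features)),
                          metric = "correlation", n_pcs = n_pcs,
                          k_range = k_range, impute = "median")
  report <- build_report(features, NULL, res, true_types)
  report$errors <- errors
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

build_report <- function(features, adaptation, res, true_types) {
  assignments <- tidy(res)
  ari <- NA_real_
  confusion <- NULL
  if (!is.null(true_types)) {
    truth <- true_types[assignments$cell_id]
    if (!anyNA(truth)) {
      assignments$true_type <- unname(truth)
      ari <- mclust::adjustedRandIndex(assignments$cluster, truth)
      confusion <- table(cluster = assignments$cluster, true_type = truth)
    }
  }
  structure(
    list(features = features,
         adaptation = adaptation,
         clustering = res,
         assignments = assignments,
         qc_failed = dplyr::filter(features, !.data$qc_pass),
         ari = ari, confusion = confusion),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf(
    "<cohort_report> %d cells (%d failed QC), chosen k = %d%s\n",
    nrow(x$features), nrow(x$qc_failed), x$clustering$chosen_k,
    if (!is.na(x$ari)) sprintf(", ARI vs truth %.3f", x$ari) else ""))
  invisible(x)
}

#' @export
glance.cohort_report <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$clustering),
    tibble::tibble(n_qc_failed = nrow(x$qc_failed), ari = x$ari)
  )
}

write_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$features, file.path(output_dir, "features.csv"))
  if (!is.null(report$adaptation)) {
    readr::write_csv(report$adaptation, file.path(output_dir, "adaptation.csv"))
  }
  readr::write_csv(report$assignments, file.path(output_dir, "labels.csv"))
  readr::write_csv(report$clustering$silhouette,
                   file.path(output_dir, "silhouette.csv"))
  write_dendrogram_newick(report$clustering$linkage,
                          file.path(output_dir, "dendrogram.nwk"),
                          labels = report$clustering$cell_ids)
  cm <- cluster_means(report)
  readr::write_csv(radar_normalize(cm), file.path(output_dir, "radar.csv"))
  invisible(output_dir)
}

# per-cluster feature means on the clustered cells
cluster_means <- function(report) {
  res <- report$clustering
  df <- res$data
  df$cluster <- res$labels
  dplyr::summarise(dplyr::group_by(df, .data$cluster),
                   dplyr::across(dplyr::all_of(res$feature_cols), mean),
                   .groups = "drop")
}

#' Cohort-recovery experiment
#'
#' Samples Gaussian cohorts from the published per-type statistics and runs
#' the full classification stage, recording the silhouette-chosen number of
#' clusters and the adjusted Rand index against the generating types for
#' each seed. The modal chosen k across seeds is the headline result.
#'
#' @param set `"three_types"` (THIN/FANS/MSN) or `"fans_subtypes"` (FANS subtypes).
#' @param n_per_type cells per type (>= 3).
#' @param n_seeds number of replicate cohorts.
#' @param seed master seed; replicate s uses `seed + s - 1`.
#' @param k_range,n_pcs clustering options.
#' @return A `recovery_result`: tibble `results` (seed, chosen_k, ari,
#'   mean_sil), `modal_k`, `set`.
#' @examples
#' rec <- recovery_experiment("three_types", n_per_type = 10, n_seeds = 3)
#' rec$modal_k
#' @export
recovery_experiment <- function(set = c("three_types", "fans_subtypes"),
                                n_per_type = 30, n_seeds = 10, seed = 1,
                                k_range = 2:8, n_pcs = 3) {
  set <- match.arg(set)
  if (n_per_type < 3) abort("`n_per_type` must be >= 3.")
  archs <- striatal_archetypes(set)
  rows <- purrr::map_dfr(seq_len(n_seeds), function(s) {
    cohort <- sample_feature_table(archs, n_per_type = n_per_type,
                                   seed = seed + s - 1)
    res <- cluster_features(cohort, n_pcs = n_pcs, k_range = k_range)
    tibble::tibble(
      seed = seed + s - 1,
      chosen_k = res$chosen_k,
      ari = mclust::adjustedRandIndex(res$labels, cohort$true_type),
      mean_sil = glance(res)$mean_sil_width,
      var_explained = glance(res)$var_explained
    )
  })
  tab <- table(rows$chosen_k)
  structure(
    list(results = rows,
         modal_k = as.integer(names(tab)[which.max(tab)]),
         set = set),
    class = "recovery_result"
  )
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result> %s: modal k = %d over %d seeds (median ARI %.2f)\n",
              x$set, x$modal_k, nrow(x$results), median(x$results$ari)))
  invisible(x)
}

#' @export
glance.recovery_result <- function(x, ...) {
  tibble::tibble(
    set = x$set, n_seeds = nrow(x$results), modal_k = x$modal_k,
    median_ari = median(x$results$ari),
    frac_ari_ge_0.9 = mean(x$results$ari >= 0.9)
  )
}
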