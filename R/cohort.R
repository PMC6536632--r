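#' Sample a Gaussian feature cohort with known type labels
#'
#' Draws `n_per_type` cells per archetype, each feature independently
#' Gaussian around the archetype's population mean. Published tables report
#' SEM, so the population SD is reconstructed as `SEM * sqrt(n_assumed)`
#' (the per-type sample sizes behind the tables are not published; 20 is the
#' package default and is exposed).
#'
#' @param archetypes named list of [archetype()] objects (or the string
#'   `"three_types"` / `"fans_subtypes"` for the built-ins).
#' @param n_per_type cells per type, >= 2.
#' @param seed integer seed.
#' @param n_assumed assumed per-type n for the SEM-to-SD conversion.
#' @param sd_rule optional function `f(sem, n_assumed) -> sd` overriding the
#'   default conversion.
#' @param on_missing what to do when a feature mean is missing for some
#'   type: `"drop"` the feature for all types (with a warning) or `"error"`.
#' @return A tibble with `cell_id`, `true_type` and one column per feature,
#'   in the canonical ordering; extra (non-canonical) features follow.
#' @examples
#' head(sample_feature_table("three_types", n_per_type = 5, seed = 1))
#' @export
sample_feature_table <- function(archetypes = "three_types", n_per_type = 30,
                                 seed = 1, n_assumed = 20, sd_rule = NULL,
                                 on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  if (is.character(archetypes)) {
    archetypes <- striatal_archetypes(archetypes)
  }
  if (n_per_type < 2) abort("`n_per_type` must be >= 2.")
  sd_rule <- sd_rule %||% function(sem, n_assumed) sem * sqrt(n_assumed)

  feats_per_type <- lapply(archetypes, function(a) names(a$feature_means))
  common <- Reduce(intersect, feats_per_type)
  all_feats <- Reduce(union, feats_per_type)
  missing <- setdiff(all_feats, common)
  if (length(missing) > 0) {
    msg <- sprintf("feature(s) %s missing for some types",
                   paste(missing, collapse = ", "))
    if (on_missing == "error") abort(msg)
    warn(paste(msg, "- dropped for all types"))
  }
  canon <- intersect(ephys_feature_names(), common)
  feats <- c(canon, setdiff(common, canon))
  if (length(feats) == 0) abort("no feature is shared by all archetypes.")

  rows <- purrr::imap(archetypes, function(a, ty) {
    mu <- a$feature_means[feats]
    s <- sd_rule(a$feature_sems[feats], n_assumed)
    draws <- with_seed(derive_seed(seed, "cohort", ty), {
      vapply(seq_along(feats), function(j) rnorm(n_per_type, mu[[j]], s[[j]]),
             numeric(n_per_type))
    })
    draws <- matrix(draws, nrow = n_per_type,
                    dimnames = list(NULL, feats))
    dplyr::bind_cols(
      tibble::tibble(
        cell_id = sprintf("%s_%03d", ty, seq_len(n_per_type)),
        true_type = ty
      ),
      tibble::as_tibble(draws)
    )
  })
  dplyr::bind_rows(rows)
}
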