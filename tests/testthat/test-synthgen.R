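test_that("protocol covers every current from min to max inclusive", {
  p <- make_protocol(-200, 200, 10, 1, 20000)
  expect_length(p$currents, 41)
  expect_equal(range(p$currents), c(-200, 200))
  expect_equal(tibble::as_tibble(p)$step_duration_s, rep(1, 41))

  expect_length(make_protocol(-100, 100, 50, 1, 10000)$currents, 5)
  expect_error(make_protocol(100, -100, 10), "current_min")
  expect_error(make_protocol(-100, 100, 0), "current_increment")
  expect_error(make_protocol(-100, 100, 10, step_duration = -1),
               "step_duration")
})

test_that("constant-rate limit of the spike model gives a regular train", {
  p <- spike_model_params(f0 = 50, f_end = 50) # no adaptation
  st <- adapting_spike_times(p, duration = 1, jitter_cv = 0)
  expect_true(abs(length(st) - 50) <= 1)
  expect_equal(unique(round(diff(st), 6)), 0.02)

  p100 <- spike_model_params(f0 = 100, f_end = 100)
  st100 <- adapting_spike_times(p100, duration = 1, jitter_cv = 0)
  expect_equal(diff(st100)[1], 0.01, tolerance = 1e-6)
})

test_that("spike trains respect rheobase and are deterministic without jitter", {
  p <- spike_model_params(rheobase = 40, gain = 1)
  expect_length(adapting_spike_times(p, current = 30, duration = 1), 0)
  # at rheobase the cell fires at least once
  expect_gte(length(adapting_spike_times(p, current = 40, duration = 1,
                                         jitter_cv = 0)), 1)
  a <- adapting_spike_times(p, current = 90, duration = 1, jitter_cv = 0)
  b <- adapting_spike_times(p, current = 90, duration = 1, jitter_cv = 0)
  expect_identical(a, b)
  expect_true(all(diff(a) > 0))
  expect_true(all(a >= 0 & a <= 1))
})

test_that("empirical IF of a deterministic train matches the closed form", {
  p <- spike_model_params(f0 = 80, f_end = 30, w_fast = 0.5,
                          tau_fast = 0.06, tau_slow = 0.45)
  st <- adapting_spike_times(p, duration = 1, jitter_cv = 0)
  ifs <- instantaneous_frequency_series(st)
  model <- striocell:::spike_rate(ifs$t_s + st[1], p)
  expect_lt(max(abs(ifs$if_Hz - model) / model), 0.01)
})

test_that("adaptation taus survive a generate-refit round trip within 2%", {
  p <- spike_model_params(f0 = 60, f_end = 25, w_fast = 0.4,
                          tau_fast = 0.05, tau_slow = 0.5)
  st <- adapting_spike_times(p, duration = 1.5, jitter_cv = 0)
  ifs <- instantaneous_frequency_series(st)
  fit <- fit_adaptation_exponential(ifs$t_s, ifs$if_norm, 2)
  expect_true(fit$converged)
  expect_lt(abs(fit$taus[1] - 0.05) / 0.05, 0.02)
  expect_lt(abs(fit$taus[2] - 0.5) / 0.5, 0.02)
})

test_that("feature cohorts reproduce the published means and are reproducible", {
  big <- sample_feature_table("three_types", n_per_type = 10000, seed = 7)
  thin <- dplyr::filter(big, true_type == "THIN")
  expect_lt(abs(mean(thin$r_in_MOhm) - 328) / 328, 0.02)
  # law of large numbers at 3 sigma for every column of every type
  archs <- striatal_archetypes("three_types")
  for (ty in names(archs)) {
    rows <- dplyr::filter(big, true_type == ty)
    mu <- archs[[ty]]$feature_means[ephys_feature_names()]
    s <- archs[[ty]]$feature_sems[ephys_feature_names()] * sqrt(20)
    for (f in ephys_feature_names()) {
      expect_lt(abs(mean(rows[[f]]) - mu[[f]]), 3 * s[[f]] / sqrt(10000))
    }
  }
  expect_identical(sample_feature_table("three_types", 10, seed = 3),
                   sample_feature_table("three_types", 10, seed = 3))
})

test_that("zero SEMs collapse each type onto its mean vector", {
  cohort <- sample_feature_table("three_types", n_per_type = 5, seed = 1,
                                 sd_rule = function(sem, n) sem * 0)
  per_type <- dplyr::count(
    dplyr::distinct(dplyr::select(cohort, -"cell_id")), true_type)
  expect_true(all(per_type$n == 1))
})

test_that("features missing for some types are dropped with a warning", {
  archs <- c(striatal_archetypes("three_types")["THIN"],
             striatal_archetypes("fans_subtypes")["I"])
  expect_warning(tab <- sample_feature_table(archs, n_per_type = 3, seed = 1),
                 "missing")
  expect_false("ap_freq_adaptation" %in% names(tab)) # absent for subtype I
  expect_true("r_in_MOhm" %in% names(tab))
  expect_error(sample_feature_table(archs, 3, seed = 1, on_missing = "error"),
               "missing")
})

test_that("rendered recordings are reproducible and quiet at 0 pA", {
  arch <- striatal_archetypes()$FANS
  proto <- make_protocol(-50, 50, 50, 1, 10000)
  a <- render_recording(arch, proto, seed = 5)
  b <- render_recording(arch, proto, seed = 5)
  expect_identical(a$voltages, b$voltages)
  v0 <- a$voltages[, "I_0"]
  expect_lt(max(abs(v0 - arch$passive$rmp)), 5 * arch$passive$noise_sd)
})

test_that("rendered FANS amplitude adaptation and THIN sag hit the published values", {
  proto <- fast_protocol()
  fans <- extract_feature_vector(
    render_recording(striatal_archetypes()$FANS, proto, seed = 2))
  expect_lt(abs(fans$ap_amp_adaptation - 0.76), 0.05)
  thin <- extract_feature_vector(
    render_recording(striatal_archetypes()$THIN, proto, seed = 2))
  expect_lt(abs(thin$sag_mV - 4.4) / 4.4, 0.10)
})

test_that("unbranched growth yields a single tip and spines follow their rate", {
  spec <- morph_archetype(n_stems = 1, branch_prob_per_um = 0,
                          mean_branch_len = 1e6, tree_extent = 100)
  tr <- generate_swc(spec, seed = 1)
  f <- global_morph_features(tr)
  expect_equal(f$n_bifurcations, 0)
  expect_equal(f$n_tips, 1)

  spec_sp <- morph_archetype(n_stems = 4, branch_prob_per_um = 0.01,
                             spine_density = 0.5, tree_extent = 150)
  tr_sp <- generate_swc(spec_sp, seed = 2)
  L <- sum(tr_sp$nodes$comp_length[tr_sp$nodes$type == 3])
  n_spines <- sum(tr_sp$nodes$type == 8)
  expect_lt(abs(n_spines - 0.5 * L), 3 * sqrt(0.5 * L)) # Poisson 3 sigma

  tr_aspiny <- generate_swc(morph_archetype(spine_density = 0), seed = 3)
  expect_equal(sum(tr_aspiny$nodes$type == 8), 0)
  expect_error(morph_archetype(n_stems = 0), "n_stems")
})

test_that("render-extract round trip holds across seeds and archetypes", {
  archs <- striatal_archetypes()
  proto <- fast_protocol()
  for (nm in names(archs)) {
    feats <- purrr::map_dfr(1:3, function(s) {
      extract_feature_vector(render_recording(archs[[nm]], proto, seed = s))
    })
    mu <- archs[[nm]]$feature_means
    for (f in c("r_in_MOhm", "rmp_mV", "cm_pF", "ap_amplitude_mV",
                "ap_half_width_ms", "ap_freq_adaptation",
                "ap_amp_adaptation")) {
      expect_lt(abs(mean(feats[[f]]) - mu[[f]]) / abs(mu[[f]]), 0.10,
                label = sprintf("%s %s relative error", nm, f))
    }
  }
})
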