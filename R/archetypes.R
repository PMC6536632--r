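#' Canonical names of the 12 intrinsic electrical properties
#'
#' Column order of every feature table produced by this package: membrane
#' capacitance, input resistance, resting potential, sag, AHP, AP amplitude,
#' AP frequency adaptation, AP amplitude adaptation, AP half-width, maximum
#' fall rate, maximum rise rate and current threshold.
#'
#' @return Character vector of length 12.
#' @export
ephys_feature_names <- function() {
  c("cm_pF", "r_in_MOhm", "rmp_mV", "sag_mV", "ahp_mV", "ap_amplitude_mV",
    "ap_freq_adaptation", "ap_amp_adaptation", "ap_half_width_ms",
    "max_fall_mV_per_ms", "max_rise_mV_per_ms", "current_threshold_pA")
}

# Published population means +/- SEM for the three striatal cell types
# (THIN / FANS / MSN, ChR2+ column for MSN). AP rise rates and current
# thresholds are not published for these types; the values used here are set
# once from physiology (narrow-spiking interneurons have steep spike
# upstrokes; MSN sit hyperpolarized with low input resistance, hence a high
# rheobase). Maximum fall rates follow from the triangular AP template used
# by the renderer: |fall| = (amp/2) / (half_width - amp / (2 * rise)).
three_type_stats <- function() {
  rise <- c(THIN = 280, FANS = 130, MSN = 180)
  amp <- c(78.7, 90.2, 87.6)
  hw <- c(1.47, 3.20, 2.34)
  fall <- -(amp / 2) / (hw - amp / (2 * rise))
  tibble::tribble(
    ~feature, ~THIN, ~FANS, ~MSN, ~THIN_sem, ~FANS_sem, ~MSN_sem,
    "cm_pF", 34.7, 76.6, 131, 2.0, 2.4, 6.5,
    "r_in_MOhm", 328, 262, 90.8, 14.5, 17.0, 7.6,
    "rmp_mV", -63.9, -73.6, -84.1, 1.2, 1.5, 1.5,
    "sag_mV", 4.4, 1.5, 0.5, 0.8, 0.2, 0.1,
    "ahp_mV", -14.9, -7.4, -10.0, 0.9, 0.7, 0.7,
    "ap_amplitude_mV", 78.7, 90.2, 87.6, 2.6, 1.5, 2.1,
    "ap_freq_adaptation", 0.30, 0.34, 0.18, 0.04, 0.03, 0.04,
    "ap_amp_adaptation", 0.47, 0.76, 0.90, 0.03, 0.02, 0.01,
    "ap_half_width_ms", 1.47, 3.20, 2.34, 0.06, 0.14, 0.07,
    "max_fall_mV_per_ms", fall[[1]], fall[[2]], fall[[3]],
    abs(fall[[1]]) * 0.05, abs(fall[[2]]) * 0.05, abs(fall[[3]]) * 0.05,
    "max_rise_mV_per_ms", 280, 130, 180, 15, 10, 12,
    "current_threshold_pA", 30, 40, 150, 4, 4, 12,
    "ap_duration_adaptation", 2.82, 1.68, 1.14, 0.31, 0.09, 0.02
  )
}

# Published means +/- SEM for the three FANS subtypes. Only the ten printed
# properties are carried; "maximum AP frequency adaptation" is an absolute
# drop in Hz, a different quantity from the adaptation ratio, and is kept
# under its own name.
fans_subtype_stats <- function() {
  tibble::tribble(
    ~feature, ~I, ~II, ~III, ~I_sem, ~II_sem, ~III_sem,
    "cm_pF", 76.8, 81.7, 73.3, 3.4, 7.0, 3.1,
    "r_in_MOhm", 275, 164, 312, 21, 18, 29,
    "rmp_mV", -74.0, -82.1, -66.2, 1.7, 2.3, 2.1,
    "sag_mV", 1.8, 1.4, 1.3, 0.5, 0.3, 0.1,
    "ahp_mV", -3.7, -5.1, -3.1, 0.6, 1.7, 0.9,
    "ap_amplitude_mV", 100, 83.6, 83.1, 1.3, 2.9, 2.1,
    "ap_amp_adaptation", 0.75, 0.63, 0.82, 0.02, 0.04, 0.02,
    "ap_half_width_ms", 3.3, 3.0, 2.8, 0.1, 0.2, 0.1,
    "current_threshold_pA", 43.5, 27.5, 35.0, 2.5, 6.4, 4.6,
    "max_freq_adaptation_Hz", 45.8, 26.6, 46.3, 6.3, 14, 6.7
  )
}

#' Construct a cell-type archetype
#'
#' An archetype bundles the published population feature statistics of one
#' neuron type with the generative model parameters (passive membrane, spike
#' train, AP template, plateau probability, morphology) needed to render
#' synthetic recordings of that type. The spike-train end ratios are
#' calibrated at construction so that feature extraction at the criterion
#' current (rheobase + 50 pA) recovers the target adaptation statistics.
#'
#' @param name type label.
#' @param feature_means,feature_sems named numeric vectors of population
#'   means and SEMs (canonical feature names).
#' @param passive a [passive_model_params()] object (its `sag_fraction` is
#'   re-solved from the `sag_mV` target when present).
#' @param rheobase,gain,w_fast,tau_fast,tau_slow spike-train model inputs
#'   (pA, Hz/pA, -, s, s).
#' @param duration_adaptation target last/first AP half-width ratio.
#' @param threshold_v AP threshold voltage (mV) used by the renderer.
#' @param onset_latency latency from step onset to the first spike (s).
#' @param plateau_prob probability that a cell of this type generates a
#'   post-stimulus plateau potential.
#' @param morph a [morph_archetype()] or `NULL`.
#' @return An `archetype` object.
#' @export
archetype <- function(name, feature_means, feature_sems,
                      passive, rheobase, gain,
                      w_fast = 0.4, tau_fast = 0.05, tau_slow = 0.5,
                      duration_adaptation = 1.5,
                      threshold_v = -45, onset_latency = 0.003,
                      plateau_prob = 0, morph = NULL) {
  stopifnot(is.character(name), inherits(passive, "passive_model_params"))
  if (any(feature_sems < 0)) abort("feature SEMs must be >= 0")
  if (any(!is.finite(feature_means))) abort("feature means must be finite")
  sag_target <- feat(feature_means, "sag_mV", 0)
  if (is.finite(sag_target) && sag_target > 0) {
    passive$sag_fraction <- solve_sag_fraction(sag_target, passive)
  }
  spiking <- calibrate_spiking(
    feature_means, rheobase = rheobase, gain = gain, w_fast = w_fast,
    tau_fast = tau_fast, tau_slow = tau_slow,
    duration_adaptation = duration_adaptation,
    onset_latency = onset_latency
  )
  structure(
    list(name = name,
         feature_means = feature_means, feature_sems = feature_sems,
         passive = passive, spiking = spiking,
         duration_adaptation = duration_adaptation,
         threshold_v = threshold_v, onset_latency = onset_latency,
         plateau_prob = plateau_prob, morph = morph),
    class = "archetype"
  )
}

#' @export
print.archetype <- function(x, ...) {
  cat(sprintf("<archetype> %s: rmp %g mV, R_in %g MOhm, rheobase %g pA\n",
              x$name, x$passive$rmp, x$passive$r_in, x$spiking$rheobase))
  invisible(x)
}

# triangular AP template geometry (ms) implied by the waveform targets
ap_template_geometry <- function(feature_means) {
  amp0 <- feat(feature_means, "ap_amplitude_mV", 85)
  ahp <- abs(feat(feature_means, "ahp_mV", 10))
  hw <- feat(feature_means, "ap_half_width_ms", 2)
  rise_rate <- feat(feature_means, "max_rise_mV_per_ms", amp0 / 0.5)
  t_rise <- amp0 / rise_rate
  t_fall <- (hw - t_rise / 2) * (amp0 + ahp) / (amp0 / 2)
  if (t_fall <= 0) abort("AP half-width too small for the chosen rise rate")
  list(amp0 = amp0, ahp = ahp, rise_rate = rise_rate,
       t_rise = t_rise, t_fall = t_fall)
}

# drop trailing spikes whose (broadened) waveform cannot complete before
# stimulus offset; the renderer and the calibration share this rule
complete_spikes <- function(st, geom, duration_adaptation, duration) {
  margin <- (geom$t_rise + geom$t_fall) * max(duration_adaptation, 1) / 1000
  st[st <= duration - margin]
}

# Solve the spike-model end parameters so that the standard estimators
# (1 - last-3/first-2 IF means; last/first amplitude and width ratios)
# evaluated on the deterministic train at rheobase + 50 pA hit the targets.
calibrate_spiking <- function(tg, rheobase, gain, w_fast, tau_fast, tau_slow,
                              duration_adaptation, onset_latency,
                              duration = 1) {
  f0 <- gain * 50
  crit <- rheobase + 50
  geom <- ap_template_geometry(tg)
  base <- function(f_end) {
    spike_model_params(
      f0 = f0, f_end = f_end, w_fast = w_fast,
      tau_fast = tau_fast, tau_slow = tau_slow,
      amp0 = feat(tg, "ap_amplitude_mV", 85),
      width0 = feat(tg, "ap_half_width_ms", 2),
      rheobase = rheobase, gain = gain
    )
  }
  alpha_target <- feat(tg, "ap_freq_adaptation", 0)
  alpha_of <- function(f_end) {
    st <- adapting_spike_times(base(f_end), current = crit,
                               duration = duration, jitter_cv = 0,
                               onset_latency = onset_latency)
    st <- complete_spikes(st, geom, duration_adaptation, duration)
    iv <- 1 / diff(st)
    1 - mean(tail(iv, 3)) / mean(head(iv, 2))
  }
  f_end <- if (alpha_target <= 0) f0 else {
    uniroot(function(fe) alpha_of(fe) - alpha_target,
            c(f0 * 0.02, f0 * 0.999), tol = 1e-6)$root
  }
  params <- base(f_end)

  st <- adapting_spike_times(params, current = crit, duration = duration,
                             jitter_cv = 0, onset_latency = onset_latency)
  st <- complete_spikes(st, geom, duration_adaptation, duration)
  h1 <- 1 # kernel at the first spike (time base starts there)
  hn <- adaptation_kernel(st[length(st)] - st[1], params)
  solve_end <- function(target) {
    # target = (e + (1-e) hn) / (e + (1-e) h1) with h1 = 1
    (target - hn) / (1 - hn)
  }
  amp_target <- feat(tg, "ap_amp_adaptation", 1)
  params$amp_ratio_end <- solve_end(amp_target)
  if (params$amp_ratio_end <= 0) {
    abort("amplitude adaptation target too strong for these time constants")
  }
  # the half-width read off the template depends on amplitude as well
  # (smaller spikes cross half-maximum earlier on the fall), so the width
  # scale needed to hit the measured duration-adaptation target is corrected
  # by the template geometry
  hw_of <- function(a) {
    a / (2 * geom$rise_rate) + geom$t_fall * (a / 2) / (a + geom$ahp)
  }
  a_n <- geom$amp0 * amp_target
  w_req <- duration_adaptation * hw_of(geom$amp0) / hw_of(a_n)
  params$width_ratio_end <- solve_end(w_req)
  params
}

#' Built-in archetypes of the three striatal cell types
#'
#' Returns fully calibrated archetypes for THIN, FANS and MSN parameterized
#' by their published population statistics, or Gaussian-only archetypes for
#' the three FANS subtypes (`set = "fans_subtypes"`; those carry feature
#' statistics for cohort sampling but no morphology).
#'
#' @param set `"three_types"` (THIN/FANS/MSN) or `"fans_subtypes"` (FANS I/II/III).
#' @return Named list of [archetype()] objects.
#' @examples
#' names(striatal_archetypes())
#' @export
striatal_archetypes <- function(set = c("three_types", "fans_subtypes")) {
  set <- match.arg(set)
  tab <- if (set == "three_types") three_type_stats() else fans_subtype_stats()
  types <- setdiff(names(tab), c("feature", grep("_sem$", names(tab), value = TRUE)))

  cfg3 <- list(
    THIN = list(gain = 0.9, w_fast = 0.5, tau_fast = 0.045, tau_slow = 0.35,
                onset_latency = 0.003, plateau_prob = 0.25,
                morph = morph_archetype(n_stems = 3, branch_prob_per_um = 0.006,
                                        mean_branch_len = 120, spine_density = 0,
                                        soma_radius = 13.7 / 2, tree_extent = 180)),
    FANS = list(gain = 1.0, w_fast = 0.4, tau_fast = 0.10, tau_slow = 0.60,
                onset_latency = 0.005, plateau_prob = 0.3,
                morph = morph_archetype(n_stems = 4, branch_prob_per_um = 0.010,
                                        mean_branch_len = 130, spine_density = 0.52,
                                        soma_radius = 15.5 / 2, tree_extent = 160)),
    MSN = list(gain = 0.5, w_fast = 0.4, tau_fast = 0.08, tau_slow = 0.50,
               onset_latency = 0.020, plateau_prob = 0,
               morph = morph_archetype(n_stems = 5, branch_prob_per_um = 0.022,
                                       mean_branch_len = 160, spine_density = 0.57,
                                       soma_radius = 13.8 / 2, tree_extent = 150))
  )
  # subtype rendering knobs (cohort sampling is what fans_subtypes is used for;
  # rendering parameters are FANS-like)
  cfg4 <- list(
    I = list(gain = 1.0, w_fast = 0.4, tau_fast = 0.10, tau_slow = 0.60,
             onset_latency = 0.005, plateau_prob = 0.1, morph = NULL),
    II = list(gain = 0.8, w_fast = 0.4, tau_fast = 0.10, tau_slow = 0.60,
              onset_latency = 0.005, plateau_prob = 0.1, morph = NULL),
    III = list(gain = 1.1, w_fast = 0.4, tau_fast = 0.10, tau_slow = 0.60,
               onset_latency = 0.005, plateau_prob = 0.7, morph = NULL)
  )
  cfg <- if (set == "three_types") cfg3 else cfg4

  out <- lapply(types, function(ty) {
    means <- setNames(tab[[ty]], tab$feature)
    sems <- setNames(tab[[paste0(ty, "_sem")]], tab$feature)
    dur_ad <- feat(means, "ap_duration_adaptation", 1.5)
    keep <- setdiff(names(means), "ap_duration_adaptation")
    cm <- means[["cm_pF"]]
    rin <- means[["r_in_MOhm"]]
    pp <- passive_model_params(
      rmp = means[["rmp_mV"]], r_in = rin, tau_m = cm * rin / 1000,
      sag_tau = 40
    )
    cc <- cfg[[ty]]
    archetype(
      name = ty,
      feature_means = means[keep], feature_sems = sems[keep],
      passive = pp,
      rheobase = feat(means, "current_threshold_pA", 40),
      gain = cc$gain, w_fast = cc$w_fast,
      tau_fast = cc$tau_fast, tau_slow = cc$tau_slow,
      duration_adaptation = dur_ad,
      onset_latency = cc$onset_latency,
      plateau_prob = cc$plateau_prob,
      morph = cc$morph
    )
  })
  setNames(out, types)
}
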