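triangle_spike <- function(rate = 20000, thr = -40, peak = 40, rise_ms = 1,
                           fall_ms = 1, base = -70, trough = NULL) {
  dt <- 1000 / rate
  nr <- round(rise_ms / dt); nf <- round(fall_ms / dt)
  if (is.null(trough)) trough <- thr
  v <- c(rep(base, 200), seq(base, thr, length.out = 200),
         thr + (peak - thr) * (1:nr) / nr,
         peak - (peak - trough) * (1:nf) / nf,
         rep(trough, 200))
  list(v = v, time = seq_along(v) / rate)
}

test_that("AP detection finds rendered spikes and nothing on flat traces", {
  t <- seq(0, 1, by = 5e-5)
  expect_length(detect_aps(rep(-70, length(t)), t), 0)

  one <- triangle_spike()
  expect_length(detect_aps(one$v, one$time), 1)
  two <- list(v = c(one$v, one$v), time = seq_len(2 * length(one$v)) / 20000)
  expect_length(detect_aps(two$v, two$time), 2)
})

test_that("detection count equals generator ground truth on rendered sweeps", {
  arch <- striatal_archetypes()$FANS
  proto <- make_protocol(90, 200, 110, 1, 20000) # two suprathreshold sweeps
  for (s in 1:20) {
    ts <- render_recording(arch, proto, seed = s)
    w <- which(ts$time >= 0 & ts$time < 1)
    for (j in seq_along(ts$currents)) {
      n_det <- length(detect_aps(ts$voltages[w, j], ts$time[w]))
      expect_equal(n_det, length(ts$truth$spike_times[[j]]),
                   label = sprintf("seed %d sweep %g pA", s, ts$currents[j]))
    }
  }
})

test_that("waveform metrics follow from triangle geometry", {
  # symmetric triangle: 1 ms rise to +40, 1 ms fall back to threshold
  sym <- triangle_spike(thr = -40, peak = 40, rise_ms = 1, fall_ms = 1)
  m <- ap_waveform_metrics(sym$v, sym$time, detect_aps(sym$v, sym$time)[1])
  expect_equal(m$amplitude, 80, tolerance = 0.02)
  expect_equal(m$half_width_ms, 1.0, tolerance = 0.02)
  expect_equal(m$max_rise, 80, tolerance = 0.02)   # 80 mV per 1 ms
  expect_equal(m$max_fall, -80, tolerance = 0.02)

  # with a post-spike trough at -54 mV the AHP is trough minus threshold
  tr <- triangle_spike(thr = -40, peak = 40, trough = -54)
  m2 <- ap_waveform_metrics(tr$v, tr$time, detect_aps(tr$v, tr$time)[1])
  expect_equal(m2$ahp, -14, tolerance = 0.05)
})

test_that("I-V fit returns the exact line for noiseless points", {
  ts <- flat_trace_set(currents = c(-200, -100, 0), rmp = -70, r_in = 100)
  iv <- fit_iv_passive(ts)
  expect_equal(iv$r_in_MOhm, 100, tolerance = 1e-10)
  expect_equal(iv$rmp_mV, -70, tolerance = 1e-10)

  one <- flat_trace_set(currents = -100)
  expect_error(fit_iv_passive(one), "two usable")
})

test_that("I-V estimates stay within 3 standard errors under noise", {
  set.seed(42)
  deviations <- replicate(100, {
    ts <- flat_trace_set(currents = seq(-200, 0, by = 50), rmp = -70,
                         r_in = 100, rate = 1000)
    ts$voltages <- ts$voltages + rnorm(length(ts$voltages), 0, 0.5)
    iv <- fit_iv_passive(ts)
    c(iv$r_in_MOhm - 100, iv$rmp_mV + 70)
  })
  # steady state averages 100 samples at 1 kHz -> per-point SE 0.05 mV
  se_slope <- 0.05 / sqrt(sum((seq(-200, 0, 50) - (-100))^2)) * 1000
  se_int <- 0.05 * sqrt(1 / 5 + 100^2 / sum((seq(-200, 0, 50) + 100)^2))
  expect_lt(abs(mean(deviations[1, ])), 3 * se_slope / sqrt(100))
  expect_lt(abs(mean(deviations[2, ])), 3 * se_int / sqrt(100))
})

test_that("sag is the trough-to-steady-state difference near -100 mV", {
  # constructed sweep: trough -104.6, steady state -100.2
  rate <- 5000
  time <- seq(-0.1, 1.2, by = 1 / rate)
  v <- rep(-70, length(time))
  on <- time >= 0 & time < 1
  v[on] <- -100.2
  v[time >= 0.05 & time < 0.15] <- -104.6
  ts <- trace_set("c", time, cbind(I_m100 = v), -100)
  expect_equal(measure_sag(ts), 4.4, tolerance = 1e-6)

  # monotonic charging has no rebound
  ts2 <- flat_trace_set(currents = c(-150, -100, -50))
  expect_lt(measure_sag(ts2), 0.05)
  expect_true(is.na(measure_sag(flat_trace_set(currents = c(0, 50)))))
})

test_that("THIN sag exceeds MSN sag on rendered cells for every seed", {
  proto <- make_protocol(-200, 0, 25, 1, 10000)
  archs <- striatal_archetypes()
  for (s in 1:5) {
    thin <- measure_sag(render_recording(archs$THIN, proto, seed = s))
    msn <- measure_sag(render_recording(archs$MSN, proto, seed = s))
    expect_gt(thin, msn)
  }
})

test_that("membrane time constant and capacitance follow tau / R", {
  rate <- 10000
  time <- seq(-0.1, 1.2, by = 1 / rate)
  on <- time >= 0 & time < 1
  v <- rep(-70, length(time))
  v[on] <- -70 - 10 * (1 - exp(-time[on] * 1000 / 20)) # tau 20 ms
  v[time >= 1] <- -80 + 10 * (1 - exp(-(time[time >= 1] - 1) * 1000 / 20))
  ts <- trace_set("c", time, cbind(I_m50 = v), -50)
  out <- measure_tau_cm(ts, r_in = 200)
  expect_equal(out$tau_m_ms, 20, tolerance = 0.01)
  expect_equal(out$cm_pF, 100, tolerance = 0.01 * 100)

  flat <- flat_trace_set(currents = c(-1, 0)) # sub-mV deflection
  expect_true(is.na(measure_tau_cm(flat, r_in = 100)$tau_m_ms))
})

test_that("current threshold is the smallest spiking sweep", {
  arch <- striatal_archetypes()$FANS # rheobase 40 pA
  ts <- render_recording(arch, fast_protocol(), seed = 4)
  expect_equal(current_threshold(ts), 40)
  expect_true(is.na(current_threshold(flat_trace_set())))

  # spikes only at the largest current
  sp <- triangle_spike(rate = 5000)
  time <- seq(-0.1, 1.2, by = 1 / 5000)
  quiet <- rep(-70, length(time))
  spiky <- quiet
  spiky[seq_along(sp$v) + sum(time < 0)] <- sp$v
  ts2 <- trace_set("c", time, cbind(I_100 = quiet, I_200 = spiky),
                   c(100, 200))
  expect_equal(current_threshold(ts2), 200)
})

test_that("QC applies the standard exclusion rules", {
  expect_false(qc_filter(list(series_resistance_MOhm = 30, rmp_mV = -70,
                              drift_fraction = 0.05))$pass)
  expect_match(qc_filter(list(series_resistance_MOhm = 30, rmp_mV = -70,
                              drift_fraction = 0.05))$reasons,
               "series resistance")
  expect_match(qc_filter(list(series_resistance_MOhm = 20, rmp_mV = -45,
                              drift_fraction = 0.05))$reasons, "RMP")
  expect_true(qc_filter(list(series_resistance_MOhm = 20, rmp_mV = -70,
                             drift_fraction = 0.05))$pass)
  miss <- qc_filter(list(series_resistance_MOhm = 20))
  expect_false(miss$pass)
  expect_match(miss$reasons, "missing-metadata")
})

test_that("feature extraction is deterministic and degrades gracefully", {
  arch <- striatal_archetypes()$THIN
  ts <- render_recording(arch, fast_protocol(), seed = 9)
  expect_identical(extract_feature_vector(ts), extract_feature_vector(ts))

  # no suprathreshold sweep: passive fields live, AP fields flagged NA
  proto_sub <- make_protocol(-100, 0, 50, 1, 10000)
  sub <- render_recording(arch, proto_sub, seed = 1)
  fv <- extract_feature_vector(sub)
  expect_false(is.na(fv$r_in_MOhm))
  expect_false(is.na(fv$sag_mV))
  expect_true(is.na(fv$ap_amplitude_mV))
  expect_true(is.na(fv$current_threshold_pA))
})

test_that("noiseless passive recovery is tight (1% R_in, 0.5 mV RMP, 5% sag)", {
  archs <- striatal_archetypes()
  proto <- fast_protocol()
  for (nm in names(archs)) {
    ts <- render_recording(archs[[nm]], proto, seed = 6, noise_sd = 0,
                           jitter_cv = 0)
    fv <- extract_feature_vector(ts)
    pp <- archs[[nm]]$passive
    expect_lt(abs(fv$r_in_MOhm - pp$r_in) / pp$r_in, 0.01)
    expect_lt(abs(fv$rmp_mV - pp$rmp), 0.5)
    sag_t <- archs[[nm]]$feature_means[["sag_mV"]]
    expect_lt(abs(fv$sag_mV - sag_t) / sag_t, 0.05)
  }
})

test_that("extracted feature means preserve the published type ordering", {
  archs <- striatal_archetypes()
  proto <- fast_protocol()
  means <- purrr::map_dfr(names(archs), function(nm) {
    feats <- purrr::map_dfr(1:3, function(s) {
      extract_feature_vector(render_recording(archs[[nm]], proto, seed = s))
    })
    dplyr::summarise(feats, type = nm,
                     rmp = mean(.data$rmp_mV), cm = mean(.data$cm_pF))
  })
  m <- split(means, means$type)
  expect_gt(m$THIN$rmp, m$FANS$rmp)
  expect_gt(m$FANS$rmp, m$MSN$rmp)
  expect_lt(m$THIN$cm, m$FANS$cm)
  expect_lt(m$FANS$cm, m$MSN$cm)
})
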