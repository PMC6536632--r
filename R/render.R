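#' Render a synthetic current-clamp recording of one cell
#'
#' Composes, for every sweep of the protocol, the passive membrane response
#' (RC charging with sag on hyperpolarizing steps) and, above rheobase, an
#' adapting spike train rendered with a threshold-anchored triangular AP
#' template whose amplitude decays and width grows along the cell's
#' adaptation kernel. Cells drawn with a plateau hold the membrane near
#' -35 mV for 100 ms after stimulus offset before relaxing to rest.
#'
#' @param arch an [archetype()].
#' @param protocol a [make_protocol()] object.
#' @param seed integer seed; identical seeds give identical traces.
#' @param cell_id label for the rendered cell.
#' @param noise_sd overrides the archetype's recording noise SD (mV).
#' @param jitter_cv overrides the interspike-interval jitter CV.
#' @return A [trace_set()] whose `truth` field records the generating
#'   parameters and per-sweep spike times.
#' @examples
#' arch <- striatal_archetypes()$THIN
#' ts <- render_recording(arch, make_protocol(sampling_rate = 10000), seed = 1)
#' @export
render_recording <- function(arch, protocol, seed = 1, cell_id = NULL,
                             noise_sd = NULL, jitter_cv = 0.05) {
  stopifnot(inherits(arch, "archetype"), inherits(protocol, "step_protocol"))
  noise_sd <- noise_sd %||% arch$passive$noise_sd
  cell_id <- cell_id %||% sprintf("%s_%05d", arch$name, seed)
  sp <- arch$spiking
  pp <- arch$passive
  rate <- protocol$sampling_rate
  dt_ms <- 1000 / rate

  # template geometry (ms): linear rise at the target rise rate, linear fall
  # whose slope yields the target half-width
  geom <- ap_template_geometry(arch$feature_means)
  amp0 <- geom$amp0
  ahp <- geom$ahp
  t_rise <- geom$t_rise
  t_fall <- geom$t_fall
  if (t_rise / dt_ms < 2) {
    abort("sampling rate too low to render the AP rising phase")
  }

  time <- protocol_time(protocol)
  tstep <- protocol$step_duration
  n <- length(time)
  istep <- which(time >= 0 & time < tstep)
  ipost <- which(time >= tstep)
  tau_s <- pp$tau_m / 1000

  cell_seed <- derive_seed(seed, arch$name)
  draws <- with_seed(cell_seed, list(
    plateau = runif(1) < arch$plateau_prob,
    rs = min(24, max(5, rnorm(1, 15, 3))),
    drift = abs(rnorm(1, 0.03, 0.015)),
    rmp_est = rnorm(1, pp$rmp, 1),
    sweep_seeds = sample.int(2^30, length(protocol$currents))
  ))

  spike_truth <- vector("list", length(protocol$currents))
  names(spike_truth) <- paste0("I_", protocol$currents)
  volts <- matrix(pp$rmp, n, length(protocol$currents))

  for (j in seq_along(protocol$currents)) {
    cur <- protocol$currents[j]
    v <- rep(pp$rmp, n)
    if (cur < sp$rheobase) {
      v[istep] <- pp$rmp + passive_deflection(time[istep], cur, pp)
      v_end <- v[max(istep)]
      v[ipost] <- pp$rmp + (v_end - pp$rmp) * exp(-(time[ipost] - tstep) / tau_s)
      spike_truth[[j]] <- numeric(0)
    } else {
      st <- adapting_spike_times(sp, current = cur, duration = tstep,
                                 seed = draws$sweep_seeds[j],
                                 jitter_cv = jitter_cv,
                                 onset_latency = arch$onset_latency)
      st <- complete_spikes(st, geom, arch$duration_adaptation, tstep)
      spike_truth[[j]] <- st
      v <- render_spiking_sweep(v, time, st, arch, t_rise, t_fall, ahp,
                                tstep, tau_s, plateau = draws$plateau)
    }
    volts[, j] <- v
  }

  if (noise_sd > 0) {
    volts <- volts + with_seed(derive_seed(cell_seed, 7),
                               matrix(rnorm(length(volts), 0, noise_sd),
                                      nrow = n))
  }

  trace_set(
    cell_id = cell_id, time = time, voltages = volts,
    currents = protocol$currents, step_duration = tstep,
    metadata = list(series_resistance_MOhm = draws$rs,
                    rmp_mV = draws$rmp_est,
                    drift_fraction = draws$drift),
    truth = list(archetype = arch$name, feature_means = arch$feature_means,
                 passive = pp, spiking = sp, plateau = draws$plateau,
                 spike_times = spike_truth, seed = seed)
  )
}

#' Render a synthetic cohort of recordings
#'
#' Convenience wrapper rendering `n_per_type` cells per archetype with
#' cell-specific seeds derived from one master seed.
#'
#' @param archetypes named list of [archetype()]s (or `"three_types"`).
#' @param n_per_type cells per type.
#' @param protocol a [make_protocol()] object.
#' @param seed master seed.
#' @param ... passed to [render_recording()].
#' @return List of [trace_set()] objects.
#' @export
render_cohort <- function(archetypes = "three_types", n_per_type = 10,
                          protocol = make_protocol(), seed = 1, ...) {
  if (is.character(archetypes)) archetypes <- striatal_archetypes(archetypes)
  cells <- list()
  for (ty in names(archetypes)) {
    for (i in seq_len(n_per_type)) {
      cells[[length(cells) + 1]] <- render_recording(
        archetypes[[ty]], protocol, seed = derive_seed(seed, ty, i),
        cell_id = sprintf("%s_%03d", ty, i), ...)
    }
  }
  cells
}

# Piecewise construction of a suprathreshold sweep: ramp from rest to
# threshold before the first spike, triangular AP + linear AHP-to-threshold
# ramp between spikes, relaxation after the last spike, plateau or passive
# decay after stimulus offset.
render_spiking_sweep <- function(v, time, st, arch, t_rise, t_fall, ahp,
                                 tstep, tau_s, plateau = FALSE) {
  sp <- arch$spiking
  thr <- arch$threshold_v
  pp <- arch$passive
  dt <- time[2] - time[1]
  n <- length(v)
  i0 <- which.min(abs(time)) # step onset index

  if (length(st) == 0) return(v)

  # adaptation state at each spike, time-based from the first spike
  rel <- st - st[1]
  a_curve <- sp$amp_ratio_end + (1 - sp$amp_ratio_end) * adaptation_kernel(rel, sp)
  w_curve <- sp$width_ratio_end + (1 - sp$width_ratio_end) * adaptation_kernel(rel, sp)
  amps <- sp$amp0 * a_curve / a_curve[1]
  wids <- w_curve / w_curve[1]

  on_idx <- i0 + round(st / dt)

  # sub-threshold ramp from rest to threshold before the first spike
  pre <- i0:(on_idx[1])
  v[pre] <- pp$rmp + (thr - pp$rmp) * (seq_along(pre) - 1) / max(length(pre) - 1, 1)

  iend_step <- max(which(time < tstep))
  dt_ms <- dt * 1000
  geom <- ap_template_geometry(arch$feature_means)
  for (k in seq_along(st)) {
    # constant-slope rise/fall capped at peak/trough, so the rendered
    # dV/dt extrema equal the template slopes exactly
    rise_slope <- geom$rise_rate / wids[k]
    fall_slope <- (amps[k] + ahp) / (t_fall * wids[k])
    nr <- max(2L, ceiling(amps[k] / (rise_slope * dt_ms)))
    nf <- max(2L, ceiling((amps[k] + ahp) / (fall_slope * dt_ms)))
    ipk <- on_idx[k] + nr
    itr <- ipk + nf
    stop_at <- if (k < length(st)) on_idx[k + 1] else iend_step
    # rising phase
    ir <- on_idx[k]:min(ipk, stop_at, n)
    v[ir] <- thr + pmin(rise_slope * dt_ms * (seq_along(ir) - 1), amps[k])
    # falling phase to the AHP trough (truncate if the next spike arrives)
    if (min(ipk, stop_at, n) == ipk && ipk < n) {
      if_ <- ipk:min(itr, stop_at, n)
      v[if_] <- pmax((thr + amps[k]) - fall_slope * dt_ms * (seq_along(if_) - 1),
                     thr - ahp)
      # interspike ramp back to threshold
      if (min(itr, stop_at, n) == itr && itr < stop_at) {
        ii <- itr:stop_at
        if (k < length(st)) {
          v[ii] <- (thr - ahp) + ahp * (seq_along(ii) - 1) / max(length(ii) - 1, 1)
        } else {
          # settle a little below threshold for the rest of the step
          v[ii] <- (thr - 3) - (ahp - 3) * exp(-(seq_along(ii) - 1) * dt / tau_s)
        }
      }
    }
  }

  ipost <- which(time >= tstep)
  v_end <- v[iend_step]
  if (plateau) {
    hold <- which(time >= tstep & time < tstep + 0.1)
    v[hold] <- -35
    late <- which(time >= tstep + 0.1)
    v[late] <- pp$rmp + (-35 - pp$rmp) * exp(-(time[late] - tstep - 0.1) / tau_s)
  } else {
    v[ipost] <- pp$rmp + (v_end - pp$rmp) * exp(-(time[ipost] - tstep) / tau_s)
  }
  v
}
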