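#' Parameters of the passive membrane model
#'
#' Subthreshold responses are modelled as single-compartment RC charging
#' toward `I * r_in`, plus (for hyperpolarizing steps) a slower sag
#' conductance that relaxes the trough back toward steady state, emulating
#' HCN-mediated sag.
#'
#' @param rmp resting membrane potential (mV).
#' @param r_in input resistance (MOhm), slope of the steady-state I-V line.
#' @param tau_m membrane time constant (ms).
#' @param sag_fraction relative extra deflection of the hyperpolarizing
#'   trough that relaxes away, in `[0, 1)`; 0 disables sag.
#' @param sag_tau time constant of the sag relaxation (ms), slower than
#'   `tau_m`.
#' @param noise_sd standard deviation of additive recording noise (mV).
#' @return A `passive_model_params` list.
#' @export
passive_model_params <- function(rmp = -70, r_in = 200, tau_m = 20,
                                 sag_fraction = 0, sag_tau = 40,
                                 noise_sd = 0.2) {
  check_number(rmp, "rmp")
  check_positive(r_in, "r_in")
  check_positive(tau_m, "tau_m")
  check_number(sag_fraction, "sag_fraction", lower = 0, upper = 0.999)
  check_positive(sag_tau, "sag_tau")
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(rmp = rmp, r_in = r_in, tau_m = tau_m,
         sag_fraction = sag_fraction, sag_tau = sag_tau,
         noise_sd = noise_sd),
    class = "passive_model_params"
  )
}

# closed-form voltage deflection (mV) at times t (s, >= 0) into a step of
# `current` pA. pA * MOhm / 1000 = mV.
passive_deflection <- function(t, current, pp) {
  tm <- pp$tau_m / 1000
  d_ss <- current * pp$r_in / 1000
  base <- 1 - exp(-t / tm)
  if (current < 0 && pp$sag_fraction > 0) {
    ts <- pp$sag_tau / 1000
    base <- base + pp$sag_fraction * (exp(-t / ts) - exp(-t / tm))
  }
  d_ss * base
}

# sag amplitude (trough minus steady state, positive mV) predicted by the
# closed-form model for a step to `current` pA
model_sag_amplitude <- function(current, pp, duration = 1) {
  t <- seq(0, duration, by = 1e-3)
  d <- passive_deflection(t, current, pp)
  d_ss <- current * pp$r_in / 1000
  max(0, d_ss - min(d))
}

# choose sag_fraction so the rendered sag at a target steady-state voltage
# (default about -100 mV, where sag is conventionally read out) matches
# `sag_mv`
solve_sag_fraction <- function(sag_mv, pp, target_v = -100) {
  if (sag_mv <= 0) return(0)
  i_sag <- (target_v - pp$rmp) * 1000 / pp$r_in
  f <- function(s) {
    pp$sag_fraction <- s
    model_sag_amplitude(i_sag, pp) - sag_mv
  }
  if (f(0.99) < 0) abort("sag target unreachable for this input resistance")
  uniroot(f, c(1e-6, 0.99), tol = 1e-8)$root
}
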