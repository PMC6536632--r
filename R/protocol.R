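#' Define a current-step stimulation protocol
#'
#' Builds the family of 1-s square current steps used for intrinsic-property
#' characterization: steps from `current_min` to `current_max` in increments
#' of `current_increment`, each preceded and followed by a baseline period.
#'
#' @param current_min,current_max smallest and largest injected current (pA).
#' @param current_increment step between successive sweeps (pA), > 0.
#' @param step_duration duration of the current step (s).
#' @param sampling_rate acquisition rate (Hz).
#' @param pre_baseline,post_baseline baseline recorded before/after the step (s).
#' @return A `step_protocol` object; `as_tibble()` lists one row per sweep.
#' @examples
#' proto <- make_protocol()
#' nrow(tibble::as_tibble(proto)) # 41 sweeps, -200..200 pA by 10
#' @export
make_protocol <- function(current_min = -200, current_max = 200,
                          current_increment = 10, step_duration = 1,
                          sampling_rate = 20000,
                          pre_baseline = 0.1, post_baseline = 0.3) {
  check_number(current_min, "current_min")
  check_number(current_max, "current_max")
  check_positive(current_increment, "current_increment")
  check_positive(step_duration, "step_duration")
  check_positive(sampling_rate, "sampling_rate")
  check_number(pre_baseline, "pre_baseline", lower = 0)
  check_number(post_baseline, "post_baseline", lower = 0)
  if (current_min > current_max) {
    abort("`current_min` must not exceed `current_max`.")
  }
  structure(
    list(
      currents = seq(current_min, current_max, by = current_increment),
      step_duration = step_duration,
      pre_baseline = pre_baseline,
      post_baseline = post_baseline,
      sampling_rate = sampling_rate
    ),
    class = "step_protocol"
  )
}

#' @export
print.step_protocol <- function(x, ...) {
  cat(sprintf(
    "<step_protocol> %d sweeps: %g..%g pA, %g s step @ %g kHz\n",
    length(x$currents), min(x$currents), max(x$currents),
    x$step_duration, x$sampling_rate / 1000
  ))
  invisible(x)
}

#' @export
as_tibble.step_protocol <- function(x, ...) {
  tibble::tibble(
    sweep = seq_along(x$currents),
    current_pA = x$currents,
    step_duration_s = x$step_duration,
    sampling_rate_Hz = x$sampling_rate
  )
}

# time grid spanning pre-baseline, step and post-baseline; t = 0 at step onset
protocol_time <- function(protocol) {
  dt <- 1 / protocol$sampling_rate
  seq(-protocol$pre_baseline,
      protocol$step_duration + protocol$post_baseline - dt,
      by = dt)
}
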