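#' Fit an exponential decay to an adaptation time course
#'
#' Nonlinear least squares of `y ~ offset + sum_i a_i * exp(-t / tau_i)`
#' with non-negative amplitudes, time constants and offset (normalized
#' adaptation series plateau above zero). Initial values come from a
#' log-linear fit to the tail (slow component) and to the early residual
#' (fast component). For two components the returned `tau` are sorted so
#' `tau[1] <= tau[2]` (fast, slow).
#'
#' @param t time from the first spike (s).
#' @param y series values (conventionally normalized to the first value).
#' @param n_components 1 or 2.
#' @param r2_flag fits with R-squared below this are flagged as poor.
#' @return An `exp_fit` object; see [tidy.exp_fit()] / [glance.exp_fit()].
#' @examples
#' t <- seq(0, 1, by = 0.02)
#' y <- 0.2 + 0.4 * exp(-t / 0.05) + 0.4 * exp(-t / 0.5)
#' glance(fit_adaptation_exponential(t, y, 2))
#' @export
fit_adaptation_exponential <- function(t, y, n_components = 2,
                                       r2_flag = 0.5) {
  stopifnot(n_components %in% 1:2, length(t) == length(y))
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 2 * n_components + 2) {
    abort("too few points for the requested number of components.")
  }
  ord <- order(t)
  t <- t[ord]; y <- y[ord]

  off0 <- max(min(y) * 0.8, 1e-4)
  tau_slow0 <- init_tau(t, y, off0, tail_frac = 0.5) %||% max(t) / 2

  fit <- NULL
  if (n_components == 1) {
    fit <- try_nls(
      y ~ off + a1 * exp(-t / tau1),
      start = list(off = off0, a1 = max(y[1] - off0, 0.1), tau1 = tau_slow0),
      lower = c(0, 0, 1e-4), t = t, y = y
    )
  } else {
    a_slow0 <- max(y[1] - off0, 0.2) * 0.6
    resid0 <- y - off0 - a_slow0 * exp(-t / tau_slow0)
    tau_est <- init_tau(t, resid0 + off0, off0, tail_frac = NULL,
                        head_frac = 0.3)
    # multi-start: the fast component is poorly identified from noisy
    # trains, so several initializations compete on residual sum of squares
    cand <- unique(pmin(pmax(c(tau_est, tau_slow0 / 20, tau_slow0 / 6,
                               tau_slow0 / 3), 1e-3), tau_slow0))
    amp0 <- max(y[1] - off0, 0.1)
    for (tf0 in cand) {
      for (wf in c(0.4, 0.7)) {
        f <- try_nls(
          y ~ off + a1 * exp(-t / tau1) + a2 * exp(-t / tau2),
          start = list(off = off0, a1 = amp0 * wf, tau1 = tf0,
                       a2 = amp0 * (1 - wf), tau2 = tau_slow0),
          lower = c(0, 0, 1e-4, 0, 1e-4), t = t, y = y
        )
        if (!is.null(f) &&
            (is.null(fit) ||
             sum(stats::residuals(f)^2) < sum(stats::residuals(fit)^2))) {
          fit <- f
        }
      }
    }
  }

  if (is.null(fit)) {
    return(new_exp_fit(n_components, amplitudes = rep(NA_real_, n_components),
                       taus = rep(NA_real_, n_components), offset = NA_real_,
                       rss = Inf, r_squared = NA_real_, converged = FALSE,
                       poor_fit = TRUE, degenerate = FALSE, n = length(t)))
  }

  cf <- coef(fit)
  if (n_components == 1) {
    amps <- cf[["a1"]]; taus <- cf[["tau1"]]
  } else {
    amps <- c(cf[["a1"]], cf[["a2"]])
    taus <- c(cf[["tau1"]], cf[["tau2"]])
    o <- order(taus)
    amps <- amps[o]; taus <- taus[o]
  }
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  degen <- n_components == 2 && any(amps < 0.01 * max(sum(amps), 1e-12))
  new_exp_fit(n_components, amplitudes = unname(amps), taus = unname(taus),
              offset = cf[["off"]], rss = rss, r_squared = r2,
              converged = TRUE,
              poor_fit = is.na(r2) || r2 < r2_flag, degenerate = degen,
              n = length(t))
}

# log-linear slope estimate of a decay time constant on a data subset
init_tau <- function(t, y, off, tail_frac = 0.5, head_frac = NULL) {
  n <- length(t)
  idx <- if (!is.null(tail_frac)) seq(ceiling(n * (1 - tail_frac)), n)
         else seq(1, max(4, ceiling(n * head_frac)))
  z <- y[idx] - off
  ok <- z > 1e-9
  if (sum(ok) < 3) return(NULL)
  sl <- coef(lm(log(z[ok]) ~ t[idx][ok]))[[2]]
  if (sl >= 0) NULL else -1 / sl
}

try_nls <- function(formula, start, lower, t, y) {
  tryCatch(
    minpack.lm::nlsLM(formula, data = list(t = t, y = y), start = start,
                      lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL
  )
}

new_exp_fit <- function(n_components, amplitudes, taus, offset, rss,
                        r_squared, converged, poor_fit, degenerate, n) {
  structure(
    list(n_components = n_components, amplitudes = amplitudes, taus = taus,
         offset = offset, rss = rss, r_squared = r_squared,
         converged = converged, poor_fit = poor_fit,
         degenerate = degenerate, n = n),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> %d component(s): tau = %s s, offset %.3g, rss %.3g%s\n",
              x$n_components,
              paste(signif(x$taus, 4), collapse = ", "),
              x$offset, x$rss,
              if (x$poor_fit) " [poor fit]" else ""))
  invisible(x)
}

#' Broom-style accessors for exponential adaptation fits
#'
#' `tidy()` returns one row per component (`component`, `amplitude`,
#' `tau_s`); `glance()` returns the one-row fit summary.
#'
#' @param x an `exp_fit`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(
    component = if (x$n_components == 2) c("fast", "slow") else "single",
    amplitude = x$amplitudes,
    tau_s = x$taus
  )
}

#' @rdname tidy.exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components, offset = x$offset, rss = x$rss,
    r_squared = x$r_squared, converged = x$converged,
    poor_fit = x$poor_fit, degenerate = x$degenerate, n = x$n
  )
}
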