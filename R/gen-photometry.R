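#' Simulate a two-channel fiber-photometry trace
#'
#' The calcium-dependent 470 nm channel is a constant baseline carrying one
#' exponential-decay transient per event (fractional amplitude
#' `transient_amplitude`, decay constant `transient_tau_s`) plus Gaussian
#' noise. The isosbestic 410 nm reference channel carries baseline and
#' noise only — by construction it is calcium-blind, which is what makes it
#' a motion control downstream.
#'
#' @param config a [synth_config()].
#' @param events event onset times, s; must lie inside the trace.
#' @param seed RNG seed.
#' @param duration_s trace length, s (default: last event + 60 s).
#' @return A `photometry_trace`: list with `t` (s), `f470`, `f410`,
#'   `events`, `fs`, and ground-truth transient parameters in
#'   `attr(, "truth")`.
#' @examples
#' cfg <- synth_config(photometry_noise_sd = 0)
#' tr <- gen_photometry(cfg, events = c(10, 40), seed = 1, duration_s = 80)
#' range(tr$f470)
#' @export
gen_photometry <- function(config, events = config$event_times_s,
                           seed = config$seed,
                           duration_s = max(events) + 60) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sampling_rate_hz
  if (fs <= 0) stop("nonpositive sampling rate", call. = FALSE)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  if (any(events < 0 | events > t[n]))
    stop("events outside the trace duration", call. = FALSE)

  shape <- numeric(n)
  for (te in events) {
    i <- t >= te
    shape[i] <- shape[i] +
      config$transient_amplitude * exp(-(t[i] - te) / config$transient_tau_s)
  }
  noise <- with_seed(seed, list(
    n470 = stats::rnorm(n, 0, config$photometry_noise_sd * config$baseline_f470),
    n410 = stats::rnorm(n, 0, config$photometry_noise_sd * config$baseline_f410)))

  tr <- photometry_trace(
    t = t,
    f470 = config$baseline_f470 * (1 + shape) + noise$n470,
    f410 = config$baseline_f410 + noise$n410,
    events = events, fs = fs)
  attr(tr, "truth") <- list(amplitude = config$transient_amplitude,
                            tau_s = config$transient_tau_s,
                            baseline_f470 = config$baseline_f470,
                            baseline_f410 = config$baseline_f410,
                            noise_sd = config$photometry_noise_sd,
                            seed = seed)
  tr
}
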