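#' Synthetic waveform specification
#'
#' Parameters of a damped, noisy harmonic-sum series emulating an hourly
#' sampled bioluminescence reporter curve:
#' \deqn{x(t) = \mathrm{offset} + e^{-\lambda t} \sum_j 2 |a_j|
#'   \sin(2\pi j t/\mathrm{period} + \phi_j) + \mathrm{noise},}
#' with `|a_j|` the one-sided coefficient moduli (matching the convention of
#' the waveform statistics, so the synthesized fundamental has peak
#' amplitude `2 |a_1|`) and uniform noise on `(-noise, noise)`.
#'
#' @param period Fundamental period (h), default 24.
#' @param amplitudes One-sided moduli `|a_1|, |a_2|, ...` (`|a_1| > 0`).
#' @param phases Harmonic phases (recycled).
#' @param damping Exponential envelope rate `lambda` (1/h), `>= 0`.
#' @param offset Baseline; default lifts the minimum safely above zero so
#'   minima-anchored detrending is well posed.
#' @param sampling Sampling interval (h), default 1.
#' @param duration Record length (h), default 72 (three circadian cycles).
#' @param noise Uniform noise half-width, default 0.
#' @return An object of class `waveform_spec` carrying `truth_ns`
#'   (the NS(m=4, q=2) implied by `amplitudes`).
#' @export
waveform_spec <- function(period = 24, amplitudes = 1, phases = 0,
                          damping = 0, offset = NULL, sampling = 1,
                          duration = 72, noise = 0) {
  stopifnot(period > 0, is.numeric(amplitudes), amplitudes[1] > 0,
            all(amplitudes >= 0), damping >= 0, sampling > 0,
            duration >= 2 * period, noise >= 0)
  if (is.null(offset)) offset <- 1.2 * (2 * sum(amplitudes)) + noise
  structure(list(period = period, amplitudes = amplitudes,
                 phases = rep_len(phases, length(amplitudes)),
                 damping = damping, offset = offset, sampling = sampling,
                 duration = duration, noise = noise,
                 truth_ns = ns_from_amplitudes(amplitudes, 4, 2)),
            class = "waveform_spec")
}

#' Harmonic amplitudes realizing a target NS
#'
#' Inverts the NS formula for a two-harmonic waveform: returns
#' `c(1, rho)` with `rho` chosen so that `NS(m, q)` equals the target.
#' Feasible for targets below `2^((m - q)/2)` (= 2 for the default
#' exponents).
#'
#' @param ns Target NS value (`>= 1`).
#' @param m,q NS exponents.
#' @return Amplitude vector `c(1, rho)`.
#' @examples
#' ns_from_amplitudes(amplitudes_for_ns(1.5))  # 1.5
#' @export
amplitudes_for_ns <- function(ns, m = 4, q = 2) {
  stopifnot(ns >= 1, m > q, q >= 0)
  if (ns^2 >= 2^(m - q)) {
    stop(sprintf("target NS must be below %g for a two-harmonic waveform",
                 2^((m - q) / 2)), call. = FALSE)
  }
  if (ns == 1) return(1)
  rho <- sqrt((ns^2 - 1) / (2^m - ns^2 * 2^q))
  c(1, rho)
}

#' Synthesize a bioluminescence-style waveform
#'
#' @param spec A [waveform_spec()].
#' @param seed Seed for the noise draw.
#' @param condition Condition label attached to the series.
#' @return A [biolum_series()] with attributes `truth_ns` and `spec`.
#' @export
synth_waveform <- function(spec, seed = NULL, condition = NA_character_) {
  stopifnot(inherits(spec, "waveform_spec"))
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, spec$duration, by = spec$sampling)
  x <- rep(spec$offset, length(t))
  env <- exp(-spec$damping * t)
  for (j in seq_along(spec$amplitudes)) {
    x <- x + env * 2 * spec$amplitudes[j] *
      sin(2 * pi * j * t / spec$period + spec$phases[j])
  }
  if (spec$noise > 0) {
    x <- x + stats::runif(length(t), -spec$noise, spec$noise)
  }
  out <- biolum_series(t, x, condition = condition)
  attr(out, "truth_ns") <- spec$truth_ns
  attr(out, "spec") <- spec
  out
}

#' Synthesize a two-condition pair
#'
#' Stand-in for a low/high-temperature reporter pair: two series sharing
#' sampling and duration but differing in harmonic content (hence true NS).
#' The two noise draws are independent substreams of the seed.
#'
#' @param spec_low,spec_high [waveform_spec()]s with equal `sampling` and
#'   `duration`.
#' @param seed Master seed.
#' @return List with `a` (low), `b` (high), and `truth` (list with the two
#'   true NS values and their difference).
#' @export
synth_condition_pair <- function(spec_low, spec_high, seed = 1L) {
  stopifnot(inherits(spec_low, "waveform_spec"),
            inherits(spec_high, "waveform_spec"),
            spec_low$sampling == spec_high$sampling,
            spec_low$duration == spec_high$duration)
  a <- synth_waveform(spec_low, seed = seed, condition = "low")
  b <- synth_waveform(spec_high,
                      seed = (as.numeric(seed) + 1000003) %% 2147483647,
                      condition = "high")
  list(a = a, b = b,
       truth = list(ns_low = spec_low$truth_ns, ns_high = spec_high$truth_ns,
                    delta_ns = spec_high$truth_ns - spec_low$truth_ns))
}

#' Hourly fixture from a simulated Goodwin limit cycle
#'
#' Integrates an oscillating Goodwin parameter set, discards the transient,
#' rescales time so that one oscillation lasts 24 h, and samples `x3`
#' hourly (optionally overlaying an exponential envelope and uniform
#' noise).  The stored ground-truth NS is measured from the dense
#' trajectory by harmonic analysis before downsampling.
#'
#' @param params Oscillating [goodwin_params()].
#' @param sampling Output sampling interval (h), default 1.
#' @param n_periods Number of 24 h cycles in the output, default 3.
#' @param damping Envelope rate (1/h) overlaid on the rescaled series.
#' @param noise Uniform noise half-width.
#' @param seed Seed for the noise draw.
#' @param jmax Harmonics for the ground-truth measurement.
#' @return A [biolum_series()] with attributes `truth_ns` and
#'   `period_native` (the model-time period).
#' @export
synth_goodwin_fixture <- function(params, sampling = 1, n_periods = 3,
                                  damping = 0, noise = 0, seed = NULL,
                                  jmax = 10L) {
  m <- sweep_measure_decomp(params, jmax = jmax)
  truth_ns <- ns_index(m$decomp, 4, 2)$ns
  s <- structural_sums(params$k1, params$k2, params$k3)
  tau_lin <- 2 * pi / sqrt(s[["s2"]])
  dt <- tau_lin / 2500
  need <- (n_periods + 1) * m$tau
  traj <- integrate_system("goodwin", params, t_end = 30 * tau_lin + need,
                           dt = dt, thin = 1L)
  tt <- traj_time(traj)
  x3 <- traj$values[, "x3"]
  t_start <- tt[length(tt)] - n_periods * m$tau
  scale <- 24 / m$tau                     # model time -> hours
  t_out <- seq(0, n_periods * 24, by = sampling)
  x_out <- stats::approx(x = (tt - t_start) * scale, y = x3,
                         xout = t_out, rule = 2)$y
  if (damping > 0) x_out <- mean(x_out) + (x_out - mean(x_out)) * exp(-damping * t_out)
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    x_out <- x_out + stats::runif(length(t_out), -noise, noise)
  }
  out <- biolum_series(t_out, x_out)
  attr(out, "truth_ns") <- truth_ns
  attr(out, "period_native") <- m$tau
  out
}
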