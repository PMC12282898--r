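#' Configuration for generalized harmonic analysis
#'
#' Controls the greedy residual-minimizing extraction of sinusoidal
#' components.  The frequency grid for the fundamental spans
#' `[0.5/T, max(4 jmax, 64)/T]` (window length `T`, capped at the Nyquist
#' frequency) at resolution `1/(20 T)` unless overridden; each grid optimum
#' is refined by golden-section search.
#' After the fundamental is found, higher components are searched only
#' within `harmonic_window` (relative) of the exact harmonics `j f1`,
#' because the waveform statistics index components as harmonics of the
#' fundamental.
#'
#' @param jmax Number of harmonic components to extract (`>= 1`).
#' @param f_min,f_max Frequency grid bounds for the fundamental search;
#'   `NULL` for the defaults above.
#' @param grid_res Grid resolution; `NULL` for `1/(20 T)`.
#' @param harmonic_window Relative half-width of the search interval around
#'   each harmonic `j f1` (default 0.02).
#' @param f1_hint Optional prior estimate of the fundamental frequency; when
#'   given, the fundamental search is confined to `f1_hint` times
#'   `(1 - harmonic_window, 1 + harmonic_window)`, which is both faster and
#'   robust for simulation output whose period is already known from peak
#'   timing.
#' @param passes Number of extraction passes (default 2).  The first pass is
#'   the greedy extract-and-subtract loop; subsequent passes revisit each
#'   component with the others subtracted, which removes the cross-component
#'   bias of the greedy frequency estimates on finite windows.
#' @return An object of class `gha_config`.
#' @export
gha_config <- function(jmax = 10L, f_min = NULL, f_max = NULL,
                       grid_res = NULL, harmonic_window = 0.02,
                       f1_hint = NULL, passes = 2L) {
  stopifnot(jmax >= 1L, harmonic_window > 0,
            is.null(grid_res) || grid_res > 0,
            is.null(f1_hint) || f1_hint > 0, passes >= 1L)
  structure(list(jmax = as.integer(jmax), f_min = f_min, f_max = f_max,
                 grid_res = grid_res, harmonic_window = harmonic_window,
                 f1_hint = f1_hint, passes = as.integer(passes)),
            class = "gha_config")
}

# golden-section minimization of the LSQ residual over angular frequency
refine_component <- function(x, t0, dt, w_lo, w_hi, tol = 1e-10) {
  o <- stats::optimize(function(w) gha_fit_cpp(x, t0, dt, w)[["sse"]],
                       lower = w_lo, upper = w_hi,
                       tol = max(tol, 1e-12 * (w_lo + w_hi)))
  o$minimum
}

#' Generalized harmonic analysis of a uniformly sampled series
#'
#' Greedy least-squares spectral decomposition: at each round the sinusoid
#' `A cos(2 pi f t) + B sin(2 pi f t)` (plus an intercept) minimizing the
#' squared residual is identified over a frequency grid with golden-section
#' refinement, subtracted, and the search repeated on the residual.  The
#' first round determines the fundamental `f1`; rounds `j = 2..jmax` are
#' locked to neighborhoods of the harmonics `j f1`, so the result is a
#' harmonic decomposition indexed by `j`.
#'
#' Amplitudes follow the one-sided real convention
#' `x(t) ~ c0 + sum_j r_j sin(2 pi j f1 t + alpha_j)` with
#' `r_j = sqrt(A_j^2 + B_j^2)` and `alpha_j = atan2(A_j, B_j)`; the
#' corresponding one-sided complex coefficient moduli are `|a_j| = r_j / 2`.
#'
#' @param x Numeric series sampled at interval `dt` (or a [trajectory()],
#'   in which case its last component is analyzed).
#' @param dt Sampling interval (ignored when `x` is a trajectory).
#' @param config A [gha_config()].
#' @param t0 Time of the first sample.
#' @return An object of class `harmonic_decomposition`: a list with
#'   `components` (data frame with columns `j, f, A, B, r, alpha`), `f1`,
#'   `mean_level`, `residual_power` (mean squared residual),
#'   `total_power` (mean squared deviation from the mean), `dt`, and
#'   `constant` (flag: no periodic component detectable).
#' @examples
#' t <- seq(0, 240, by = 0.1)
#' d <- gha_decompose(sin(2 * pi * t / 24), dt = 0.1, config = gha_config(jmax = 3))
#' d$f1 * 24
#' @export
gha_decompose <- function(x, dt = NULL, config = gha_config(), t0 = 0) {
  if (inherits(x, "trajectory")) {
    dt <- x$dt
    t0 <- x$t0
    x <- x$values[, ncol(x$values)]
  }
  stopifnot(is.numeric(x), length(x) >= 8L, !is.null(dt), dt > 0,
            inherits(config, "gha_config"))
  x <- as.numeric(x)
  Tw <- (length(x) - 1) * dt
  mean_level <- mean(x)
  total_power <- mean((x - mean_level)^2)
  jmax <- config$jmax
  comp <- data.frame(j = seq_len(jmax), f = NA_real_, A = NA_real_,
                     B = NA_real_, r = NA_real_, alpha = NA_real_)
  if (total_power <= (1e-14 * max(1, abs(mean_level)))^2) {
    comp$f <- 0; comp$A <- 0; comp$B <- 0; comp$r <- 0; comp$alpha <- 0
    return(structure(list(components = comp, f1 = NA_real_,
                          mean_level = mean_level, residual_power = 0,
                          total_power = total_power, dt = dt,
                          constant = TRUE),
                     class = "harmonic_decomposition"))
  }
  res <- x
  hw <- config$harmonic_window
  # fundamental search window
  if (!is.null(config$f1_hint)) {
    w_lo <- 2 * pi * config$f1_hint * (1 - hw)
    w_hi <- 2 * pi * config$f1_hint * (1 + hw)
    w1 <- refine_component(res, t0, dt, w_lo, w_hi)
  } else {
    f_lo <- if (is.null(config$f_min)) 0.5 / Tw else config$f_min
    # span enough of the spectrum that a fundamental with up to ~64 cycles in
    # the window is reachable even when few harmonics are requested
    f_hi <- if (is.null(config$f_max)) max(4 * jmax, 64) / Tw else config$f_max
    f_hi <- min(f_hi, 0.5 / dt)  # Nyquist
    resn <- if (is.null(config$grid_res)) 1 / (20 * Tw) else config$grid_res
    grid <- 2 * pi * seq(f_lo, f_hi, by = resn)
    sse <- gha_scan_cpp(res, t0, dt, grid)
    i <- which.min(sse)
    w_lo <- grid[max(1L, i - 1L)]
    w_hi <- grid[min(length(grid), i + 1L)]
    w1 <- refine_component(res, t0, dt, w_lo, w_hi)
  }
  tt <- t0 + (seq_along(res) - 1) * dt
  ws <- numeric(jmax)
  As <- numeric(jmax)
  Bs <- numeric(jmax)
  for (j in seq_len(jmax)) {
    wj <- if (j == 1L) w1 else
      refine_component(res, t0, dt, j * w1 * (1 - hw), j * w1 * (1 + hw))
    fit <- gha_fit_cpp(res, t0, dt, wj)
    ws[j] <- wj; As[j] <- fit[["A"]]; Bs[j] <- fit[["B"]]
    res <- res - fit[["c0"]] - fit[["A"]] * cos(wj * tt) - fit[["B"]] * sin(wj * tt)
  }
  # refinement passes: revisit each component with the others held out,
  # removing the cross-component bias of the greedy pass
  if (config$passes > 1L) {
    for (pass in seq_len(config$passes - 1L)) {
      for (j in seq_len(jmax)) {
        res_plus <- res + As[j] * cos(ws[j] * tt) + Bs[j] * sin(ws[j] * tt)
        lo <- if (j == 1L) ws[1] * (1 - hw) else j * ws[1] * (1 - hw)
        hi <- if (j == 1L) ws[1] * (1 + hw) else j * ws[1] * (1 + hw)
        wj <- refine_component(res_plus, t0, dt, lo, hi)
        fit <- gha_fit_cpp(res_plus, t0, dt, wj)
        ws[j] <- wj; As[j] <- fit[["A"]]; Bs[j] <- fit[["B"]]
        res <- res_plus - fit[["c0"]] - fit[["A"]] * cos(wj * tt) -
          fit[["B"]] * sin(wj * tt)
      }
    }
  }
  f1 <- ws[1] / (2 * pi)
  comp$f <- ws / (2 * pi)
  comp$A <- As
  comp$B <- Bs
  comp$r <- sqrt(As^2 + Bs^2)
  comp$alpha <- atan2(As, Bs)
  structure(list(components = comp, f1 = f1, mean_level = mean_level,
                 residual_power = mean((res - mean(res))^2),
                 total_power = total_power, dt = dt, constant = FALSE),
            class = "harmonic_decomposition")
}

#' @export
print.harmonic_decomposition <- function(x, ...) {
  cat(sprintf("<harmonic decomposition: f1 = %g, %d components, residual/total power = %.3g>\n",
              x$f1, nrow(x$components),
              if (x$total_power > 0) x$residual_power / x$total_power else 0))
  print(x$components, digits = 4)
  invisible(x)
}

#' Construct a harmonic decomposition from known coefficients
#'
#' Builds the same object [gha_decompose()] returns, from explicit one-sided
#' sine-convention amplitudes and phases.  Used for closed-form examples and
#' to feed the waveform statistics with analytically known coefficients.
#'
#' @param f1 Fundamental frequency.
#' @param r One-sided amplitudes `r_j` for `j = 1..jmax`
#'   (`|a_j| = r_j / 2`).
#' @param alpha Phases `alpha_j` (sine convention); recycled to the length
#'   of `r`.
#' @param mean_level Constant offset.
#' @return A `harmonic_decomposition`.
#' @export
harmonic_components <- function(f1, r, alpha = 0, mean_level = 0) {
  stopifnot(f1 > 0, is.numeric(r), all(r >= 0), length(r) >= 1L)
  alpha <- rep_len(alpha, length(r))
  j <- seq_along(r)
  comp <- data.frame(j = j, f = j * f1, A = r * sin(alpha),
                     B = r * cos(alpha), r = r, alpha = alpha)
  structure(list(components = comp, f1 = f1, mean_level = mean_level,
                 residual_power = 0, total_power = sum(r^2) / 2, dt = NA_real_,
                 constant = all(r == 0)),
            class = "harmonic_decomposition")
}

#' Evaluate a harmonic decomposition on a time grid
#'
#' @param decomp A `harmonic_decomposition`.
#' @param t Times.
#' @return `mean_level + sum_j r_j sin(2 pi f_j t + alpha_j)`.
#' @export
evaluate_harmonics <- function(decomp, t) {
  stopifnot(inherits(decomp, "harmonic_decomposition"))
  cmp <- decomp$components
  out <- rep(decomp$mean_level, length(t))
  for (j in seq_len(nrow(cmp))) {
    out <- out + cmp$r[j] * sin(2 * pi * cmp$f[j] * t + cmp$alpha[j])
  }
  out
}

ns_from_r <- function(r, m, q) {
  j <- seq_along(r)
  p <- r^2  # convention constant cancels in the ratio
  sqrt(sum(p * j^m) / sum(p * j^q))
}

#' Non-sinusoidal power from explicit harmonic amplitudes
#'
#' Direct evaluation of
#' \deqn{NS = \sqrt{\sum_j |a_j|^2 j^m / \sum_j |a_j|^2 j^q}}
#' for amplitudes indexed `j = 1, 2, ...`.  `NS = 1` for a pure sinusoid and
#' `NS > 1` whenever higher harmonics carry power (for `m > q`).
#'
#' @param amplitudes Harmonic amplitude magnitudes (any fixed convention;
#'   the statistic is scale-free).
#' @param m,q Integer exponents with `m > q >= 0` (defaults 4 and 2, the
#'   exponents entering the analytic period formula).
#' @return The NS value.
#' @examples
#' ns_from_amplitudes(c(1, 0.5))            # sqrt(2.5)
#' ns_from_amplitudes(1)                    # exactly 1
#' @export
ns_from_amplitudes <- function(amplitudes, m = 4, q = 2) {
  stopifnot(is.numeric(amplitudes), all(amplitudes >= 0),
            m == round(m), q == round(q), m > q, q >= 0)
  if (all(amplitudes == 0)) {
    stop("NS is undefined when all harmonic amplitudes vanish", call. = FALSE)
  }
  ns_from_r(amplitudes, m, q)
}

#' Non-sinusoidal power (NS) of a harmonic decomposition
#'
#' Waveform-distortion index of a periodic series; see
#' [ns_from_amplitudes()] for the formula.  The decomposition must carry a
#' nonzero fundamental.
#'
#' @param decomp A `harmonic_decomposition`.
#' @param m,q Integer exponents, `m > q >= 0`.
#' @return An object of class `ns_result`: list with `ns`, `m`, `q`, `jmax`.
#' @export
ns_index <- function(decomp, m = 4, q = 2) {
  stopifnot(inherits(decomp, "harmonic_decomposition"))
  r <- decomp$components$r
  if (isTRUE(decomp$constant) || r[1] <= 0) {
    stop("NS is undefined: no fundamental component", call. = FALSE)
  }
  structure(list(ns = ns_from_amplitudes(r, m, q), m = m, q = q,
                 jmax = length(r)),
            class = "ns_result")
}

#' @export
print.ns_result <- function(x, ...) {
  cat(sprintf("NS(m = %d, q = %d, jmax = %d) = %.6g\n", x$m, x$q, x$jmax, x$ns))
  invisible(x)
}

#' Analytic period of the Goodwin model from its waveform
#'
#' The period of the linear-degradation Goodwin oscillator is fixed by the
#' degradation rates and the harmonic content of `x3`:
#' \deqn{\tau = 2\pi \sqrt{\frac{\sum_j |a_j|^2 j^4}
#'   {(k_1 k_2 + k_2 k_3 + k_3 k_1) \sum_j |a_j|^2 j^2}}
#'   = \frac{2\pi}{\sqrt{s_2}} NS(m = 4, q = 2).}
#' A more distorted waveform (larger NS) lengthens the period at fixed
#' degradation rates, which is the root of the waveform hypothesis for
#' temperature compensation.
#'
#' @param k1,k2,k3 Degradation rates.
#' @param decomp A `harmonic_decomposition` of `x3(t)`.
#' @return Predicted period.
#' @export
period_formula <- function(k1, k2, k3, decomp) {
  stopifnot(k1 > 0, k2 > 0, k3 > 0)
  s2 <- k1 * k2 + k2 * k3 + k3 * k1
  ns <- ns_index(decomp, m = 4, q = 2)$ns
  2 * pi / sqrt(s2) * ns
}

#' Synchronization waveform statistic R
#'
#' \deqn{R = |a_1| / \sum_j |a_j|^2 j^4} in the one-sided convention
#' `|a_j| = r_j / 2`.  R shrinks when higher-harmonic power grows at fixed
#' fundamental amplitude, and it scales the analytic entrainment bound: a
#' more distorted waveform admits a narrower range of entraining
#' frequencies.  Unlike NS, R is not scale-free, so the coefficient
#' convention matters and is fixed package-wide.
#'
#' @param decomp A `harmonic_decomposition`.
#' @return The R value.
#' @export
r_statistic <- function(decomp) {
  stopifnot(inherits(decomp, "harmonic_decomposition"))
  a <- decomp$components$r / 2
  if (isTRUE(decomp$constant) || a[1] <= 0) {
    stop("R is undefined: no fundamental component", call. = FALSE)
  }
  j <- seq_along(a)
  a[1] / sum(a^2 * j^4)
}

wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y <= -pi, y + 2 * pi, y)
}

#' Phase of the second harmonic relative to the fundamental
#'
#' The series is implicitly time-shifted so that its fundamental is a pure
#' sine, `sin(omega t)`; the returned value is the residual phase of the
#' second harmonic in that frame, i.e. the `alpha` of
#' `r_2 sin(2 omega t + alpha)`, reduced to `(-pi, pi]`.  This phase controls
#' the skew of the waveform: smaller values give a steeper rise and a longer
#' falling tail.
#'
#' @param decomp A `harmonic_decomposition` with at least two components.
#' @param noise_floor Relative amplitude `r_2 / r_1` below which the phase is
#'   flagged low-confidence (default 1e-4).
#' @return Phase in `(-pi, pi]` with attribute `low_confidence`.
#' @export
second_harmonic_phase <- function(decomp, noise_floor = 1e-4) {
  stopifnot(inherits(decomp, "harmonic_decomposition"),
            nrow(decomp$components) >= 2L)
  cmp <- decomp$components
  if (isTRUE(decomp$constant) || cmp$r[1] <= 0) {
    stop("second-harmonic phase undefined: no fundamental", call. = FALSE)
  }
  val <- wrap_phase(cmp$alpha[2] - 2 * cmp$alpha[1])
  attr(val, "low_confidence") <- cmp$r[2] < noise_floor * cmp$r[1]
  val
}

#' Argument of a one-sided complex Fourier coefficient
#'
#' Converts the stored sine-convention phase to the argument of the complex
#' coefficient `a_j` in `x(t) = sum_j a_j exp(i j omega t) + c.c.`
#' (`arg a_j = alpha_j - pi/2`).  For `j = 1` this is the phase `beta`
#' entering the entrainment balance.
#'
#' @param decomp A `harmonic_decomposition`.
#' @param j Harmonic index.
#' @return Argument in `(-pi, pi]`.
#' @export
coefficient_argument <- function(decomp, j = 1L) {
  stopifnot(inherits(decomp, "harmonic_decomposition"))
  cmp <- decomp$components
  stopifnot(j >= 1L, j <= nrow(cmp))
  wrap_phase(cmp$alpha[j] - pi / 2)
}
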