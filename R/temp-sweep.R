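#' Configuration of the randomized temperature-compensation sweep
#'
#' Reference parameter sets of the power-law Goodwin model are drawn at
#' random and each is "heated" by multiplying every rate by an independent
#' random factor; the sweep records how period and waveform respond.
#' Defaults follow the study design: 100 oscillating references (six rates
#' uniform on (0, 10], cooperativity an integer uniform on 9..15), 49
#' oscillation-persisting perturbations each (factors uniform on
#' (1.1, 1.9)), and a period-stability band of 0.85-1.15 for calling a
#' perturbation temperature-compensated.
#'
#' @param n_reference Number of oscillating reference sets.
#' @param n_perturb Oscillation-persisting perturbations kept per reference.
#' @param rate_max Upper bound of the uniform rate draws.
#' @param n_range Integer range (inclusive) of the cooperativity draw.
#' @param factor_range Range of the multiplicative perturbation factors.
#' @param band Relative-period band for the compensated flag.
#' @param seed Master seed; every record stores the derived per-reference
#'   substream seed.
#' @param periods Integration horizon in units of the linearized period
#'   `2 pi / sqrt(s2)` (first half is discarded as transient).
#' @param steps_per_period RK4 steps per linearized period.
#' @param jmax Harmonics extracted for the NS measurement.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(n_reference = 100L, n_perturb = 49L, rate_max = 10,
                         n_range = c(9L, 15L), factor_range = c(1.1, 1.9),
                         band = c(0.85, 1.15), seed = 1L, periods = 44,
                         steps_per_period = 2500L, jmax = 10L) {
  stopifnot(n_reference >= 1L, n_perturb >= 1L, rate_max > 0,
            length(n_range) == 2L, n_range[1] >= 1, n_range[2] >= n_range[1],
            length(factor_range) == 2L, factor_range[1] > 1,
            factor_range[2] >= factor_range[1],
            length(band) == 2L, band[1] > 0, band[2] > band[1],
            periods >= 10, steps_per_period >= 200L, jmax >= 2L)
  structure(list(n_reference = as.integer(n_reference),
                 n_perturb = as.integer(n_perturb), rate_max = rate_max,
                 n_range = as.integer(n_range), factor_range = factor_range,
                 band = band, seed = as.integer(seed), periods = periods,
                 steps_per_period = as.integer(steps_per_period),
                 jmax = as.integer(jmax)),
            class = "sweep_config")
}

#' Measure period, waveform distortion, and amplitude of one parameter set
#'
#' Integrates the power-law Goodwin model with the sweep's integration
#' heuristics (RK4, step scaled to the linearized period, first half of the
#' horizon discarded), classifies sustained oscillation, and if oscillating
#' measures the period (interpolated peak intervals), the NS index
#' (generalized harmonic analysis locked to harmonics of the measured
#' fundamental, `m = 4, q = 2`), and the peak-to-trough amplitude of `x3`.
#'
#' Amplitude relaxation onto the limit cycle can be slow near the Hopf
#' point, so when the first integration window is not yet stationary the
#' integration is continued from its end state (up to `max_rounds` windows)
#' before the set is classified as non-oscillating.
#'
#' @param params A [goodwin_params()] (power-law form).
#' @param periods,steps_per_period,jmax See [sweep_config()].
#' @param max_rounds Maximum number of continuation windows.
#' @return List with `oscillating`, `tau`, `ns`, `amplitude` (the last
#'   three `NA` when not oscillating or when integration diverges).
#' @export
sweep_measure <- function(params, periods = 44, steps_per_period = 2500L,
                          jmax = 10L, max_rounds = 5L) {
  s <- structural_sums(params$k1, params$k2, params$k3)
  tau_lin <- 2 * pi / sqrt(s[["s2"]])
  dt <- tau_lin / steps_per_period
  thin <- max(1L, floor(steps_per_period / 500))
  na <- list(oscillating = FALSE, tau = NA_real_, ns = NA_real_,
             amplitude = NA_real_)
  level <- goodwin_fixed_point(params)[["x3"]]
  init <- NULL
  traj <- NULL
  lc <- NULL
  for (round in seq_len(max_rounds)) {
    traj <- tryCatch(
      integrate_system("goodwin", params, init = init,
                       t_end = periods * tau_lin, dt = dt, thin = thin),
      error = function(e) NULL)
    if (is.null(traj)) return(na)
    lc <- detect_limit_cycle(traj, transient_fraction = 0.5)
    if (lc$oscillating) break
    # no stationary peaks yet: either a decaying spiral (amplitude collapsing
    # toward the fixed point) or slow relaxation onto the cycle; continue in
    # the latter case
    if (lc$amplitude < 1e-4 * level) break
    init <- traj$values[nrow(traj$values), ]
  }
  if (!lc$oscillating) {
    return(list(oscillating = FALSE, tau = NA_real_, ns = NA_real_,
                amplitude = lc$amplitude))
  }
  tau <- measure_period(traj, transient_fraction = 0.5)
  win <- post_transient(traj, 0.5)
  # an integer number of periods in the analysis window keeps spectral
  # leakage out of the high-harmonic terms (they carry j^4 weights in NS)
  n_per <- max(3L, floor((length(win$x) - 1L) * win$dt / tau))
  n_per <- min(n_per, 12L)
  n_keep <- min(length(win$x), round(n_per * tau / win$dt) + 1L)
  x <- win$x[(length(win$x) - n_keep + 1L):length(win$x)]
  stride <- max(1L, ceiling(length(x) / 8192))
  x <- x[seq(1L, length(x), by = stride)]
  dec <- gha_decompose(x, dt = win$dt * stride,
                       config = gha_config(jmax = jmax, f1_hint = 1 / tau))
  list(oscillating = TRUE, tau = tau, ns = ns_index(dec, 4, 2)$ns,
       amplitude = lc$amplitude, decomp = dec)
}

draw_reference <- function(config) {
  repeat {
    rates <- stats::runif(6, 0, config$rate_max)
    if (any(rates == 0)) next
    n <- sample(seq(config$n_range[1], config$n_range[2]), 1L)
    p <- goodwin_power_law(rates[1], rates[2], rates[3], rates[4], rates[5],
                           r = rates[6], n = n)
    return(p)
  }
}

hopf_possible <- function(params) {
  s <- structural_sums(params$k1, params$k2, params$k3)
  params$transcription$n > s[["s4"]] / s[["s3"]]
}

#' Sample oscillating reference parameter sets
#'
#' Rejection sampling of power-law Goodwin parameter sets: the six rates are
#' uniform on `(0, rate_max]`, the cooperativity is an integer uniform on
#' `n_range`; a draw is kept only if it passes the Hopf necessary condition
#' `n > s4/s3` and a simulation confirms a sustained oscillation.
#' Reproducible for a fixed config seed.
#'
#' @param config A [sweep_config()].
#' @return List of `n_reference` [goodwin_params()] objects.
#' @export
sample_reference_sets <- function(config = sweep_config()) {
  stopifnot(inherits(config, "sweep_config"))
  set.seed(config$seed)
  out <- vector("list", config$n_reference)
  kept <- 0L
  draws <- 0L
  while (kept < config$n_reference) {
    draws <- draws + 1L
    if (draws > 1e6) {
      stop("acceptance rate below 1e-4 over 1e6 draws; check the sweep bounds",
           call. = FALSE)
    }
    p <- draw_reference(config)
    if (!hopf_possible(p)) next
    m <- sweep_measure(p, config$periods, config$steps_per_period,
                       config$jmax)
    if (m$oscillating) {
      kept <- kept + 1L
      attr(p, "measure") <- m
      out[[kept]] <- p
    }
  }
  out
}

#' Multiplicative perturbation of a Goodwin parameter set
#'
#' Each of the six rates (`k1, k2, k3, p1, p2, r`) is multiplied by an
#' independent uniform factor in `(lo, hi)`; the cooperativity `n` is never
#' modified.  Mimics acceleration of every reaction by a temperature rise.
#'
#' @param params A [goodwin_params()].
#' @param lo,hi Factor bounds (defaults 1.1 and 1.9).
#' @return List with `params` (perturbed set) and `factors` (named vector).
#' @export
perturb_params <- function(params, lo = 1.1, hi = 1.9) {
  stopifnot(inherits(params, "goodwin_params"), hi >= lo, lo > 0)
  f <- stats::runif(6, lo, hi)
  names(f) <- c("k1", "k2", "k3", "p1", "p2", "r")
  tr <- params$transcription
  list(params = goodwin_params(params$k1 * f[1], params$k2 * f[2],
                               params$k3 * f[3], params$p1 * f[4],
                               params$p2 * f[5],
                               transcription_spec(tr$form, r = tr$r * f[6],
                                                  n = tr$n, K = tr$K)),
       factors = f)
}

ref_substream_seed <- function(master, i) {
  (as.numeric(master) * 48271 + i * 16807) %% 2147483647
}

#' Run the temperature-compensation sweep
#'
#' For each oscillating reference set, perturbations are drawn (redrawing
#' those that lose the oscillation) until `n_perturb` oscillation-persisting
#' records are collected; each record stores the reference and perturbed
#' periods `tau1, tau2`, their ratio (the relative period), the NS values
#' and their ratio (the relative NS), and both amplitudes.  A reference
#' whose perturbations fail to oscillate after ten times the quota of draws
#' is skipped with a warning.  Fully determined by the config seed.
#'
#' @param config A [sweep_config()].
#' @param references Optional pre-sampled reference list (from
#'   [sample_reference_sets()] with the same config).
#' @param progress Print progress every 10 references.
#' @return Data frame of sweep records, one row per perturbation.
#' @export
run_sweep <- function(config = sweep_config(), references = NULL,
                      progress = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  if (is.null(references)) references <- sample_reference_sets(config)
  rows <- vector("list", length(references) * config$n_perturb)
  idx <- 0L
  for (i in seq_along(references)) {
    ref <- references[[i]]
    m1 <- attr(ref, "measure")
    if (is.null(m1)) {
      m1 <- sweep_measure(ref, config$periods, config$steps_per_period,
                          config$jmax)
    }
    if (!isTRUE(m1$oscillating)) next
    sub_seed <- ref_substream_seed(config$seed, i)
    set.seed(sub_seed)
    kept <- 0L
    tries <- 0L
    while (kept < config$n_perturb && tries < 10L * config$n_perturb) {
      tries <- tries + 1L
      pert <- perturb_params(ref, config$factor_range[1],
                             config$factor_range[2])
      if (!hopf_possible(pert$params)) next
      m2 <- sweep_measure(pert$params, config$periods,
                          config$steps_per_period, config$jmax)
      if (!m2$oscillating) next
      kept <- kept + 1L
      idx <- idx + 1L
      tr <- ref$transcription
      rel <- m2$tau / m1$tau
      rows[[idx]] <- data.frame(
        ref_id = i, sub_seed = sub_seed,
        k1 = ref$k1, k2 = ref$k2, k3 = ref$k3, p1 = ref$p1, p2 = ref$p2,
        r = tr$r, n = tr$n,
        f_k1 = pert$factors[["k1"]], f_k2 = pert$factors[["k2"]],
        f_k3 = pert$factors[["k3"]], f_p1 = pert$factors[["p1"]],
        f_p2 = pert$factors[["p2"]], f_r = pert$factors[["r"]],
        tau1 = m1$tau, tau2 = m2$tau, rel_period = rel,
        ns1 = m1$ns, ns2 = m2$ns, rel_ns = m2$ns / m1$ns,
        amp1 = m1$amplitude, amp2 = m2$amplitude,
        rel_amp = m2$amplitude / m1$amplitude,
        compensated = rel >= config$band[1] & rel <= config$band[2])
    }
    if (kept < config$n_perturb) {
      warning(sprintf("reference %d: only %d oscillation-persisting perturbations after %d draws; reference skipped",
                      i, kept, tries))
      # drop partial records for this reference to keep the design balanced
      drop <- vapply(rows[seq_len(idx)],
                     function(d) d$ref_id[1] == i, logical(1))
      rows[seq_len(idx)][drop] <- list(NULL)
    }
    if (progress && i %% 10L == 0L) {
      message(sprintf("sweep: %d/%d references done", i, length(references)))
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  do.call(rbind, rows)
}

#' Summarize a sweep
#'
#' @param records Data frame from [run_sweep()].
#' @param band Relative-period band defining temperature compensation.
#' @return List with the total record count, the number with relative period
#'   at or above the lower band edge (`n_stable`), the number inside the
#'   band (`n_compensated`), the mean relative period, the Spearman rank
#'   correlation between relative period and relative NS, and the mean
#'   relative NS and relative amplitude among compensated records.
#' @export
summarize_sweep <- function(records, band = c(0.85, 1.15)) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  stable <- records$rel_period >= band[1]
  comp <- stable & records$rel_period <= band[2]
  list(n_total = nrow(records),
       n_stable = sum(stable),
       n_compensated = sum(comp),
       mean_rel_period = mean(records$rel_period),
       spearman_rel_period_rel_ns =
         stats::cor(records$rel_period, records$rel_ns, method = "spearman"),
       mean_rel_ns_compensated = if (any(comp)) mean(records$rel_ns[comp]) else NA_real_,
       mean_rel_amp_compensated = if (any(comp)) mean(records$rel_amp[comp]) else NA_real_)
}
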