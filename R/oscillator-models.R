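#' Transcription function specification
#'
#' The negative-feedback transcription function of the Goodwin oscillator.
#' Two forms are supported: the saturating Hill repressor
#' \eqn{f(x_3) = r / (1 + (x_3/K)^n)} and the power-law repressor
#' \eqn{f(x_3) = r / x_3^n}, which is the analytically tractable limit used
#' throughout the renormalization-group analysis.
#'
#' @param form `"hill_saturating"` or `"power_law"`.
#' @param r Maximal transcription rate (concentration/time), `> 0`.
#' @param n Cooperativity (Hill coefficient), `>= 1`.  Acts as the Hopf
#'   bifurcation parameter of the power-law model.
#' @param K Repression threshold concentration (`> 0`); required for the
#'   Hill form, ignored for the power-law form.
#' @return An object of class `transcription_spec`.
#' @examples
#' transcription_spec("power_law", r = 1, n = 10)
#' transcription_spec("hill_saturating", r = 1, n = 20, K = 0.0184)
#' @export
transcription_spec <- function(form = c("power_law", "hill_saturating"),
                               r, n, K = NULL) {
  form <- match.arg(form)
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r), r > 0,
            is.numeric(n), length(n) == 1L, is.finite(n), n >= 1)
  if (form == "hill_saturating") {
    if (is.null(K) || !is.numeric(K) || length(K) != 1L || !is.finite(K) ||
        K <= 0) {
      stop("hill_saturating form requires a threshold K > 0", call. = FALSE)
    }
  } else {
    K <- NA_real_
  }
  structure(list(form = form, r = unname(r), n = unname(n), K = unname(K)),
            class = "transcription_spec")
}

#' Goodwin model parameters
#'
#' Parameter vector of the three-variable Goodwin negative-feedback
#' oscillator: mRNA (`x1`) is transcribed under repression by the
#' phosphorylated protein (`x3`), translated into protein (`x2`), which is
#' phosphorylated into `x3`; each species decays linearly.
#'
#' @param k1,k2,k3 First-order degradation rates (1/time), `> 0`.
#' @param p1 Protein synthesis (translation) rate (1/time), `> 0`.
#' @param p2 Phosphorylation rate (1/time), `> 0`.
#' @param transcription A [transcription_spec()].
#' @return An object of class `goodwin_params`.
#' @examples
#' goodwin_params(1, 1, 1, 1, 1, transcription_spec("power_law", r = 1, n = 10))
#' @export
goodwin_params <- function(k1, k2, k3, p1, p2, transcription) {
  rates <- c(k1, k2, k3, p1, p2)
  stopifnot(is.numeric(rates), all(is.finite(rates)), all(rates > 0),
            inherits(transcription, "transcription_spec"))
  structure(list(k1 = unname(k1), k2 = unname(k2), k3 = unname(k3),
                 p1 = unname(p1), p2 = unname(p2),
                 transcription = transcription),
            class = "goodwin_params")
}

#' @export
print.goodwin_params <- function(x, ...) {
  tr <- x$transcription
  cat("Goodwin model parameters\n")
  cat(sprintf("  degradation  k = (%g, %g, %g)\n", x$k1, x$k2, x$k3))
  cat(sprintf("  synthesis    p1 = %g, p2 = %g\n", x$p1, x$p2))
  if (tr$form == "power_law") {
    cat(sprintf("  transcription f(x3) = r/x3^n, r = %g, n = %g\n", tr$r, tr$n))
  } else {
    cat(sprintf("  transcription f(x3) = r/(1+(x3/K)^n), r = %g, K = %g, n = %g\n",
                tr$r, tr$K, tr$n))
  }
  invisible(x)
}

# convenience constructor used heavily in sweeps and tests
#' Power-law Goodwin parameter shortcut
#'
#' Convenience wrapper building a [goodwin_params()] object with the
#' power-law transcription function \eqn{f(x_3)=r/x_3^n}.
#'
#' @param k1,k2,k3,p1,p2 Positive rate constants (1/time).
#' @param r Transcription rate.
#' @param n Cooperativity.
#' @return A `goodwin_params` object.
#' @export
goodwin_power_law <- function(k1, k2, k3, p1, p2, r, n) {
  goodwin_params(k1, k2, k3, p1, p2,
                 transcription_spec("power_law", r = r, n = n))
}

#' Light forcing specification
#'
#' Sinusoidal light input `I cos(Omega t)` added to the mRNA equation to
#' model a light-dark cycle.
#'
#' @param I Light intensity (concentration/time), `>= 0`.
#' @param Omega Angular frequency of the light-dark cycle (rad/time), `> 0`.
#' @return An object of class `forcing_spec`.
#' @export
forcing_spec <- function(I, Omega) {
  stopifnot(is.numeric(I), length(I) == 1L, is.finite(I), I >= 0,
            is.numeric(Omega), length(Omega) == 1L, is.finite(Omega),
            Omega > 0)
  structure(list(I = I, Omega = Omega), class = "forcing_spec")
}

#' Arrhenius temperature scaling of rate constants
#'
#' Each reaction rate follows the Arrhenius law
#' \eqn{b_i = A_i \exp(-E_i/(R T))} with frequency factor \eqn{A_i},
#' activation energy \eqn{E_i} (J/mol), gas constant \eqn{R = 8.314}
#' J/mol/K and absolute temperature \eqn{T} (K).
#'
#' @param A Named numeric vector of frequency factors (same units as the
#'   rates), all `> 0`.
#' @param E Activation energies (J/mol), `>= 0`, same length/names as `A`.
#' @param R Gas constant; fixed default 8.314 J/mol/K.
#' @return An object of class `arrhenius_spec`.
#' @seealso [arrhenius_rates()]
#' @export
arrhenius_spec <- function(A, E, R = 8.314) {
  stopifnot(is.numeric(A), all(is.finite(A)), all(A > 0),
            is.numeric(E), all(is.finite(E)), all(E >= 0),
            length(A) == length(E), is.numeric(R), R > 0)
  if (!is.null(names(A)) && is.null(names(E))) names(E) <- names(A)
  structure(list(A = A, E = E, R = R), class = "arrhenius_spec")
}

#' Evaluate Arrhenius rates at a temperature
#'
#' @param spec An [arrhenius_spec()].
#' @param T Absolute temperature in kelvin, `> 0`.
#' @return Numeric vector of rates \eqn{b_i = A_i \exp(-E_i/(R T))}.
#' @examples
#' sp <- arrhenius_spec(A = c(k1 = 2), E = c(k1 = 5e4))
#' arrhenius_rates(sp, 293) < arrhenius_rates(sp, 303)
#' @export
arrhenius_rates <- function(spec, T) {
  stopifnot(inherits(spec, "arrhenius_spec"), is.numeric(T), all(T > 0))
  spec$A * exp(-spec$E / (spec$R * T))
}

#' Lotka-Volterra parameters
#'
#' Parameters of the two-species Lotka-Volterra oscillator
#' \eqn{dx/dt = a x - \epsilon x y}, \eqn{dy/dt = -b y + \epsilon' x y}.
#'
#' @param a Prey growth rate, `> 0`.
#' @param b Predator death rate, `> 0`.
#' @param eps Predation rate, `> 0`.
#' @param eps_prime Conversion rate, `> 0`.
#' @return An object of class `lotka_volterra_params`.
#' @export
lotka_volterra_params <- function(a, b, eps, eps_prime) {
  v <- c(a, b, eps, eps_prime)
  stopifnot(is.numeric(v), all(is.finite(v)), all(v > 0))
  structure(list(a = a, b = b, eps = eps, eps_prime = eps_prime),
            class = "lotka_volterra_params")
}

#' Van der Pol parameters
#'
#' Parameter of the van der Pol oscillator
#' \eqn{\ddot x - \epsilon(1 - x^2)\dot x + x = 0}; `eps = 0` is the
#' harmonic limit, large `eps` gives relaxation oscillations.
#'
#' @param eps Nonlinearity strength, `>= 0`.
#' @return An object of class `van_der_pol_params`.
#' @export
van_der_pol_params <- function(eps) {
  stopifnot(is.numeric(eps), length(eps) == 1L, is.finite(eps), eps >= 0)
  structure(list(eps = eps), class = "van_der_pol_params")
}

transcription_f <- function(tr, x3) {
  if (tr$form == "power_law") tr$r / x3^tr$n else tr$r / (1 + (x3 / tr$K)^tr$n)
}

#' Right-hand side of the Goodwin equations
#'
#' Time derivatives of the (optionally light-forced) Goodwin model:
#' \deqn{\dot x_1 = f(x_3) - k_1 x_1 + I\cos(\Omega t),\quad
#'       \dot x_2 = p_1 x_1 - k_2 x_2,\quad
#'       \dot x_3 = p_2 x_2 - k_3 x_3.}
#'
#' @param state Numeric 3-vector `(x1, x2, x3)`.
#' @param params A [goodwin_params()].
#' @param forcing Optional [forcing_spec()]; `NULL` for the free-running model.
#' @param t Time (only used when forcing is present).
#' @return Numeric 3-vector of derivatives.
#' @export
goodwin_rhs <- function(state, params, forcing = NULL, t = 0) {
  stopifnot(inherits(params, "goodwin_params"), is.numeric(state),
            length(state) == 3L, all(is.finite(state)))
  tr <- params$transcription
  if (tr$form == "power_law" && state[3] <= 0) {
    stop(sprintf("power_law transcription undefined at x3 = %g (state = %s)",
                 state[3], paste(signif(state, 6), collapse = ", ")),
         call. = FALSE)
  }
  dx1 <- transcription_f(tr, state[3]) - params$k1 * state[1]
  if (!is.null(forcing)) {
    stopifnot(inherits(forcing, "forcing_spec"))
    dx1 <- dx1 + forcing$I * cos(forcing$Omega * t)
  }
  c(dx1,
    params$p1 * state[1] - params$k2 * state[2],
    params$p2 * state[2] - params$k3 * state[3])
}

#' Right-hand side of the Lotka-Volterra equations
#'
#' @param state Numeric 2-vector `(x, y)`, strictly positive.
#' @param params A [lotka_volterra_params()].
#' @param t Time (unused; autonomous system).
#' @return Numeric 2-vector of derivatives.
#' @export
lotka_volterra_rhs <- function(state, params, t = 0) {
  stopifnot(inherits(params, "lotka_volterra_params"), is.numeric(state),
            length(state) == 2L)
  if (any(state <= 0)) {
    stop("Lotka-Volterra state must be strictly positive", call. = FALSE)
  }
  c(params$a * state[1] - params$eps * state[1] * state[2],
    -params$b * state[2] + params$eps_prime * state[1] * state[2])
}

#' Right-hand side of the van der Pol equations
#'
#' First-order form `(x, v)` of
#' \eqn{\ddot x - \epsilon (1 - x^2) \dot x + x = 0}.
#'
#' @param state Numeric 2-vector `(x, v)`.
#' @param params A [van_der_pol_params()].
#' @param t Time (unused; autonomous system).
#' @return Numeric 2-vector of derivatives.
#' @export
van_der_pol_rhs <- function(state, params, t = 0) {
  stopifnot(inherits(params, "van_der_pol_params"), is.numeric(state),
            length(state) == 2L)
  c(state[2], params$eps * (1 - state[1]^2) * state[2] - state[1])
}

#' Fixed point of the Goodwin model
#'
#' Steady state of the unforced model.  For the power-law transcription
#' function it is closed-form,
#' \eqn{x_3^* = (p_1 p_2 r / s_3)^{1/(n+1)}} with \eqn{s_3 = k_1 k_2 k_3};
#' for the Hill form the scalar equation
#' \eqn{s_3 x_3 = p_1 p_2 f(x_3)} is solved numerically.
#'
#' @param params A [goodwin_params()].
#' @return Numeric 3-vector `(x1*, x2*, x3*)`.
#' @export
goodwin_fixed_point <- function(params) {
  tr <- params$transcription
  s3 <- params$k1 * params$k2 * params$k3
  pp <- params$p1 * params$p2
  if (tr$form == "power_law") {
    x3 <- (pp * tr$r / s3)^(1 / (tr$n + 1))
  } else {
    g <- function(x) s3 * x - pp * transcription_f(tr, x)
    hi <- pp * tr$r / s3  # f <= r so x3* <= p1 p2 r / s3
    x3 <- stats::uniroot(g, lower = hi * 1e-12, upper = hi * (1 + 1e-9),
                         tol = 1e-14 * max(1, hi))$root
  }
  x2 <- params$k3 * x3 / params$p2
  x1 <- params$k2 * x2 / params$p1
  c(x1 = x1, x2 = x2, x3 = x3)
}

#' Trajectory container
#'
#' Uniformly sampled multi-component time series produced by
#' [integrate_system()].
#'
#' @param values Numeric matrix, one column per component.
#' @param t0 Time of the first row.
#' @param dt Sampling interval between stored rows.
#' @param system Name of the generating system.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(values, t0 = 0, dt, system = "custom") {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), dt > 0, nrow(values) >= 2L,
            all(is.finite(values)))
  structure(list(values = values, t0 = t0, dt = dt, system = system),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %s, %d samples x %d components, t = [%g, %g], dt = %g>\n",
              x$system, nrow(x$values), ncol(x$values), x$t0,
              x$t0 + (nrow(x$values) - 1) * x$dt, x$dt))
  invisible(x)
}

#' Time axis of a trajectory
#' @param traj A [trajectory()].
#' @return Numeric vector of sample times.
#' @export
traj_time <- function(traj) {
  traj$t0 + (seq_len(nrow(traj$values)) - 1) * traj$dt
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  df <- data.frame(time = traj_time(x), x$values)
  names(df) <- c("time", colnames(x$values))
  df
}

default_goodwin_init <- function(params, displacement = 0.02) {
  fp <- goodwin_fixed_point(params)
  fp * c(1, 1, 1 + displacement)
}

#' Integrate an oscillator model
#'
#' Fixed-step classical fourth-order Runge-Kutta integration.  This is the
#' reference integration mode throughout the package (step 0.001 for the
#' Goodwin model and 0.0001 for the Lotka-Volterra and van der Pol systems
#' unless overridden); results are deterministic for fixed inputs.
#'
#' @param system `"goodwin"`, `"lotka_volterra"`, or `"van_der_pol"`.
#' @param params Matching parameter object.
#' @param init Initial state.  For the Goodwin model the default is the
#'   fixed point with `x3` displaced upward by 2%, which keeps power-law
#'   trajectories strictly positive.
#' @param t_end End time (integration starts at 0).
#' @param dt Integration step.  Defaults: 0.001 (Goodwin), 0.0001 (others).
#' @param forcing Optional [forcing_spec()] (Goodwin only).
#' @param thin Store every `thin`-th step (the integration itself always
#'   uses step `dt`).
#' @return A [trajectory()].  Errors with the first failing time if the
#'   state becomes non-finite (or non-positive where positivity is
#'   structurally required).
#' @examples
#' gp <- goodwin_power_law(1, 1, 1, 1, 1, r = 1, n = 10)
#' tr <- integrate_system("goodwin", gp, t_end = 50, dt = 0.005)
#' @export
integrate_system <- function(system = c("goodwin", "lotka_volterra",
                                        "van_der_pol"),
                             params, init = NULL, t_end, dt = NULL,
                             forcing = NULL, thin = 1L) {
  system <- match.arg(system)
  if (is.null(dt)) dt <- if (system == "goodwin") 0.001 else 0.0001
  stopifnot(dt > 0, t_end > dt, thin >= 1L)
  nsteps <- floor(t_end / dt + 1e-9)
  thin <- as.integer(thin)
  if (system == "goodwin") {
    stopifnot(inherits(params, "goodwin_params"))
    if (is.null(init)) init <- default_goodwin_init(params)
    stopifnot(length(init) == 3L)
    tr <- params$transcription
    I <- 0; Om <- 1
    if (!is.null(forcing)) {
      stopifnot(inherits(forcing, "forcing_spec"))
      I <- forcing$I; Om <- forcing$Omega
    }
    res <- rk4_goodwin_cpp(as.numeric(init), params$k1, params$k2, params$k3,
                           params$p1, params$p2, tr$r, tr$n,
                           if (tr$form == "power_law") 0L else 1L,
                           if (is.na(tr$K)) 1 else tr$K,
                           I, Om, dt, nsteps, thin)
    comp <- c("x1", "x2", "x3")
  } else if (system == "lotka_volterra") {
    stopifnot(inherits(params, "lotka_volterra_params"))
    if (is.null(init)) init <- c(params$b / params$eps_prime * 1.5,
                                 params$a / params$eps * 1.5)
    stopifnot(length(init) == 2L, all(init > 0))
    if (!is.null(forcing)) stop("forcing is only supported for the Goodwin model")
    res <- rk4_lv_cpp(as.numeric(init), params$a, params$b, params$eps,
                      params$eps_prime, dt, nsteps, thin)
    comp <- c("x", "y")
  } else {
    stopifnot(inherits(params, "van_der_pol_params"))
    if (is.null(init)) init <- c(1, 0)
    stopifnot(length(init) == 2L)
    if (!is.null(forcing)) stop("forcing is only supported for the Goodwin model")
    res <- rk4_vdp_cpp(as.numeric(init), params$eps, dt, nsteps, thin)
    comp <- c("x", "v")
  }
  if (isTRUE(res$diverged)) {
    stop(sprintf("integration of the %s model diverged at t = %g",
                 system, res$t_fail), call. = FALSE)
  }
  vals <- res$values[seq_len(res$rows), , drop = FALSE]
  colnames(vals) <- comp
  trajectory(vals, t0 = 0, dt = dt * thin, system = system)
}

# Local maxima of a sampled series with 3-point parabolic interpolation.
# Returns a matrix with columns t (interpolated time) and height
# (interpolated peak value).
local_maxima <- function(x, t0, dt) {
  n <- length(x)
  if (n < 3L) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("t", "height"))))
  core <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  core <- core[core > 1L & core < n]
  if (!length(core)) {
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("t", "height"))))
  }
  a <- x[core - 1L]; b <- x[core]; cc <- x[core + 1L]
  denom <- a - 2 * b + cc
  off <- ifelse(abs(denom) > 0, 0.5 * (a - cc) / denom, 0)
  off[!is.finite(off) | abs(off) > 1] <- 0
  h <- b - 0.25 * (a - cc) * off
  cbind(t = t0 + (core - 1L + off) * dt, height = h)
}

post_transient <- function(traj, transient_fraction, component = ncol(traj$values)) {
  n <- nrow(traj$values)
  i0 <- max(1L, floor(n * transient_fraction) + 1L)
  list(x = traj$values[i0:n, component],
       t0 = traj$t0 + (i0 - 1L) * traj$dt, dt = traj$dt)
}

#' Detect a limit cycle in a trajectory
#'
#' After discarding an initial transient, the trajectory is classified as a
#' sustained oscillation if at least three successive maxima of the monitored
#' component exist and their heights agree to within `rel_tol` (relative to
#' the oscillation amplitude where the mean level is not informative).
#' The tolerance separates limit cycles from slowly decaying spirals at the
#' default integration steps.
#'
#' @param traj A [trajectory()].
#' @param transient_fraction Fraction of the record discarded as transient
#'   (default 0.5).
#' @param rel_tol Relative tolerance on successive peak heights (default 1e-3).
#' @param component Column monitored (default: last, i.e. `x3` for Goodwin).
#' @return List with elements `oscillating` (logical), `amplitude`
#'   (post-transient peak-to-trough of the monitored component) and
#'   `n_peaks`.
#' @export
detect_limit_cycle <- function(traj, transient_fraction = 0.5,
                               rel_tol = 1e-3,
                               component = ncol(traj$values)) {
  stopifnot(inherits(traj, "trajectory"))
  win <- post_transient(traj, transient_fraction, component)
  if (length(win$x) < 10L) {
    stop("trajectory too short after transient discard", call. = FALSE)
  }
  pk <- local_maxima(win$x, win$t0, win$dt)
  amp <- max(win$x) - min(win$x)
  if (nrow(pk) < 3L) {
    return(list(oscillating = FALSE, amplitude = amp, n_peaks = nrow(pk)))
  }
  h <- pk[, "height"]
  # peak-height stationarity is judged against the oscillation swing of the
  # final third of the window, so a spiral that has already collapsed onto
  # the fixed point (tiny late swing, flat peaks) is not mistaken for a
  # sustained cycle
  late <- win$x[(length(win$x) - length(win$x) %/% 3):length(win$x)]
  amp_late <- max(late) - min(late)
  osc <- amp_late > 1e-6 * max(abs(win$x)) &&
    all(abs(diff(h)) <= rel_tol * amp_late)
  list(oscillating = osc, amplitude = amp, n_peaks = nrow(pk))
}

#' Measure the oscillation period of a trajectory
#'
#' Mean interval between successive post-transient maxima of the monitored
#' component, with 3-point parabolic interpolation of each peak for sub-step
#' accuracy.
#'
#' @inheritParams detect_limit_cycle
#' @return Period estimate (scalar).  Errors if fewer than two peaks are
#'   found after the transient.
#' @export
measure_period <- function(traj, transient_fraction = 0.5,
                           component = ncol(traj$values)) {
  stopifnot(inherits(traj, "trajectory"))
  win <- post_transient(traj, transient_fraction, component)
  pk <- local_maxima(win$x, win$t0, win$dt)
  if (nrow(pk) < 2L) {
    stop("fewer than two post-transient peaks; cannot measure a period",
         call. = FALSE)
  }
  mean(diff(pk[, "t"]))
}
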