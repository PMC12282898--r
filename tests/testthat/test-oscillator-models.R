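test_that("goodwin_rhs matches hand-evaluated derivatives", {
  hill <- goodwin_params(1, 1, 1, 1, 1,
                         transcription_spec("hill_saturating", r = 1, n = 2,
                                            K = 1))
  # f(1) = 1/(1 + 1) = 0.5
  expect_equal(goodwin_rhs(c(0, 0, 1), hill), c(0.5, 0, -1))
  pow <- gp_sym(n = 2)
  # f(2) = 1/4; dx3 = 1*0.5 - 1*2
  expect_equal(goodwin_rhs(c(1, 0.5, 2), pow), c(0.25 - 1, 1 - 0.5, -1.5))
})

test_that("forcing with I = 0 reduces to the unforced right-hand side", {
  p <- gp_asym()
  st <- c(0.4, 0.7, 1.1)
  expect_identical(goodwin_rhs(st, p, forcing_spec(0, 2), t = 3.7),
                   goodwin_rhs(st, p))
})

test_that("derivatives vanish at the fixed point (root-finding oracle)", {
  for (p in list(gp_sym(9), gp_asym(11),
                 goodwin_params(0.5, 1.5, 2.5, 2, 0.8,
                                transcription_spec("hill_saturating", r = 2,
                                                   n = 12, K = 0.3)))) {
    fp <- goodwin_fixed_point(p)
    expect_lt(max(abs(goodwin_rhs(fp, p))), 1e-10)
  }
})

test_that("power-law rhs raises a domain error at non-positive x3", {
  expect_error(goodwin_rhs(c(1, 1, -0.5), gp_sym()), "x3 = -0.5")
})

test_that("Arrhenius rates: zero activation energy, ratio inversion, monotonicity", {
  sp <- arrhenius_spec(A = c(k1 = 3, k2 = 0.5), E = c(k1 = 0, k2 = 0))
  expect_equal(arrhenius_rates(sp, 250), c(k1 = 3, k2 = 0.5))
  expect_equal(arrhenius_rates(sp, 320), c(k1 = 3, k2 = 0.5))
  # activation energy tuned so the rate doubles from 293 K to 303 K
  E2 <- log(2) * 8.314 / (1 / 293 - 1 / 303)
  sp2 <- arrhenius_spec(A = 1, E = E2)
  expect_equal(arrhenius_rates(sp2, 303) / arrhenius_rates(sp2, 293), 2,
               tolerance = 1e-12)
  temps <- seq(280, 320, by = 5)
  expect_true(all(diff(arrhenius_rates(sp2, temps)) > 0))
})

test_that("van der Pol at eps = 0 is harmonic with period 2*pi", {
  tr <- integrate_system("van_der_pol", van_der_pol_params(0),
                         init = c(1, 0), t_end = 12 * 2 * pi, dt = 0.001)
  expect_equal(measure_period(tr, transient_fraction = 0.1,
                              component = 1), 2 * pi, tolerance = 1e-3)
})

test_that("RK4 end-state error drops ~16x when the step is halved", {
  # harmonic oscillator (vdP, eps = 0) has the exact solution cos(t)
  err <- function(dt) {
    tr <- integrate_system("van_der_pol", van_der_pol_params(0),
                           init = c(1, 0), t_end = 10, dt = dt)
    abs(tr$values[nrow(tr$values), 1] - cos(10))
  }
  ratio <- err(0.02) / err(0.01)
  expect_gt(ratio, 12)
  expect_lt(ratio, 20)
})

test_that("RK4 agrees with deSolve's rk4 on a short Goodwin run", {
  skip_if_not_installed("deSolve")
  p <- gp_asym()
  init <- c(0.9, 1.0, 1.1)
  ours <- integrate_system("goodwin", p, init = init, t_end = 5, dt = 0.01)
  ref <- deSolve::rk4(y = init, times = seq(0, 5, by = 0.01),
                      func = function(t, y, parms) list(goodwin_rhs(y, p)),
                      parms = NULL)
  expect_equal(unname(ours$values[nrow(ours$values), ]),
               unname(ref[nrow(ref), 2:4]), tolerance = 1e-10)
})

test_that("Hill transcription with K = 0.0184, n = 20 sustains an oscillation", {
  p <- goodwin_params(1, 1, 1, 1, 1,
                      transcription_spec("hill_saturating", r = 1, n = 20,
                                         K = 0.0184))
  tr <- integrate_system("goodwin", p, t_end = 150, dt = 0.005, thin = 5)
  expect_true(detect_limit_cycle(tr)$oscillating)
})

test_that("oscillation onset brackets the Hopf threshold n = 8 for equal rates", {
  below <- sweep_measure(gp_sym(n = 7.5))
  above <- sweep_measure(gp_sym(n = 9))
  expect_false(below$oscillating)
  expect_true(above$oscillating)
})

test_that("uniform rate scaling rescales the period as 1/lambda", {
  p <- goodwin_power_law(0.8, 1.2, 1.0, 0.9, 1.1, r = 1.3, n = 12)
  lam <- 2.5
  p2 <- goodwin_power_law(0.8 * lam, 1.2 * lam, 1.0 * lam, 0.9 * lam,
                          1.1 * lam, r = 1.3 * lam, n = 12)
  t1 <- sweep_measure(p)$tau
  t2 <- sweep_measure(p2)$tau
  expect_equal(t2, t1 / lam, tolerance = 1e-3)
})

test_that("limit-cycle detection separates sines from damped spirals", {
  sine <- sine_trajectory(period = 24, amplitude = 0.7)
  lc <- detect_limit_cycle(sine, transient_fraction = 0.2)
  expect_true(lc$oscillating)
  expect_equal(lc$amplitude, 1.4, tolerance = 1e-3)
  t <- seq(0, 240, by = 0.06)
  damped <- trajectory(matrix(exp(-0.02 * t) * sin(2 * pi * t / 24), ncol = 1),
                       dt = 0.06, system = "damped")
  expect_false(detect_limit_cycle(damped, transient_fraction = 0.2)$oscillating)
})

test_that("measure_period recovers a 24 h sine period", {
  expect_equal(measure_period(sine_trajectory(), transient_fraction = 0.1),
               24, tolerance = 1e-3)
  expect_error(measure_period(trajectory(matrix(1:20 / 20, ncol = 1),
                                         dt = 1), 0.5),
               "fewer than two")
})

test_that("Lotka-Volterra rhs and positivity domain", {
  lv <- lotka_volterra_params(1, 1, 1, 1)
  expect_equal(lotka_volterra_rhs(c(1, 1), lv), c(0, 0))
  expect_equal(lotka_volterra_rhs(c(2, 0.5), lv), c(2 - 1, -0.5 + 1))
  expect_error(lotka_volterra_rhs(c(-1, 1), lv), "positive")
})

test_that("relaxation-limit van der Pol is more distorted than the weakly nonlinear one", {
  ns_of_vdp <- function(eps) {
    tr <- integrate_system("van_der_pol", van_der_pol_params(eps),
                           init = c(1.5, 0), t_end = 150, dt = 0.002,
                           thin = 10)
    tau <- measure_period(tr, 0.4, component = 1)
    win <- tr$values[(nrow(tr$values) %/% 2):nrow(tr$values), 1]
    dec <- gha_decompose(win, dt = tr$dt,
                         config = gha_config(jmax = 6, f1_hint = 1 / tau))
    ns_index(dec)$ns
  }
  expect_gt(ns_of_vdp(3), ns_of_vdp(0.1))
})

test_that("Lotka-Volterra uniform parameter scaling preserves relative-period law", {
  # scaling all four rates by c rescales time: period ratio = 1/c, NS ratio = 1
  measure_lv <- function(scl) {
    lv <- lotka_volterra_params(1 * scl, 1 * scl, 1 * scl, 1 * scl)
    tr <- integrate_system("lotka_volterra", lv, init = c(1.8, 1.0),
                           t_end = 120 / scl, dt = 0.001 / scl, thin = 20)
    tau <- measure_period(tr, 0.3, component = 1)
    win <- tr$values[(nrow(tr$values) %/% 3):nrow(tr$values), 1]
    dec <- gha_decompose(win, dt = tr$dt,
                         config = gha_config(jmax = 5, f1_hint = 1 / tau))
    list(tau = tau, ns = ns_index(dec)$ns)
  }
  a <- measure_lv(1)
  b <- measure_lv(1.5)
  expect_equal(b$tau / a$tau, 1 / 1.5, tolerance = 1e-3)
  expect_equal(b$ns / a$ns, 1, tolerance = 1e-3)
})

test_that("divergent integration reports the failing time", {
  # a step far above the stability limit makes the solution blow up
  p <- gp_sym(n = 12)
  expect_error(integrate_system("goodwin", p, init = c(1e-6, 1e-6, 50),
                                t_end = 3000, dt = 5),
               "diverged at t")
})
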