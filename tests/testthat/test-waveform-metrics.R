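test_that("GHA recovers a single cosine component", {
  t <- seq(0, 240, by = 0.1)
  d <- gha_decompose(cos(2 * pi * t / 24), dt = 0.1,
                     config = gha_config(jmax = 3))
  expect_equal(d$f1, 1 / 24, tolerance = 1e-5)
  expect_equal(d$components$r[1], 1, tolerance = 1e-3)
  expect_lt(d$components$r[2], 1e-3)
  expect_lt(d$residual_power, 1e-4 * d$total_power)
})

test_that("GHA round-trips a two-harmonic synthesis", {
  w <- 2 * pi / 24
  t <- seq(0, 240, by = 0.05)
  x <- sin(w * t) + 0.4 * sin(2 * w * t + 1.0)
  d <- gha_decompose(x, dt = 0.05, config = gha_config(jmax = 4))
  expect_equal(d$components$r[1], 1, tolerance = 1e-2)
  expect_equal(d$components$r[2], 0.4, tolerance = 1e-2)
  expect_equal(second_harmonic_phase(d), 1.0, tolerance = 0.02,
               ignore_attr = TRUE)
  # reconstruction captures essentially all signal power
  expect_lt(d$residual_power, 1e-4 * d$total_power)
})

test_that("constant input is flagged, not decomposed", {
  d <- gha_decompose(rep(3.2, 600), dt = 0.1, config = gha_config(jmax = 3))
  expect_true(d$constant)
  expect_true(all(d$components$r == 0))
  expect_error(ns_index(d), "undefined")
})

test_that("NS evaluates the harmonic-power ratio exactly", {
  expect_equal(ns_from_amplitudes(1), 1)
  expect_equal(ns_from_amplitudes(c(1, 0.5)), sqrt(2.5))
  expect_equal(ns_from_amplitudes(c(0, 1)), 2)
  expect_equal(ns_from_amplitudes(c(2, 1), m = 6, q = 0),
               sqrt((4 + 64) / (4 + 1)))
  d <- harmonic_components(1 / 24, r = c(1, 0.5))
  expect_equal(ns_index(d, 4, 2)$ns, sqrt(2.5))
})

test_that("NS is invariant under time shift and amplitude scaling", {
  w <- 2 * pi / 17
  dt <- 0.05
  t <- seq(0, 170, by = dt)
  for (seed in 1:5) {
    set.seed(seed)
    r2 <- runif(1, 0.05, 0.5)
    ph <- runif(2, -pi, pi)
    shift <- runif(1, 0, 17)
    scale <- runif(1, 0.2, 5)
    base <- function(tt) sin(w * tt + ph[1]) + r2 * sin(2 * w * tt + ph[2])
    ns0 <- ns_index(gha_decompose(base(t), dt = dt,
                                  config = gha_config(jmax = 3)))$ns
    ns1 <- ns_index(gha_decompose(scale * base(t + shift), dt = dt,
                                  config = gha_config(jmax = 3)))$ns
    expect_equal(ns1, ns0, tolerance = 1e-4)
    expect_gte(ns0 + 1e-9, 1)
  }
})

test_that("period formula: sinusoid case and monotonicity in added harmonics", {
  sine <- harmonic_components(1 / 24, r = 1)
  expect_equal(period_formula(1, 1, 1, sine), 2 * pi / sqrt(3),
               tolerance = 1e-12)
  taus <- vapply(c(0, 0.1, 0.25, 0.5), function(r2) {
    period_formula(1, 1, 1, harmonic_components(1 / 24, r = c(1, r2)))
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
})

test_that("period formula matches the simulated period to 0.5%", {
  for (p in list(gp_sym(10), gp_asym(12))) {
    m <- sweep_measure(p)
    s <- structural_sums(p$k1, p$k2, p$k3)
    tau_pred <- 2 * pi / sqrt(s[["s2"]]) * m$ns
    expect_equal(tau_pred, m$tau, tolerance = 5e-3)
  }
})

test_that("R statistic follows the one-sided coefficient convention", {
  # |a1| = 1 (r = 2): R = 1 / (1^2 * 1) = 1
  expect_equal(r_statistic(harmonic_components(1, r = 2)), 1)
  # |a1| = 0.5: R = 0.5 / 0.25 = 2
  expect_equal(r_statistic(harmonic_components(1, r = 1)), 2)
  # |a1| = 1, |a2| = 0.3: R = 1 / (1 + 0.09 * 16)
  expect_equal(r_statistic(harmonic_components(1, r = c(2, 0.6))), 1 / 2.44)
  # adding harmonic power at fixed |a1| strictly decreases R
  r_vals <- vapply(c(0, 0.2, 0.4, 0.8), function(r2) {
    r_statistic(harmonic_components(1, r = c(2, r2)))
  }, numeric(1))
  expect_true(all(diff(r_vals) < 0))
})

test_that("second-harmonic phase: synthesis round trip and low-confidence flag", {
  w <- 2 * pi / 24
  t <- seq(0, 360, by = 0.05)
  x <- 2.4 * sin(w * t + 0.5) + 0.72 * sin(2 * w * t + 0.8 + 2 * 0.5)
  d <- gha_decompose(x, dt = 0.05, config = gha_config(jmax = 3))
  ph <- second_harmonic_phase(d)
  expect_equal(as.numeric(ph), 0.8, tolerance = 0.02)
  expect_false(attr(ph, "low_confidence"))
  dp <- gha_decompose(sin(w * t), dt = 0.05, config = gha_config(jmax = 3))
  expect_true(attr(second_harmonic_phase(dp), "low_confidence"))
})

test_that("phase convention converts to complex-coefficient arguments", {
  d <- harmonic_components(1, r = c(2, 1), alpha = c(0.4, -0.3))
  expect_equal(coefficient_argument(d, 1), 0.4 - pi / 2)
  expect_equal(coefficient_argument(d, 2), -0.3 - pi / 2)
})
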