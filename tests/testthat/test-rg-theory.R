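test_that("structural sums match hand evaluation and homogeneity degrees", {
  expect_equal(structural_sums(1, 1, 1), c(s1 = 3, s2 = 3, s3 = 1, s4 = 8))
  expect_equal(structural_sums(1, 2, 3), c(s1 = 6, s2 = 11, s3 = 6, s4 = 60))
  s <- structural_sums(0.7, 1.9, 3.2)
  s_scaled <- structural_sums(0.7 * 2, 1.9 * 2, 3.2 * 2)
  expect_equal(unname(s_scaled / s), c(2, 4, 8, 8))
  # s4/s3 >= 8 with equality only for equal rates (AM-GM)
  expect_gt(s[["s4"]] / s[["s3"]], 8)
})

test_that("RG solution at the bifurcation point: epsilon = 0, omega = sqrt(s2)", {
  sol <- rg_solution(gp_sym(n = 8))
  expect_equal(sol$epsilon, 0)
  expect_equal(sol$omega, sqrt(3))
  expect_equal(sol$amp1, 0)
  expect_equal(sol$amp2, 0)
  expect_error(rg_solution(gp_sym(n = 7.9)), "below the Hopf")
  expect_error(rg_solution(goodwin_params(1, 1, 1, 1, 1,
    transcription_spec("hill_saturating", r = 1, n = 10, K = 1))),
    "power_law")
})

test_that("omega is degree-1 and alpha, epsilon degree-0 under uniform rate scaling", {
  for (lam in c(0.5, 2, 7)) {
    a <- rg_solution(goodwin_power_law(0.6, 1.1, 2.3, 0.9, 1.4, r = 2, n = 12))
    b <- rg_solution(goodwin_power_law(0.6 * lam, 1.1 * lam, 2.3 * lam,
                                       0.9 * lam, 1.4 * lam, r = 2 * lam,
                                       n = 12))
    expect_equal(b$omega, lam * a$omega, tolerance = 1e-12)
    expect_equal(b$alpha, a$alpha, tolerance = 1e-12)
    expect_equal(b$epsilon, a$epsilon, tolerance = 1e-9)
    expect_equal(b$A1, a$A1, tolerance = 1e-12)
  }
})

test_that("RG waveform round-trips its own second-harmonic phase to 1e-6", {
  sol <- rg_solution(gp_asym(n = 11))
  Tper <- 2 * pi / sol$omega
  dt <- Tper / 500
  t <- seq(0, 50 * Tper - dt / 2, by = dt)
  d <- gha_decompose(evaluate_rg_waveform(sol, t), dt = dt,
                     config = gha_config(jmax = 2,
                                         f1_hint = sol$omega / (2 * pi),
                                         passes = 3))
  expect_equal(as.numeric(second_harmonic_phase(d)), sol$alpha,
               tolerance = 1e-6)
  expect_equal(d$f1 * 2 * pi, sol$omega, tolerance = 1e-8)
  # NS of the two-harmonic waveform is self-consistent with the coefficients
  expect_equal(ns_index(d)$ns, ns_from_amplitudes(c(sol$amp1, sol$amp2)),
               tolerance = 1e-4)
})

test_that("RG-vs-RK4 waveform discrepancy shrinks monotonically toward the Hopf point", {
  # the comparison is between mean-centered waveforms: the oscillatory shape
  # is the second-order content of the solution, while the cycle mean
  # carries a first-order offset from the at-bifurcation constant term
  k <- c(1, 2, 3)
  s <- structural_sums(k[1], k[2], k[3])
  tau_lin <- 2 * pi / sqrt(s[["s2"]])
  rms_gap <- vapply(c(1.2, 0.6, 0.3, 0.15), function(eps) {
    p <- goodwin_power_law(k[1], k[2], k[3], 1, 1, r = 1,
                           n = s[["s4"]] / s[["s3"]] + eps)
    sol <- rg_solution(p)
    tr <- integrate_system("goodwin", p, t_end = 1200 * tau_lin,
                           dt = tau_lin / 2000, thin = 10)
    win <- waveclock:::post_transient(tr, 0.98)  # last ~24 periods
    tt <- (seq_along(win$x) - 1) * win$dt
    tau_m <- measure_period(tr, 0.9)
    dec <- gha_decompose(win$x, dt = win$dt,
                         config = gha_config(jmax = 2, f1_hint = 1 / tau_m))
    w_sim <- 2 * pi * dec$f1
    rg <- evaluate_rg_waveform(sol, (tt + dec$components$alpha[1] / w_sim) *
                                 w_sim / sol$omega)
    sqrt(mean(((rg - mean(rg)) - (win$x - mean(win$x)))^2)) /
      diff(range(win$x))
  }, numeric(1))
  expect_true(all(diff(rms_gap) < 0))
  expect_lt(rms_gap[length(rms_gap)], 0.05)
})

test_that("A1 elasticities sum to zero and A1 is scale-invariant", {
  set.seed(42)
  for (i in 1:20) {
    p <- random_oscillating_params()
    el <- a1_elasticities(p)
    expect_lt(abs(el$sum), 1e-6)
    # signs: phosphorylation and transcription rates always lower A1
    expect_true(all(el$elasticities[c("p1", "p2", "r")] < 0))
    lam <- runif(1, 0.5, 3)
    p2 <- goodwin_power_law(p$k1 * lam, p$k2 * lam, p$k3 * lam, p$p1 * lam,
                            p$p2 * lam, r = p$transcription$r * lam,
                            n = p$transcription$n)
    expect_equal(rg_solution(p2)$A1, rg_solution(p)$A1, tolerance = 1e-9)
  }
})

test_that("differentials: zero input, Euler homogeneity, symbolic vs finite differences", {
  k <- c(0.9, 1.7, 2.4)
  n <- 13
  expect_equal(differentials(k, c(0, 0, 0), n)[c("domega", "dalpha")],
               list(domega = 0, dalpha = 0))
  # uniform relative bump: domega = h * omega (degree 1), dalpha = 0 (degree 0)
  h <- 1e-3
  d <- differentials(k, h * k, n)
  sol <- rg_solution(goodwin_power_law(k[1], k[2], k[3], 1, 1, r = 1, n = n))
  expect_equal(d$domega, h * sol$omega, tolerance = 1e-9)
  expect_equal(d$dalpha, 0, tolerance = 1e-12)
  # cross-validate the symbolic gradients against central finite differences
  omega_of <- function(kk) {
    rg_solution(goodwin_power_law(kk[1], kk[2], kk[3], 1, 1, r = 1,
                                  n = n))$omega
  }
  alpha_of <- function(kk) {
    rg_solution(goodwin_power_law(kk[1], kk[2], kk[3], 1, 1, r = 1,
                                  n = n))$alpha
  }
  for (i in 1:3) {
    hstep <- 1e-6 * k[i]
    kp <- k; kp[i] <- k[i] + hstep
    km <- k; km[i] <- k[i] - hstep
    fd_o <- (omega_of(kp) - omega_of(km)) / (2 * hstep)
    fd_a <- (alpha_of(kp) - alpha_of(km)) / (2 * hstep)
    expect_equal(d$grad_omega[i], fd_o, tolerance = 1e-6)
    expect_equal(d$grad_alpha[i], fd_a, tolerance = 1e-6)
  }
})

test_that("the period-preserving surface forces the phase to fall, approaching tangency at high n", {
  cls12 <- classify_dalpha_on_domega_surface(12, grid_n = 16L)
  expect_equal(cls12$fraction_negative, 1)
  cls20 <- classify_dalpha_on_domega_surface(20, grid_n = 16L)
  expect_equal(cls20$fraction_negative, 1)
  # the dalpha = 0 surface is approached (but not crossed) as n grows
  expect_gt(cls20$max_dalpha, cls12$max_dalpha)
  expect_lt(cls20$max_dalpha, 0)
})

test_that("damped-oscillator demo: limits, Taylor frequency error, RK4 comparison", {
  t <- seq(0, 50, by = 0.01)
  # eps -> 0: RG and exact coincide
  small <- damped_oscillator_rg(1e-6, A0 = 1, phi0 = 0.3, t = t)
  expect_lt(small$max_gap, 1e-8)
  d <- damped_oscillator_rg(0.1, t = t)
  expect_equal(d$freq_error, -0.1^4 / 8, tolerance = 0.01)
  # independent RK4 integration of x'' + 2 eps x' + x = 0 at eps = 0.2
  eps <- 0.2
  y <- c(cos(0.3), -eps * cos(0.3) - sqrt(1 - eps^2) * sin(0.3))
  dt <- 0.001
  nst <- 50 / dt
  out <- numeric(nst + 1)
  out[1] <- y[1]
  rhs <- function(y) c(y[2], -2 * eps * y[2] - y[1])
  for (i in seq_len(nst)) {
    k1 <- rhs(y); k2 <- rhs(y + dt / 2 * k1); k3 <- rhs(y + dt / 2 * k2)
    k4 <- rhs(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1] <- y[1]
  }
  tg <- seq(0, 50, by = dt)
  rg <- damped_oscillator_rg(eps, A0 = 1, phi0 = 0.3, t = tg)
  expect_lt(max(abs(rg$rg - out)), 0.02)
})
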