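fly_like <- function(amps = c(1, 0.3), noise = 0, damping = 0.01,
                     duration = 72) {
  synth_waveform(waveform_spec(period = 24, amplitudes = amps,
                               damping = damping, duration = duration,
                               noise = noise))
}

test_that("noise replicates: zero bounds, CLT mean, distinct seeds", {
  s <- fly_like()
  cfg0 <- pipeline_config(noise_amp = 0, n_replicates = 10L)
  reps0 <- add_noise_replicates(s, cfg0, seed = 1)
  expect_true(all(reps0 == s$value))
  cfg <- pipeline_config(noise_amp = 0.4, n_replicates = 100L)
  reps <- add_noise_replicates(s, cfg, seed = 1)
  expect_true(all(abs(rowMeans(reps) - s$value) < 5 * 0.4 / sqrt(3 * 100)))
  reps2 <- add_noise_replicates(s, cfg, seed = 2)
  expect_false(identical(reps, reps2))
})

test_that("spline resampling is exact at the nodes and for cubics", {
  t <- 0:30
  y <- 0.3 * t^3 - 2 * t^2 + t - 5
  rs <- spline_resample(t, y, dt = 0.25)
  expect_equal(rs$value[rs$time %in% t], y, tolerance = 1e-8)
  expect_equal(rs$value, 0.3 * rs$time^3 - 2 * rs$time^2 + rs$time - 5,
               tolerance = 1e-6)
  # hourly sinusoid, 24 h period: sub-1e-3 interpolation error
  ts <- 0:96
  ys <- sin(2 * pi * ts / 24)
  rs2 <- spline_resample(ts, ys, dt = 0.1)
  inner <- rs2$time > 2 & rs2$time < 94
  expect_lt(max(abs(rs2$value - sin(2 * pi * rs2$time / 24))[inner]), 1e-3)
  expect_error(spline_resample(c(0, 1, 1, 2), 1:4, 0.1), "increasing")
})

test_that("exponential detrending recovers a known envelope", {
  t <- seq(0, 96, by = 0.1)
  base <- 3 + sin(2 * pi * t / 24)
  flat <- exponential_detrend(t, base, "minima")
  expect_lt(abs(flat$lambda), 1e-6)
  expect_equal(flat$value, base, tolerance = 1e-4)
  # strong enough oscillation that cycle minima survive the envelope
  damped <- (3 + 2 * sin(2 * pi * t / 24)) * exp(-0.1 * t)
  fit <- exponential_detrend(t, damped, "minima")
  expect_equal(fit$lambda, 0.1, tolerance = 0.05)
  # anchor minima approximately equalized after detrending
  h <- fit$value[fit$anchors]
  expect_lt(max(abs(h - mean(h))), 0.1 * abs(mean(h)))
  # detrending preserves the fundamental period
  d_raw <- gha_decompose(base, dt = 0.1, config = gha_config(jmax = 2))
  d_det <- gha_decompose(fit$value, dt = 0.1, config = gha_config(jmax = 2))
  expect_equal(d_det$f1, d_raw$f1, tolerance = 5e-3)
})

test_that("per-replicate NS: sinusoid gives 1, known distortion is recovered", {
  cfg <- pipeline_config(noise_amp = 0, n_replicates = 3L)
  sine <- fly_like(amps = 1, damping = 0)
  reps <- add_noise_replicates(sine, cfg, seed = 1)
  ns <- ns_per_replicate(reps, sine$time, cfg)
  expect_equal(as.numeric(ns), rep(1, 3), tolerance = 1e-3)
  dist <- fly_like(amps = c(1, 0.3), damping = 0.01)
  ns2 <- ns_per_replicate(add_noise_replicates(dist, cfg, seed = 1),
                          dist$time, cfg)
  expect_equal(as.numeric(ns2), rep(ns_from_amplitudes(c(1, 0.3)), 3),
               tolerance = 0.02)
})

test_that("NS spread shrinks as the noise amplitude goes to zero", {
  s <- fly_like(amps = c(1, 0.3))
  spread <- vapply(c(0.4, 0.1, 0), function(na) {
    cfg <- pipeline_config(noise_amp = na, n_replicates = 30L)
    stats::sd(ns_per_replicate(add_noise_replicates(s, cfg, seed = 5),
                               s$time, cfg))
  }, numeric(1))
  expect_true(all(diff(spread) < 0))
})

test_that("Welch test matches the closed-form statistic", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 3, 4, 5, 6)
  res <- welch_t_test(a, b)
  # hand formula: se = sqrt(2.5/5 + 2.5/5) = 1, t = -1, Welch df = 8
  expect_equal(res$t, -1)
  expect_equal(res$df, 8)
  expect_equal(res$p, 2 * pt(-1, 8))
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # equal variances and sizes: df approaches 2n - 2
  set.seed(1)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(welch_t_test(x, y)$df, 98, tolerance = 0.05)
})

test_that("pipeline report: identical inputs with shared seeds give t = 0; labels antisymmetric", {
  s <- fly_like(amps = c(1, 0.25))
  cfg <- pipeline_config(noise_amp = 0.2, n_replicates = 20L)
  same <- run_pipeline(s, s, cfg, seed_a = 99, seed_b = 99)
  expect_equal(same$ttest$t, 0)
  pair <- synth_condition_pair(
    waveform_spec(amplitudes = amplitudes_for_ns(1.1), damping = 0.01),
    waveform_spec(amplitudes = amplitudes_for_ns(1.5), damping = 0.01),
    seed = 3)
  ab <- run_pipeline(pair$a, pair$b, cfg, seed_a = 5, seed_b = 6)
  ba <- run_pipeline(pair$b, pair$a, cfg, seed_a = 6, seed_b = 5)
  expect_equal(ba$ttest$t, -ab$ttest$t, tolerance = 1e-12)
  # the higher-distortion condition is recovered as higher
  expect_lt(ab$mean_a, ab$mean_b)
})
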