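test_that("the admissible interval solves the cubic inequality (root oracle)", {
  iv <- solve_sync_interval(1, 0.01)
  # independent oracle: roots of Omega^3 - Omega = +/- 0.01 via polyroot
  up <- Re(polyroot(c(-0.01, -1, 0, 1)))
  up <- up[which.min(abs(up - 1))]
  dn <- Re(polyroot(c(0.01, -1, 0, 1)))
  dn <- dn[which.min(abs(dn - 1))]
  expect_equal(unname(iv), c(dn, up), tolerance = 1e-9)
  expect_equal(unname(iv), c(0.99501, 1.00496), tolerance = 1e-4)
  expect_equal(unname(solve_sync_interval(2.3, 0)), c(2.3, 2.3))
})

test_that("bound width is linear in intensity and shrinks with distortion", {
  p <- gp_asym(12)
  dec1 <- harmonic_components(1, r = c(2, 0))
  widths <- vapply(c(0.01, 0.02, 0.04), function(I) {
    unname(diff(sync_bound(p, I, decomp = dec1)$interval))
  }, numeric(1))
  expect_equal(widths[2] / widths[1], 2, tolerance = 1e-2)
  expect_equal(widths[3] / widths[2], 2, tolerance = 1e-2)
  # adding a second harmonic at fixed |a1| shrinks the admissible interval
  w2 <- vapply(c(0, 0.3, 0.6), function(r2) {
    unname(diff(sync_bound(p, 0.02,
                           decomp = harmonic_components(1, r = c(2, r2)))$interval))
  }, numeric(1))
  expect_true(all(diff(w2) < 0))
})

test_that("natural frequency from the entrainment balance approaches sqrt(s2) for a sinusoid", {
  p <- gp_sym(10)
  sb <- sync_bound(p, 0.01, decomp = harmonic_components(1, r = 2))
  expect_equal(sb$omega, sqrt(3), tolerance = 1e-12)
  # the balance frequency reproduces the simulated frequency and approaches
  # sqrt(s2) as the waveform becomes sinusoidal near the Hopf point
  err <- vapply(c(10, 8.3), function(n) {
    pp <- gp_sym(n)
    sb_n <- sync_bound(pp, 0.01)
    m <- sweep_measure(pp)
    expect_equal(sb_n$omega, 2 * pi / m$tau, tolerance = 2e-3)
    abs(sb_n$omega - sqrt(3)) / sqrt(3)
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.02)
})

test_that("entrainment detection: locks at zero detuning, not without coupling", {
  p <- gp_sym(10)
  sb <- sync_bound(p, 0.02)
  crit <- entrainment_criterion()
  expect_true(as.logical(
    entrainment_check(p, forcing_spec(0.02, sb$omega), crit)))
  # I = 0: free-running period cannot match an off-resonant drive
  expect_false(as.logical(
    entrainment_check(p, forcing_spec(0, sb$omega * 1.05), crit)))
  # far outside the analytic bound: no lock
  expect_false(as.logical(
    entrainment_check(p, forcing_spec(0.02, sb$omega * 1.2), crit)))
})

test_that("tongue width grows with intensity; entrained points satisfy the exact balance", {
  p <- gp_sym(10)
  res <- lapply(c(0.01, 0.03), function(I) {
    compare_bound_vs_numeric(p, I, step = 5e-4)
  })
  # necessity with the entrained solution's own coefficients holds everywhere
  expect_true(all(vapply(res, `[[`, logical(1), "balance_all_satisfied")))
  w <- vapply(res, `[[`, numeric(1), "numeric_width")
  expect_gt(w[1], 0)
  expect_gt(w[2], w[1])
  # the free-running interval tracks the tongue's scale (same order of
  # magnitude) even though the entrained waveform adapts
  expect_gt(w[1], 0.3 * res[[1]]$analytic_width)
  expect_lt(w[1], 4 * res[[1]]$analytic_width)
})

test_that("signed entrainment balance verifies against the entrained decomposition", {
  p <- gp_sym(10)
  sb <- sync_bound(p, 0.02)
  b <- sync_balance_check(p, forcing_spec(0.02, sb$omega + 0.01))
  expect_true(b$entrained)
  expect_true(b$satisfied)
  expect_equal(b$lhs, b$rhs, tolerance = 0.02)
})
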