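#' Entrainment criterion
#'
#' Quantitative stand-in for "amplitude change smaller than rounding error":
#' after discarding `transient_cycles` forcing cycles, the model counts as
#' entrained when (a) the successive peak heights of `x3` over
#' `check_cycles` cycles vary by less than `amp_tol` (relative) and (b) the
#' mean peak interval matches the forcing period `2 pi / Omega` within
#' `period_tol` (relative).
#'
#' Near a tongue edge at weak coupling the unlocked state is a torus whose
#' beat can be slower than the check window, in which case it masquerades
#' as locked; `check_cycles` sets the discriminating power, since the
#' accumulated phase slip over the window is what the period-match test
#' detects.  Use a long window (hundreds to thousands of cycles) when a
#' definitive yes/no at a specific frequency matters more than scan speed.
#'
#' @param transient_cycles Forcing cycles discarded before checking.
#' @param check_cycles Forcing cycles examined.
#' @param amp_tol Relative amplitude-stationarity tolerance.
#' @param period_tol Relative period-match tolerance.
#' @param steps_per_cycle RK4 steps per forcing cycle.
#' @return An object of class `entrainment_criterion`.
#' @export
entrainment_criterion <- function(transient_cycles = 300L, check_cycles = 10L,
                                  amp_tol = 1e-6, period_tol = 1e-4,
                                  steps_per_cycle = 1000L) {
  stopifnot(transient_cycles >= 1L, check_cycles >= 3L, amp_tol > 0,
            period_tol > 0, steps_per_cycle >= 200L)
  structure(list(transient_cycles = as.integer(transient_cycles),
                 check_cycles = as.integer(check_cycles),
                 amp_tol = amp_tol, period_tol = period_tol,
                 steps_per_cycle = as.integer(steps_per_cycle)),
            class = "entrainment_criterion")
}

#' Check 1:1 entrainment of the forced Goodwin model
#'
#' Integrates the light-forced model past transients and applies the
#' [entrainment_criterion()].
#'
#' @param params A [goodwin_params()].
#' @param forcing A [forcing_spec()].
#' @param criterion An [entrainment_criterion()].
#' @param init Initial state (default: displaced fixed point).  Passing the
#'   final state of a neighboring forcing frequency ("warm start") shortens
#'   the locking transient considerably and is what the tongue scan does.
#' @return Logical flag with attributes `amp_variation` (relative spread of
#'   the checked peak heights), `period_error` (relative mismatch with
#'   the forcing period), and `final_state` (state at the end of the
#'   integration, for warm-started scans).  `FALSE` (with `NA` attributes)
#'   if the forced trajectory diverges out of the criterion's reach.
#' @export
entrainment_check <- function(params, forcing,
                              criterion = entrainment_criterion(),
                              init = NULL) {
  stopifnot(inherits(params, "goodwin_params"),
            inherits(forcing, "forcing_spec"),
            inherits(criterion, "entrainment_criterion"))
  t_cycle <- 2 * pi / forcing$Omega
  n_cycles <- criterion$transient_cycles + criterion$check_cycles
  dt <- t_cycle / criterion$steps_per_cycle
  traj <- tryCatch(
    integrate_system("goodwin", params, init = init,
                     t_end = n_cycles * t_cycle, dt = dt,
                     forcing = forcing, thin = 2L),
    error = function(e) NULL)
  fail <- structure(FALSE, amp_variation = NA_real_, period_error = NA_real_,
                    final_state = NULL)
  if (is.null(traj)) return(fail)
  frac <- criterion$transient_cycles / n_cycles
  win <- post_transient(traj, frac)
  pk <- local_maxima(win$x, win$t0, win$dt)
  final_state <- traj$values[nrow(traj$values), ]
  if (nrow(pk) < 3L) {
    attr(fail, "final_state") <- final_state
    return(fail)
  }
  h <- pk[, "height"]
  amp_var <- (max(h) - min(h)) / max(abs(h))
  per <- mean(diff(pk[, "t"]))
  per_err <- abs(per - t_cycle) / t_cycle
  # demand one peak per forcing cycle (1:1 locking, not higher-order plateaus)
  one_to_one <- abs(nrow(pk) - criterion$check_cycles) <= 1L
  structure(isTRUE(amp_var <= criterion$amp_tol &&
                     per_err <= criterion$period_tol && one_to_one),
            amp_variation = amp_var, period_error = per_err,
            final_state = final_state, window = win)
}

#' Entrainment balance check with the entrained solution's own coefficients
#'
#' For an entrained forced solution the balance
#' \eqn{\Omega^3 - \omega^2\Omega = \tfrac12 p_1 p_2 I R \sin\beta}
#' holds exactly with \eqn{\omega}, `R`, and \eqn{\beta} computed from the
#' Fourier coefficients of that entrained solution (and therefore
#' \eqn{|\Omega^3 - \omega^2\Omega| \le \tfrac12 p_1 p_2 I R}).  This
#' function integrates the forced model, decomposes the entrained window,
#' and evaluates both sides.
#'
#' @inheritParams entrainment_check
#' @param jmax Harmonics used for the entrained decomposition.
#' @return List with `entrained`; and when entrained: `lhs`
#'   (\eqn{\Omega^3-\omega^2\Omega}), `rhs` (\eqn{\tfrac12 p_1p_2 I R
#'   \sin\beta}), `half_width` (\eqn{\tfrac12 p_1p_2 I R}), `satisfied`
#'   (`|lhs| <= half_width`), `omega_entrained`, `R_entrained`, `beta`, and
#'   `final_state`.
#' @export
sync_balance_check <- function(params, forcing,
                               criterion = entrainment_criterion(),
                               init = NULL, jmax = 10L) {
  e <- entrainment_check(params, forcing, criterion, init)
  out <- list(entrained = as.logical(e),
              final_state = attr(e, "final_state"))
  if (!out$entrained) return(out)
  win <- attr(e, "window")
  dec <- gha_decompose(win$x, dt = win$dt, t0 = win$t0,
                       config = gha_config(jmax = jmax,
                                           f1_hint = forcing$Omega / (2 * pi)))
  s <- structural_sums(params$k1, params$k2, params$k3)
  a <- dec$components$r / 2
  j <- seq_along(a)
  w_ent <- sqrt(s[["s2"]] * sum(a^2 * j^2) / sum(a^2 * j^4))
  R_ent <- a[1] / sum(a^2 * j^4)
  beta <- coefficient_argument(dec, 1)
  H <- 0.5 * params$p1 * params$p2 * forcing$I * R_ent
  lhs <- forcing$Omega^3 - w_ent^2 * forcing$Omega
  out$lhs <- lhs
  out$rhs <- H * sin(beta)
  out$half_width <- H
  out$satisfied <- abs(lhs) <= H
  out$omega_entrained <- w_ent
  out$R_entrained <- R_ent
  out$beta <- beta
  out$decomp <- dec
  out
}

#' Natural frequency and waveform bound for synchronization
#'
#' From the Fourier coefficients of the free-running limit cycle, computes
#' the natural angular frequency
#' \eqn{\omega = \sqrt{s_2 \sum_j |a_j|^2 j^2 / \sum_j |a_j|^2 j^4}},
#' the waveform statistic `R` ([r_statistic()]), and the admissible forcing
#' frequencies solving
#' \deqn{|\Omega^3 - \omega^2 \Omega| \le \tfrac{1}{2} p_1 p_2 I R.}
#' The cubic on the left is monotone increasing near `Omega = omega`, so the
#' admissible set around the natural frequency is an interval; it shrinks
#' when harmonic distortion grows (R falls) and widens linearly with the
#' light intensity `I`.
#'
#' @param params A [goodwin_params()].
#' @param I Light intensity.
#' @param decomp Optional `harmonic_decomposition` of the free-running
#'   `x3(t)`; computed by simulation ([sweep_measure()]-style integration
#'   plus GHA) when omitted.
#' @param jmax Harmonics used when `decomp` is computed here.
#' @return An object of class `sync_bound`: list with `omega`, `R`,
#'   `half_width` (`p1 p2 I R / 2`), `interval` (admissible `c(lo, hi)`,
#'   degenerate at `omega` when `I = 0`), and `decomp`.
#' @export
sync_bound <- function(params, I, decomp = NULL, jmax = 10L) {
  stopifnot(inherits(params, "goodwin_params"), I >= 0)
  if (is.null(decomp)) {
    m <- sweep_measure_decomp(params, jmax = jmax)
    decomp <- m$decomp
  }
  s <- structural_sums(params$k1, params$k2, params$k3)
  a <- decomp$components$r / 2
  if (a[1] <= 0) stop("no fundamental component in the decomposition",
                      call. = FALSE)
  j <- seq_along(a)
  omega <- sqrt(s[["s2"]] * sum(a^2 * j^2) / sum(a^2 * j^4))
  R <- r_statistic(decomp)
  H <- 0.5 * params$p1 * params$p2 * I * R
  structure(list(omega = omega, R = R, half_width = H,
                 interval = solve_sync_interval(omega, H), decomp = decomp),
            class = "sync_bound")
}

#' Admissible forcing-frequency interval of the cubic inequality
#'
#' Solves `|Omega^3 - omega^2 Omega| <= H` for the interval of `Omega`
#' containing `omega` (the branch on which the cubic is monotone).
#'
#' @param omega Natural angular frequency.
#' @param H Bound half-width (`>= 0`).
#' @return `c(lo, hi)`; both equal `omega` when `H = 0`.
#' @export
solve_sync_interval <- function(omega, H) {
  stopifnot(omega > 0, H >= 0)
  if (H == 0) return(c(lo = omega, hi = omega))
  g <- function(x) x^3 - omega^2 * x
  # monotone-increasing branch for x > omega/sqrt(3)
  lo_floor <- omega / sqrt(3)
  lo <- if (g(lo_floor) >= -H) lo_floor else
    stats::uniroot(function(x) g(x) + H, lower = lo_floor, upper = omega,
                   tol = 1e-13 * omega)$root
  hi_cap <- omega + 1
  while (g(hi_cap) < H) hi_cap <- hi_cap * 2
  hi <- stats::uniroot(function(x) g(x) - H, lower = omega, upper = hi_cap,
                       tol = 1e-13 * omega)$root
  c(lo = lo, hi = hi)
}

#' @export
print.sync_bound <- function(x, ...) {
  cat(sprintf("Synchronization bound: omega = %.6g, R = %.6g, half-width = %.3g\n",
              x$omega, x$R, x$half_width))
  cat(sprintf("  admissible Omega in [%.6g, %.6g] (width %.3g)\n",
              x$interval[1], x$interval[2], diff(x$interval)))
  invisible(x)
}

# free-running decomposition used by sync_bound and compare_bound_vs_numeric
sweep_measure_decomp <- function(params, jmax = 10L) {
  m <- sweep_measure(params, jmax = jmax)
  if (!m$oscillating) {
    stop("the unforced model does not sustain an oscillation", call. = FALSE)
  }
  list(decomp = m$decomp, tau = m$tau, amplitude = m$amplitude)
}

#' Numerical Arnold tongue (1:1 entrainment range)
#'
#' Scans the forcing frequency `Omega` on a uniform grid (default step
#' 0.0001) and reports the contiguous block of entrained frequencies around
#' the natural frequency.  Isolated entrained points away from that block
#' (higher-order locking plateaus) are recorded but excluded from the tongue
#' edges.
#'
#' The scan starts at the grid point nearest the natural frequency and
#' walks outward in both directions, warm-starting every integration from
#' the final state of its neighbor, which keeps locking transients short.
#'
#' @param params A [goodwin_params()].
#' @param I Light intensity.
#' @param omega_range Scan range `c(lo, hi)`; defaults to the analytic
#'   admissible interval (free-running approximation) inflated to twice its
#'   width about its center (with a minimum probing width of 10 grid steps
#'   each side).
#' @param step Grid step (default 1e-4).
#' @param criterion An [entrainment_criterion()]; its `transient_cycles`
#'   applies to the first (cold) point of each directional walk.
#' @param warm_cycles Transient cycles for warm-started points.
#' @param balance Also evaluate the entrained-coefficient balance
#'   ([sync_balance_check()]) at every entrained grid point.
#' @return An object of class `arnold_tongue`: list with `Omega` (grid),
#'   `entrained` (flags), `Omega_small`, `Omega_large` (tongue edges; `NA`
#'   when the tongue is empty), `width`, `I`, `omega_natural`, `bound`
#'   (free-running [sync_bound()]), and (when `balance = TRUE`)
#'   `balance_satisfied` per grid point (`NA` where not entrained).
#' @export
arnold_tongue <- function(params, I, omega_range = NULL, step = 1e-4,
                          criterion = entrainment_criterion(),
                          warm_cycles = 150L, balance = FALSE) {
  stopifnot(inherits(params, "goodwin_params"), I >= 0, step > 0)
  sb <- sync_bound(params, I)
  if (is.null(omega_range)) {
    ctr <- mean(sb$interval)
    half <- max(diff(sb$interval), 10 * step)
    omega_range <- c(ctr - half, ctr + half)
  }
  grid <- seq(omega_range[1], omega_range[2], by = step)
  ent <- rep(NA, length(grid))
  bal <- rep(NA, length(grid))
  warm_crit <- criterion
  warm_crit$transient_cycles <- as.integer(warm_cycles)
  i_start <- which.min(abs(grid - sb$omega))
  for (dir in c(1L, -1L)) {
    idxs <- if (dir == 1L) seq(i_start, length(grid)) else
      if (i_start > 1L) seq(i_start - 1L, 1L) else integer(0)
    state <- NULL
    for (ii in idxs) {
      crit_ii <- if (is.null(state)) criterion else warm_crit
      f <- forcing_spec(I, grid[ii])
      if (balance) {
        b <- sync_balance_check(params, f, crit_ii, init = state)
        ent[ii] <- b$entrained
        bal[ii] <- if (b$entrained) b$satisfied else NA
        state <- b$final_state
      } else {
        e <- entrainment_check(params, f, crit_ii, init = state)
        ent[ii] <- as.logical(e)
        state <- attr(e, "final_state")
      }
    }
  }
  # contiguous block containing the grid point nearest the natural frequency
  Omega_small <- Omega_large <- NA_real_
  if (any(ent)) {
    i0 <- which.min(abs(grid - sb$omega))
    blocks <- rle(ent)
    ends <- cumsum(blocks$lengths)
    starts <- ends - blocks$lengths + 1L
    bi <- which(blocks$values & starts <= i0 & ends >= i0)
    if (length(bi) == 0L) {
      # natural frequency not itself on an entrained point: take the block
      # nearest to it
      cand <- which(blocks$values)
      if (length(cand)) {
        d <- pmin(abs(grid[starts[cand]] - sb$omega),
                  abs(grid[ends[cand]] - sb$omega))
        bi <- cand[which.min(d)]
      }
    }
    if (length(bi) == 1L) {
      Omega_small <- grid[starts[bi]]
      Omega_large <- grid[ends[bi]]
    }
  }
  structure(list(Omega = grid, entrained = ent, Omega_small = Omega_small,
                 Omega_large = Omega_large,
                 width = if (is.na(Omega_small)) 0 else Omega_large - Omega_small,
                 I = I, omega_natural = sb$omega, bound = sb, step = step,
                 balance_satisfied = if (balance) bal else NULL),
            class = "arnold_tongue")
}

#' @export
print.arnold_tongue <- function(x, ...) {
  if (is.na(x$Omega_small)) {
    cat(sprintf("Arnold tongue (I = %g): empty on the scanned grid\n", x$I))
  } else {
    cat(sprintf("Arnold tongue (I = %g): Omega in [%.6g, %.6g], width %.3g\n",
                x$I, x$Omega_small, x$Omega_large, x$width))
  }
  invisible(x)
}

#' Compare the numerical tongue with the analytic bound
#'
#' The cubic inequality is a necessary condition for entrainment when its
#' coefficients come from the entrained solution itself; with that
#' convention every numerically entrained frequency satisfies it
#' (`balance_all_satisfied`).  The a-priori interval computed from the
#' free-running limit cycle's coefficients ([sync_bound()]) replaces the
#' entrained waveform with the unforced one; it tracks the tongue's width
#' and its shrinkage with distortion, but because the entrained waveform
#' adapts to the drive, the numerical tongue can overhang that approximate
#' interval at finite intensity — `contained` reports whether it does.
#'
#' @param params A [goodwin_params()].
#' @param I Light intensity.
#' @param ... Passed to [arnold_tongue()].
#' @return List with `tongue`, `bound`, `contained` (tongue inside the
#'   free-running interval, up to one grid step), `balance_all_satisfied`
#'   (entrained-coefficient inequality at every entrained grid point),
#'   `numeric_width`, `analytic_width`.
#' @export
compare_bound_vs_numeric <- function(params, I, ...) {
  tong <- arnold_tongue(params, I, balance = TRUE, ...)
  sb <- tong$bound
  contained <- TRUE
  if (!is.na(tong$Omega_small)) {
    contained <- tong$Omega_small >= sb$interval[1] - tong$step &&
      tong$Omega_large <= sb$interval[2] + tong$step
  }
  list(tongue = tong, bound = sb, contained = contained,
       balance_all_satisfied = all(tong$balance_satisfied, na.rm = TRUE),
       numeric_width = tong$width,
       analytic_width = unname(diff(sb$interval)))
}
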