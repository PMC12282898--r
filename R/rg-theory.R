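#' Structural sums of the degradation rates
#'
#' The four symmetric functions of `(k1, k2, k3)` that parameterize the
#' analytic limit-cycle solution:
#' `s1 = k1 + k2 + k3`, `s2 = k1 k2 + k2 k3 + k3 k1`, `s3 = k1 k2 k3`,
#' `s4 = (k1 + k2)(k2 + k3)(k3 + k1)`.  Note `s4 = s1 s2 - s3`, and by
#' AM-GM `s4 / s3 >= 8` with equality iff `k1 = k2 = k3`.
#'
#' @param k1,k2,k3 Positive degradation rates.
#' @return Named numeric vector `(s1, s2, s3, s4)`.
#' @examples
#' structural_sums(1, 1, 1)  # c(3, 3, 1, 8)
#' @export
structural_sums <- function(k1, k2, k3) {
  stopifnot(k1 > 0, k2 > 0, k3 > 0)
  c(s1 = k1 + k2 + k3,
    s2 = k1 * k2 + k2 * k3 + k3 * k1,
    s3 = k1 * k2 * k3,
    s4 = (k1 + k2) * (k2 + k3) * (k3 + k1))
}

# A1 depends only on the rates (not on the bifurcation distance), so it is
# computed without the at-bifurcation gate; used by rg_solution and by the
# elasticity stencil.
rg_a1 <- function(params) {
  s <- structural_sums(params$k1, params$k2, params$k3)
  ppr <- params$p1 * params$p2 * params$transcription$r
  s[["s4"]] * s[["s1"]] / (12 * s[["s3"]] * sqrt(s[["s1"]]^2 + 4 * s[["s2"]])) *
    (s[["s3"]] / ppr)^(s[["s3"]] / (s[["s1"]] * s[["s2"]]))
}

#' Renormalization-group solution of the power-law Goodwin model
#'
#' Second-order approximate limit-cycle waveform of the phosphorylated
#' protein obtained by resumming the secular perturbation series about the
#' Hopf point of the power-law model (\eqn{f(x_3) = r/x_3^n}):
#' \deqn{x_3(t) = \left(\frac{p_1 p_2 r}{s_3}\right)^{s_3/(s_1 s_2)}
#'   + \varepsilon A_0 \sin(\omega t)
#'   + \varepsilon^2 A_1 A_0^2 \sin(2\omega t + \alpha) + o(\varepsilon^2),}
#' with bifurcation parameter \eqn{\varepsilon = n - s_4/s_3}, angular
#' velocity
#' \deqn{\omega = \sqrt{s_2} - \varepsilon\,
#'   \frac{s_1 s_3 s_4}{6\,(2 s_1 s_2^2 - (s_1^2 + 6 s_2) s_3)\sqrt{s_2}},}
#' second-harmonic phase \eqn{\alpha = \arctan(s_1 / (2\sqrt{s_2}))}, and
#' amplitude factors
#' \deqn{A_0 = \sqrt{\frac{4 s_3^3 ((s_1^2+s_2)^2 - 2\varepsilon s_1 s_3)
#'   (s_1^2 + 4 s_2)}{\varepsilon (2 s_1 s_2^2 - (s_1^2+6 s_2) s_3)
#'   (s_1^2+s_2)^2 s_4 s_1 s_2}}
#'   \left(\frac{p_1 p_2 r}{s_3}\right)^{s_3/(s_1 s_2)},\quad
#'  A_1 = \frac{s_4 s_1}{12 s_3 \sqrt{s_1^2 + 4 s_2}}
#'   \left(\frac{s_3}{p_1 p_2 r}\right)^{s_3/(s_1 s_2)}.}
#' At the bifurcation (`epsilon = 0`) the waveform degenerates to the fixed
#' point and `omega = sqrt(s2)` exactly.  `omega` is homogeneous of degree 1
#' and `alpha`, `epsilon` of degree 0 under uniform scaling of the rates;
#' `A1` is invariant under uniform scaling of all six rates.
#'
#' @param params A [goodwin_params()] with power-law transcription and
#'   `epsilon >= 0` (at or above the Hopf point).
#' @return An object of class `rg_solution` with fields `s1..s4`, `epsilon`,
#'   `omega`, `alpha`, `A0`, `A1`, `level` (fixed-point term), and the
#'   derived harmonic amplitudes `amp1 = epsilon A0` and
#'   `amp2 = epsilon^2 A1 A0^2` (both finite, and zero, at `epsilon = 0`).
#' @export
rg_solution <- function(params) {
  stopifnot(inherits(params, "goodwin_params"))
  tr <- params$transcription
  if (tr$form != "power_law") {
    stop("the RG solution is derived for the power_law transcription form",
         call. = FALSE)
  }
  s <- structural_sums(params$k1, params$k2, params$k3)
  s1 <- s[["s1"]]; s2 <- s[["s2"]]; s3 <- s[["s3"]]; s4 <- s[["s4"]]
  eps <- tr$n - s4 / s3
  if (eps < 0) {
    stop(sprintf("parameters are below the Hopf bifurcation (epsilon = %g < 0)",
                 eps), call. = FALSE)
  }
  D <- 2 * s1 * s2^2 - (s1^2 + 6 * s2) * s3
  level <- (params$p1 * params$p2 * tr$r / s3)^(s3 / (s1 * s2))
  omega <- sqrt(s2) - eps * s1 * s3 * s4 / (6 * D * sqrt(s2))
  alpha <- atan(s1 / (2 * sqrt(s2)))
  rad <- 4 * s3^3 * ((s1^2 + s2)^2 - 2 * eps * s1 * s3) * (s1^2 + 4 * s2) /
    (D * (s1^2 + s2)^2 * s4 * s1 * s2)
  if (rad <= 0) {
    stop("RG amplitude radicand is non-positive; parameters are outside the
 expansion's validity range", call. = FALSE)
  }
  amp1 <- sqrt(eps * rad) * level          # = eps * A0, finite at eps = 0
  A0 <- if (eps > 0) sqrt(rad / eps) * level else Inf
  A1 <- rg_a1(params)
  amp2 <- A1 * amp1^2                      # eps^2 A1 A0^2 = A1 (eps A0)^2
  structure(list(s1 = s1, s2 = s2, s3 = s3, s4 = s4, epsilon = eps,
                 omega = omega, alpha = alpha, A0 = A0, A1 = A1,
                 level = level, amp1 = amp1, amp2 = amp2, params = params),
            class = "rg_solution")
}

#' @export
print.rg_solution <- function(x, ...) {
  cat("RG limit-cycle solution (power-law Goodwin model)\n")
  cat(sprintf("  epsilon = %.6g  omega = %.6g  alpha = %.6g\n",
              x$epsilon, x$omega, x$alpha))
  cat(sprintf("  level = %.6g  amp1 = %.6g  amp2 = %.6g\n",
              x$level, x$amp1, x$amp2))
  invisible(x)
}

#' Evaluate the RG waveform on a time grid
#'
#' @param sol An [rg_solution()].
#' @param t Times.
#' @return `level + amp1 sin(omega t) + amp2 sin(2 omega t + alpha)`.
#' @export
evaluate_rg_waveform <- function(sol, t) {
  stopifnot(inherits(sol, "rg_solution"))
  sol$level + sol$amp1 * sin(sol$omega * t) +
    sol$amp2 * sin(2 * sol$omega * t + sol$alpha)
}

#' Elasticities of the second-harmonic amplitude factor A1
#'
#' Logarithmic sensitivities \eqn{\partial \ln A_1 / \partial \ln q_i} for
#' each rate \eqn{q_i \in \{k_1, k_2, k_3, p_1, p_2, r\}}, estimated by
#' central finite differences on the log scale.  Because `A1` is invariant
#' under uniform scaling of all six rates, the six elasticities sum to zero.
#'
#' @param params A [goodwin_params()] with power-law transcription, at or
#'   above the Hopf point.
#' @param rel_step Relative step of the central stencil (default 1e-6; use
#'   0.01 for the 1%-bump variant).
#' @return List with `elasticities` (named numeric, length 6) and `sum`.
#' @export
a1_elasticities <- function(params, rel_step = 1e-6) {
  stopifnot(inherits(params, "goodwin_params"), rel_step > 0)
  invisible(rg_solution(params))  # validates oscillatory regime at the center
  bump <- function(p, what, fac) {
    if (what %in% c("k1", "k2", "k3", "p1", "p2")) {
      p[[what]] <- p[[what]] * fac
    } else {
      p$transcription$r <- p$transcription$r * fac
    }
    p
  }
  qs <- c("k1", "k2", "k3", "p1", "p2", "r")
  el <- vapply(qs, function(q) {
    up <- log(rg_a1(bump(params, q, 1 + rel_step)))
    dn <- log(rg_a1(bump(params, q, 1 - rel_step)))
    (up - dn) / (log(1 + rel_step) - log(1 - rel_step))
  }, numeric(1))
  list(elasticities = el, sum = sum(el))
}

# symbolic partial derivatives of omega(k; n) and alpha(k), built once at
# load time via stats::deriv (the closed forms are smooth compositions of
# arithmetic, sqrt and atan)
omega_expression <- quote(
  sqrt(k1 * k2 + k2 * k3 + k3 * k1) -
    (n - ((k1 + k2) * (k2 + k3) * (k3 + k1)) / (k1 * k2 * k3)) *
      ((k1 + k2 + k3) * (k1 * k2 * k3) *
         ((k1 + k2) * (k2 + k3) * (k3 + k1))) /
      (6 * (2 * (k1 + k2 + k3) * (k1 * k2 + k2 * k3 + k3 * k1)^2 -
              ((k1 + k2 + k3)^2 + 6 * (k1 * k2 + k2 * k3 + k3 * k1)) *
                (k1 * k2 * k3)) *
         sqrt(k1 * k2 + k2 * k3 + k3 * k1))
)
alpha_expression <- quote(
  atan((k1 + k2 + k3) / (2 * sqrt(k1 * k2 + k2 * k3 + k3 * k1)))
)
omega_deriv <- stats::deriv(omega_expression, c("k1", "k2", "k3"),
                            function.arg = c("k1", "k2", "k3", "n"))
alpha_deriv <- stats::deriv(alpha_expression, c("k1", "k2", "k3"),
                            function.arg = c("k1", "k2", "k3"))

#' Total differentials of the RG frequency and second-harmonic phase
#'
#' Exact (symbolically differentiated) total differentials
#' \eqn{d\omega = \sum_i (\partial\omega/\partial k_i) dk_i} and
#' \eqn{d\alpha = \sum_i (\partial\alpha/\partial k_i) dk_i} under a
#' degradation-rate change `dk`.  `omega` depends on the cooperativity `n`
#' through the bifurcation distance; `alpha` does not.
#'
#' @param k Numeric 3-vector of degradation rates.
#' @param dk Numeric 3-vector of rate variations.
#' @param n Cooperativity at which `omega` is evaluated.
#' @return List with `domega`, `dalpha`, and the gradients `grad_omega`,
#'   `grad_alpha`.
#' @export
differentials <- function(k, dk, n) {
  stopifnot(length(k) == 3L, all(k > 0), length(dk) == 3L, n >= 1)
  go <- as.numeric(attr(omega_deriv(k[1], k[2], k[3], n), "gradient"))
  ga <- as.numeric(attr(alpha_deriv(k[1], k[2], k[3]), "gradient"))
  list(domega = sum(go * dk), dalpha = sum(ga * dk),
       grad_omega = go, grad_alpha = ga)
}

#' Sign of the phase differential on the period-preserving surface
#'
#' Samples the level set `domega = 0` (the degradation-rate combinations for
#' which a prescribed rate increase `dk` leaves the RG frequency unchanged)
#' on a logarithmic grid over `(k1, k2)` by locating sign changes of
#' `domega` along `k3` and refining each crossing with 1-D root finding.  At
#' each surface point the sign of `dalpha` is recorded.  Finding
#' `dalpha < 0` on the whole surface means the second-harmonic phase must
#' fall — the waveform must steepen its rise — whenever the period is held
#' against faster rates.
#'
#' The closed forms are evaluated over the whole grid as formal functions of
#' the rates (the level set largely lies where the distance to the Hopf
#' point is negative; each point's `epsilon` is reported so users can
#' restrict attention to the oscillatory subset, which for moderate `n`
#' contains no `domega = 0` points at all).  Because the gradient of
#' `omega` is homogeneous of degree 0 and that of `alpha` of degree -1, the
#' sign pattern on the surface is invariant along rays `k -> lambda k`, so
#' the choice of `k_range` does not affect the classification.
#'
#' @param n Cooperativity.
#' @param dk Numeric 3-vector of rate increases (default `c(0.3, 0.2, 0.1)`).
#' @param k_range Range of each rate (default `c(0.05, 5)`).
#' @param grid_n Grid points per axis (default 40).
#' @return List with `surface` (data frame: `k1, k2, k3, domega, dalpha,
#'   epsilon`), `fraction_negative`, `max_dalpha`, and `n_points`.  Errors
#'   if the level set is empty on the grid.
#' @export
classify_dalpha_on_domega_surface <- function(n, dk = c(0.3, 0.2, 0.1),
                                              k_range = c(0.05, 5),
                                              grid_n = 40L) {
  stopifnot(n >= 1, length(dk) == 3L, length(k_range) == 2L,
            k_range[1] > 0, k_range[2] > k_range[1], grid_n >= 8L)
  ks <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = grid_n))
  dom <- function(k3, k1, k2) {
    as.numeric(sum(attr(omega_deriv(k1, k2, k3, n), "gradient") * dk))
  }
  eps_at <- function(k1, k2, k3) {
    n - (k1 + k2) * (k2 + k3) * (k3 + k1) / (k1 * k2 * k3)
  }
  out <- vector("list", grid_n * grid_n)
  idx <- 0L
  for (i in seq_len(grid_n)) {
    for (jj in seq_len(grid_n)) {
      k1 <- ks[i]; k2 <- ks[jj]
      vals <- vapply(ks, dom, numeric(1), k1 = k1, k2 = k2)
      sgn <- sign(vals)
      cross <- which(sgn[-1] * sgn[-grid_n] < 0)
      for (ci in cross) {
        root <- stats::uniroot(dom, lower = ks[ci], upper = ks[ci + 1],
                               k1 = k1, k2 = k2, tol = 1e-10)$root
        da <- as.numeric(sum(attr(alpha_deriv(k1, k2, root),
                                  "gradient") * dk))
        idx <- idx + 1L
        out[[idx]] <- c(k1 = k1, k2 = k2, k3 = root, domega = 0,
                        dalpha = da, epsilon = eps_at(k1, k2, root))
      }
    }
  }
  if (idx == 0L) {
    stop(sprintf("no domega = 0 surface points found for n = %g", n),
         call. = FALSE)
  }
  surface <- as.data.frame(do.call(rbind, out[seq_len(idx)]))
  list(surface = surface,
       fraction_negative = mean(surface$dalpha < 0),
       max_dalpha = max(surface$dalpha),
       n_points = idx)
}

#' RG solution of the linear damped oscillator (pedagogical demo)
#'
#' For \eqn{\ddot x + 2\epsilon \dot x + x = 0} the RG resummation of the
#' secular perturbation series yields
#' \eqn{x_{RG}(t) = A_0 e^{-\epsilon t} \cos((1 - \epsilon^2/2) t + \phi_0)},
#' to be compared with the exact solution
#' \eqn{A_0 e^{-\epsilon t} \cos(\sqrt{1-\epsilon^2}\, t + \phi_0)}.  The
#' frequency error is \eqn{\sqrt{1-\epsilon^2} - (1 - \epsilon^2/2) =
#' -\epsilon^4/8 + O(\epsilon^6)}: the resummed solution is globally valid
#' (uniform in `t` up to the phase drift of that order).
#'
#' @param eps Damping, `0 < eps < 1`.
#' @param A0 Initial amplitude.
#' @param phi0 Initial phase.
#' @param t Time grid.
#' @return List with `rg`, `exact` (series on `t`), `max_gap`
#'   (max pointwise difference), and `freq_error`.
#' @export
damped_oscillator_rg <- function(eps, A0 = 1, phi0 = 0, t) {
  stopifnot(eps > 0, eps < 1)
  env <- A0 * exp(-eps * t)
  rg <- env * cos((1 - eps^2 / 2) * t + phi0)
  exact <- env * cos(sqrt(1 - eps^2) * t + phi0)
  list(rg = rg, exact = exact, max_gap = max(abs(rg - exact)),
       freq_error = sqrt(1 - eps^2) - (1 - eps^2 / 2))
}
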