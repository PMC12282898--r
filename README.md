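# waveclock

Waveform distortion as the organizing principle of temperature compensation
and entrainment in circadian oscillator models.

Circadian clocks hold a ~24 h period even though their component reactions
accelerate with temperature. `waveclock` implements a quantitative analysis
of this puzzle on the three-variable Goodwin negative-feedback oscillator
(mRNA → protein → phosphoprotein → transcription repression),

    dx1/dt = f(x3) - k1 x1 (+ I cos(Ωt) under light forcing)
    dx2/dt = p1 x1 - k2 x2
    dx3/dt = p2 x2 - k3 x3,

built around one identity: writing the limit cycle of `x3` as a Fourier
series with coefficients `a_j`, the period of the linear-degradation model
is

    τ = 2π/√s2 · NS(4,2),   s2 = k1k2 + k2k3 + k3k1,

where

    NS = sqrt( Σ_j |a_j|² j^m / Σ_j |a_j|² j^q ),   m > q ≥ 0,

the *non-sinusoidal power*, equals 1 for a sinusoid and grows with
harmonic distortion. Faster (hotter) rates increase `s2`, so a
temperature-compensated period forces `NS` up: the waveform must distort.
The same distortion narrows the admissible band of entraining light-dark
frequencies, `|Ω³ − ω²Ω| ≤ ½ p1 p2 I R` with
`R = |a_1| / Σ_j |a_j|² j⁴`.

## What the package provides

- **Oscillator models** (`integrate_system`, `goodwin_rhs`,
  `arrhenius_rates`, `detect_limit_cycle`, `measure_period`): compiled
  fixed-step RK4 integration of the Goodwin model (free-running, forced,
  Arrhenius-scaled) plus the auxiliary Lotka–Volterra and van der Pol
  systems; peak-interpolated period measurement.
- **Waveform metrics** (`gha_decompose`, `ns_index`, `period_formula`,
  `r_statistic`, `second_harmonic_phase`): generalized harmonic analysis
  (greedy residual-minimizing sinusoid extraction with harmonic locking)
  and the waveform statistics above.
- **Analytic theory** (`rg_solution`, `evaluate_rg_waveform`,
  `a1_elasticities`, `differentials`,
  `classify_dalpha_on_domega_surface`, `damped_oscillator_rg`): the
  second-order renormalization-group (envelope) solution of the power-law
  Goodwin limit cycle — frequency, second-harmonic phase and amplitudes in
  closed form — with exact symbolic sensitivities showing that holding the
  period against faster rates forces the second-harmonic phase down
  (steeper rise, longer tail).
- **Temperature sweep** (`run_sweep`, `summarize_sweep`): the randomized
  compensation experiment — 100 oscillating random reference sets × 49
  multiplicative "heating" perturbations each.
- **Entrainment** (`arnold_tongue`, `sync_bound`, `sync_balance_check`,
  `compare_bound_vs_numeric`): numerical 1:1 Arnold-tongue scans with
  warm-started continuation, and the analytic synchronization bound.
- **Reanalysis pipeline** (`run_pipeline` and stages): the
  reporter-curve protocol — uniform-noise replicates, spline resampling,
  exponential detrending, one-period GHA, per-replicate NS, Welch's
  *t*-test — with synthetic generators (`synth_waveform`,
  `synth_condition_pair`, `synth_goodwin_fixture`) providing exact ground
  truth.

## Worked example

```r
library(waveclock)

p <- goodwin_power_law(1, 2, 3, 1, 1, r = 1, n = 12)
m <- sweep_measure(p)          # integrate, detect the cycle, measure
m$tau
#> [1] 2.041762                 # simulated period
m$ns
#> [1] 1.077759                 # NS(4,2): mildly distorted waveform

s <- structural_sums(p$k1, p$k2, p$k3)
2 * pi / sqrt(s[["s2"]]) * m$ns
#> [1] 2.041762                 # period formula reproduces the simulation

sol <- rg_solution(p)
c(sol$omega, 2 * pi / m$tau)
#> [1] 3.058186 3.077335        # analytic vs simulated frequency (eps = 2)

sync_bound(p, I = 0.03)$interval
#>       lo       hi
#> 3.069907 3.084708             # admissible entrainment frequencies
```

The period formula matches the simulated period because the identity is
exact for the true Fourier series; the residual (here below the printed
precision) is harmonic truncation plus estimation error. The analytic
frequency sits within 0.7% of the simulation even this far above the Hopf
point.

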