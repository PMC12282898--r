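---
title: "Waveform distortion, temperature compensation, and entrainment in the Goodwin clock model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Waveform distortion, temperature compensation, and entrainment in the Goodwin clock model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waveclock)
```

## The scientific question

Circadian clocks keep a near-24 h period although almost every underlying
reaction accelerates with temperature (typically 2–3× per 10 °C, following
the Arrhenius law).  This package implements a quantitative account of one
resolution of that paradox: if all rates speed up but the period must stay
fixed, the *waveform* of the gene-activity rhythm cannot stay the same — it
must become more distorted (steeper rise, longer falling tail), with more
power in its higher harmonics.  The same waveform distortion, in turn,
narrows the range of light–dark cycle frequencies to which the clock can
entrain.

Everything is developed on the three-variable Goodwin oscillator

$$
\dot x_1 = f(x_3) - k_1 x_1,\qquad
\dot x_2 = p_1 x_1 - k_2 x_2,\qquad
\dot x_3 = p_2 x_2 - k_3 x_3,
$$

where $x_1$ is mRNA, $x_2$ protein, $x_3$ phosphorylated protein, and
$f$ the repressive transcription function — either the saturating Hill form
$f(x_3) = r/(1+(x_3/K)^n)$ or the power-law form $f(x_3) = r/x_3^n$ used for
all analytic work.  Light forcing adds $I\cos(\Omega t)$ to the mRNA
equation.

## The NS index and the period formula

Write the limit cycle of $x_3$ as a Fourier series with coefficients $a_j$.
The **non-sinusoidal power**

$$
NS = \sqrt{\frac{\sum_{j\ge 1} |a_j|^2 j^m}{\sum_{j\ge 1} |a_j|^2 j^q}},
\qquad m > q \ge 0,
$$

equals 1 for a pure sinusoid and grows as higher harmonics gain power.
With $m=4$, $q=2$ it is exactly the waveform factor in the period of the
linear-degradation Goodwin model,

$$
\tau = \frac{2\pi}{\sqrt{s_2}}\, NS(4,2), \qquad
s_2 = k_1k_2+k_2k_3+k_3k_1 .
$$

This identity is the backbone of the package: faster degradation rates
(larger $s_2$) can only leave $\tau$ unchanged if $NS$ rises — temperature
compensation *requires* waveform distortion.  `period_formula()` evaluates
the identity from a harmonic decomposition, and a property-style test
verifies it against peak-measured simulation periods to well under 0.5%.

Harmonic content is estimated by **generalized harmonic analysis** (GHA,
`gha_decompose()`): a greedy least-squares extraction that at each round
finds the frequency, cosine and sine amplitude minimizing the squared
residual, subtracts the component, and repeats.  After the fundamental is
found, rounds $j \ge 2$ are restricted to ±2% neighborhoods of $j f_1$,
since the statistics index components as harmonics.  Two refinement passes
(each component re-fit with the others held out) remove the
cross-component bias of the greedy pass on finite windows; with a third
pass the phase of the second harmonic of a noiseless two-harmonic signal is
recovered to better than $10^{-6}$ rad.  Analysis windows are trimmed to an
integer number of periods wherever the period is known, because leakage
power is amplified by the $j^4$ weights.

Coefficient convention: the package stores one-sided sine-convention
amplitudes $r_j$ with $|a_j| = r_j/2$.  $NS$ and $\tau$ are ratios and do
not depend on this choice; the entrainment statistic $R$ below does, so the
convention is fixed package-wide and the synthetic generators use the same
$2|a_j|$ scaling.

## The randomized temperature sweep

`run_sweep()` reproduces the randomized compensation experiment: 100
oscillating reference parameter sets (all six rates uniform on $(0,10]$,
cooperativity an integer uniform on 9–15, power-law $f$), each "heated" by
multiplying every rate by an independent uniform factor in $(1.1,1.9)$
until 49 oscillation-persisting perturbations are collected — 4900 records.
A record is *compensated* when the relative period $\tau_2/\tau_1$ lies in
$[0.85, 1.15]$, the experimental wild-type range for a 10 °C step.

Since the average factor is 1.5, the mean relative period is close to
$1/1.5 \approx 0.67$; compensation is rare (tens of records out of 4900),
and compensated records show relative $NS > 1$ (more distortion) and larger
amplitude — the waveform and amplitude signatures of temperature
compensation arising purely from the period identity above.

Design choices a user should know:

* **4900 = 100 × 49.**  The experiment fixes 49 persisting perturbations
  per reference, redrawing non-oscillating ones, which keeps the design
  balanced; a reference whose perturbations keep failing is skipped with a
  warning.
* **Integration.**  Fixed-step classical RK4 is the reference integrator
  throughout (compiled; step 0.001 for the Goodwin model in its native time
  units, 0.0001 for the auxiliary Lotka–Volterra and van der Pol systems).
  The sweep scales the step to the linearized period,
  $\Delta t = 2\pi/(\sqrt{s_2}\cdot 2500)$, because random rates change the
  period by more than an order of magnitude; a unit test checks the
  time-rescaling symmetry $\tau(\lambda k) = \tau(k)/\lambda$ to 0.1%,
  which exercises exactly this scaling.
* **Oscillation detection.**  A set counts as oscillating when, after
  discarding half the window, at least three successive interpolated peaks
  of $x_3$ agree to $10^{-3}$ of the late-window swing.  Near the Hopf
  point relaxation onto the cycle is slow, so the integration is continued
  from its end state (up to five 44-period windows) before a set is
  declared non-oscillating.  Sets extremely close to threshold may still be
  excluded; any finite-horizon criterion shares this property.
* **Determinism.**  A master seed drives reference sampling, and each
  reference's perturbation stream is re-seeded from a recorded per-reference
  substream, so individual records can be regenerated in isolation.

The degenerate-factor control is the strongest end-to-end oracle: forcing
all six factors equal to $c$ makes the perturbed system an exact
time-rescaled copy, so the relative period must be $1/c$ and the relative
NS exactly 1; the test suite checks the full pipeline against this identity.

## The renormalization-group solution

Near the Hopf point of the power-law model the limit cycle admits a
closed-form second-order approximation obtained by resumming the secular
terms of perturbation theory (the envelope construction; see
`damped_oscillator_rg()` for the classic damped-linear-oscillator
demonstration, where the method turns the secular series into
$A_0 e^{-\epsilon t}\cos((1-\epsilon^2/2)t+\phi_0)$ with frequency error
$-\epsilon^4/8$):

$$
x_3(t) = \Big(\tfrac{p_1p_2r}{s_3}\Big)^{s_3/(s_1s_2)}
 + \varepsilon A_0 \sin(\omega t)
 + \varepsilon^2 A_1 A_0^2 \sin(2\omega t + \alpha) + o(\varepsilon^2),
$$

with $\varepsilon = n - s_4/s_3$ the distance above the Hopf point
($s_1=\sum k_i$, $s_3=\prod k_i$, $s_4=(k_1+k_2)(k_2+k_3)(k_3+k_1)$;
note $s_4/s_3 \ge 8$ with equality iff the $k_i$ are equal, so cooperativity
above 8 is needed at best), and

$$
\omega = \sqrt{s_2} - \varepsilon\,
 \frac{s_1 s_3 s_4}{6\,(2s_1s_2^2 - (s_1^2+6s_2)s_3)\sqrt{s_2}},
\qquad
\alpha = \arctan\!\frac{s_1}{2\sqrt{s_2}} .
$$

`rg_solution()` also evaluates the amplitude factors $A_0$ (with its
$1/\sqrt{\varepsilon}$ Hopf scaling) and the scale-invariant $A_1$.
Because these closed forms were transcribed from typeset mathematics, the
package validates them against two independent oracle families rather than
trusting the transcription:

* **Homogeneity identities.**  Under $k \to \lambda k$ (all six rates),
  $\omega$ is exactly degree 1, and $\alpha$, $\varepsilon$, $NS$, $A_1$
  degree 0.  These are exact identities of the implemented expressions and
  are tested numerically over $\lambda$ sweeps.
* **Simulation.**  RK4 + GHA measurements of $\omega$, the fundamental
  amplitude $\varepsilon A_0$, the second-harmonic amplitude
  $\varepsilon^2A_1A_0^2$, and the second-harmonic phase $\alpha$ agree
  with the closed forms to ~0.1% at $\varepsilon \le 0.3$ across
  asymmetric rate sets, with errors vanishing as $\varepsilon \to 0$.

Two empirical facts about the expansion's accuracy shape the tests: the
mean level of the simulated cycle drifts from the constant term at first
order in $\varepsilon$ (the printed constant is the fixed point *at* the
bifurcation), so waveform-quality comparisons are made between
mean-centered shapes; and the measured second-harmonic phase approaches
$\alpha$ linearly in $\varepsilon$, so the exact round trip is asserted on
the RG waveform itself, while simulations check the limit.

### Sensitivities: why compensation forces a phase drop

`a1_elasticities()` differentiates $\ln A_1$ with respect to the six rates:
the elasticities always sum to zero (scale invariance) and are negative for
$p_1$, $p_2$, $r$.  `differentials()` evaluates exact symbolic gradients of
$\omega$ (which depends on $n$ through $\varepsilon$) and $\alpha$ under a
degradation-rate change $dk$, and
`classify_dalpha_on_domega_surface()` samples the level set $d\omega = 0$ —
the rate combinations at which a prescribed increase
$dk = (0.3, 0.2, 0.1)$ leaves the frequency unchanged — and records the
sign of $d\alpha$ there.  For $n = 12,13,14$ every surface point has
$d\alpha < 0$: holding the period against faster rates forces the
second-harmonic phase down, i.e. a steeper rise and longer tail.

Two numerical notes.  First, the level set is computed from the closed
forms over the whole rate grid; restricted to the oscillatory region
($\varepsilon > 0$) it is empty at these $n$, so the classification is a
statement about the formal sensitivity surfaces, mirroring how the
surfaces are usually displayed.  Second, because $\nabla\omega$ is
homogeneous of degree 0 and $\nabla\alpha$ of degree $-1$, the sign
pattern is invariant along rays $k \to \lambda k$, so the classification
does not depend on the chosen grid range.  The test suite tracks the
maximum of $d\alpha$ on the sampled surface: it is strictly negative at
every cooperativity tested and rises toward zero as $n$ grows — the
surfaces approach tangency at high (biologically unrealistic) $n$, but we
find no $d\alpha > 0$ pocket even at $n = 20$.

## Entrainment and the synchronization bound

For the light-forced model, multiplying the collapsed third-order equation
by $\dot x_3$ and integrating over one forcing cycle gives the exact
balance

$$
\Omega^3 - \omega^2\Omega = \tfrac12 p_1 p_2 I R \sin\beta,
\qquad
R = \frac{|a_1|}{\sum_j |a_j|^2 j^4},
$$

where $\omega^2 = s_2 \sum|a_j|^2j^2 / \sum|a_j|^2j^4$ and the $a_j$ are
the Fourier coefficients *of the entrained solution* ($\beta$ the phase of
$a_1$).  Since $|\sin\beta| \le 1$, an entrained $\Omega$ must satisfy
$|\Omega^3 - \omega^2\Omega| \le \tfrac12 p_1p_2IR$.  $R$ shrinks as
harmonic power grows, so a more distorted waveform — e.g. the
temperature-compensated clock at the higher temperature — entrains over a
narrower frequency range.

The package implements both routes:

* `sync_balance_check()` verifies the balance on simulated entrained
  solutions (it holds to a fraction of a percent) and the inequality at
  every entrained grid frequency — this is the necessity test.
* `sync_bound()` evaluates the admissible interval *a priori* from the
  free-running limit cycle's coefficients.  This substitution is exact only
  in the limit of vanishing forcing-induced waveform change; at finite
  intensity the entrained amplitude adapts with detuning (it grows toward
  the low-frequency edge), and the numerical tongue can overhang the
  free-running interval by a factor of order two.  The free-running
  interval still tracks the tongue's scale, its linear growth with $I$,
  and its shrinkage with distortion, which is what the
  temperature-compensation argument uses.
* `arnold_tongue()` scans a frequency grid (default step $10^{-4}$) for
  1:1 locking, defined as relative peak-amplitude stationarity below
  $10^{-6}$ over 10 forcing cycles plus a period match within $10^{-4}$
  (a reproducible stand-in for "amplitude change smaller than rounding
  error"), walking outward from the natural frequency and warm-starting
  each integration from its neighbor's final state; locking transients
  shrink from hundreds of cold cycles (over a thousand at $I = 0.001$) to
  ~150 warm ones.

## The reanalysis pipeline and its synthetic ground truth

`run_pipeline()` mirrors the analysis chain used for published
luciferase-reporter curves digitized at 1 h intervals: add uniform noise
(±0.4 on the curve's scale; ±0.05 for max-normalized data) in 100
replicates; cubic-spline resample to 0.1 h; detrend by multiplying
$e^{\hat\lambda t}$ with $\hat\lambda$ from a log-linear fit through one
anchor extremum per cycle (minima by default, maxima where the rising
flank carries the trend); window one period from the first anchor; GHA up
to the third harmonic; $NS(4,2)$ per replicate; Welch's *t*-test between
conditions.

The synthetic generators (`synth_waveform()`, `synth_condition_pair()`,
`synth_goodwin_fixture()`) produce damped, noisy, hourly curves with known
harmonic content, so the whole chain can be tested against exact ground
truth: a two-harmonic spec with $|a_2|/|a_1|$ chosen by
`amplitudes_for_ns()` has a closed-form true NS.  What the fixtures
emulate: 24 h period, exponential envelope, hourly sampling, uniform
noise.  What they do not emulate: real reporter curves have
non-stationary period and waveform, colored noise, and shared systematic
digitization error — so a clean pass on synthetic pairs demonstrates that
the *pipeline* recovers known distortion differences at matched noise
levels, not that any particular published difference is correct.  Two
further caveats are deliberate: the published *t* statistics depend on the
specific digitized curves and noise draws and are not reproduction
targets; and treating the 100 noise replicates as independent samples is
pseudo-replication inherited from the protocol — the package's null
calibration therefore feeds *clean* average curves (the measurement noise
enters only through the replicate stage), under which the test's type-I
rate is nominal.

Condition pairs use independent per-condition noise substreams derived
from the master seed; passing equal substream seeds with identical inputs
reproduces identical replicates (and $t = 0$ exactly), which the tests use
as a determinism oracle.

## Numerical choices and limitations

* RK4 step sizes: 0.001 (Goodwin reference), $\tau_{\rm lin}/2500$
  (sweep), $\tau_{\rm lin}/2000$–$/3000$ (validation runs), 0.0001
  (Lotka–Volterra, van der Pol); order-4 convergence and agreement with an
  independent integrator are unit-tested.
* Problem sizes: the sweep runs its native 100 × 49 design (minutes of
  CPU); RG validation ladders use ~10³ periods per rung; the entrainment
  battery checks ten random oscillating sets at three intensities with
  dense grids near the interval edges plus interior probes.
* GHA defaults: fundamental grid $[0.5/T, \max(4j_{\max},64)/T]$ at
  resolution $1/(20T)$ with golden-section refinement, harmonic locking at
  ±2%, two refinement passes.
* Degenerate inputs are first-class: constant series yield a flagged
  all-zero decomposition rather than an error; NS and $R$ error when the
  fundamental vanishes; below-bifurcation parameter sets error in
  `rg_solution()`; diverging integrations report the first failing time.
* Limitations: linear degradation only (the Michaelis–Menten Goodwin
  variant, stochastic dynamics, and higher-order RG corrections are out of
  scope); the free-running synchronization interval is an approximation as
  described above; oscillation detection over finite horizons can miss
  sets arbitrarily close to the Hopf threshold.

## A worked example

```{r example, eval = FALSE}
library(waveclock)

p <- goodwin_power_law(1, 2, 3, 1, 1, r = 1, n = 12)
m <- sweep_measure(p)
m$tau                                   # measured period
m$ns                                    # NS(4, 2) of x3
s <- structural_sums(p$k1, p$k2, p$k3)
2 * pi / sqrt(s[["s2"]]) * m$ns         # period formula: same number

sol <- rg_solution(p)
c(sol$omega, 2 * pi / m$tau)            # analytic vs simulated frequency

sb <- sync_bound(p, I = 0.03)
sb$interval                             # admissible forcing frequencies
```
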