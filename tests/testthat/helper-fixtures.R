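# canonical oscillating parameter sets used across tests

gp_sym <- function(n = 10) {
  goodwin_power_law(1, 1, 1, 1, 1, r = 1, n = n)
}

gp_asym <- function(n = 12) {
  goodwin_power_law(1, 2, 3, 1, 1, r = 1, n = n)
}

# random oscillating power-law set (rejection sampled, deterministic under
# the caller's RNG state)
random_oscillating_params <- function(rate_max = 10, n_range = c(9L, 15L)) {
  repeat {
    rates <- stats::runif(6, 0.05, rate_max)
    n <- sample(seq(n_range[1], n_range[2]), 1L)
    s <- structural_sums(rates[1], rates[2], rates[3])
    if (n <= s[["s4"]] / s[["s3"]]) next
    p <- goodwin_power_law(rates[1], rates[2], rates[3], rates[4], rates[5],
                           r = rates[6], n = n)
    m <- sweep_measure(p)
    if (m$oscillating) {
      attr(p, "measure") <- m
      return(p)
    }
  }
}

# sine-wave trajectory object (period in the same units as dt)
sine_trajectory <- function(period = 24, amplitude = 1, n_periods = 10,
                            dt = period / 400, phase = 0) {
  t <- seq(0, n_periods * period, by = dt)
  trajectory(matrix(amplitude * sin(2 * pi * t / period + phase), ncol = 1,
                    dimnames = list(NULL, "x")),
             dt = dt, system = "sine")
}
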