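# Independent statistical oracles for the generator tests.

# Kolmogorov-Smirnov distance between sampled z values and the Boltzmann
# law exp(-F/kBT) on a periodic box of length L, via a dense numeric CDF.
ks_distance_boltzmann <- function(z, Ffun, L, temperature) {
  kT <- 0.008314462618 * temperature
  grid <- seq(-L / 2, L / 2, length.out = 8192L)
  w <- exp(-(Ffun(grid) - min(Ffun(grid))) / kT)
  cdf <- cumsum((w[-1] + w[-length(w)]) / 2 * diff(grid))
  cdf <- c(0, cdf / cdf[length(cdf)])
  z <- sort(z)
  theo <- approx(grid, cdf, xout = z, rule = 2)$y
  emp_hi <- seq_along(z) / length(z)
  emp_lo <- (seq_along(z) - 1) / length(z)
  max(pmax(abs(emp_hi - theo), abs(emp_lo - theo)))
}
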