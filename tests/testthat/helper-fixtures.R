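# Shared fixtures built in code.

# A spectrum series whose diagnostic optical densities are constructed by
# inverting the four-wavelength coefficient matrix, so the target species
# signals (and hence OxyHb%) are recovered exactly by the quartet pathway.
# Each spectrum is defined on the minimal grid {560, 576, 630, 700} nm.
make_quartet_series <- function(oxy_pct, od700 = 0.05, met_share = 0.1) {
  spectra <- lapply(seq_along(oxy_pct), function(i) {
    f <- oxy_pct[i] / 100
    s <- c(met = met_share * (1 - f), deoxy = (1 - met_share) * (1 - f),
           oxy = f)
    d <- solve(hb_quartet_coefficients, s)
    spectrum(c(560, 576, 630, 700), c(d + od700, od700),
             sample_id = "quartet_synth", time_h = i - 1)
  })
  spectrum_series(spectra, "cycle")
}

random_quartet <- function() {
  od_quartet(runif(1, 0, 1), runif(1, 0, 1), runif(1, 0, 1), runif(1, 0, 1))
}

# dyadic rationals (multiples of 2^-20, magnitude < 2) are exactly
# representable, and so are their pairwise sums and differences
dyadic <- function(n) sample.int(2^21, n, replace = TRUE) / 2^20 - 1
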