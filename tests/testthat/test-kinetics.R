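test_that("quartet-mode deoxygenation curve inverts its forward model exactly", {
  target <- seq(92, 4, length.out = 50)
  series <- make_quartet_series(target)
  curve <- oda_timecourse(series, mode = "quartet")
  expect_equal(curve$oxy_fraction_pct, target, tolerance = 1e-9)
  expect_equal(curve$start_pct, target[10], tolerance = 1e-9)
  expect_equal(curve$end_pct, target[50], tolerance = 1e-9)
})

test_that("unmix-mode deoxygenation curve recovers the generating oxy fractions", {
  basis <- make_basis()
  f_oxy <- seq(0.92, 0.04, length.out = 12)
  fr <- cbind(f_oxy, (1 - f_oxy) * 0.95, (1 - f_oxy) * 0.05)
  gen <- make_mixture_series(basis, fr, cadence_label = "cycle")
  curve <- oda_timecourse(gen$series, mode = "unmix", basis = basis,
                          window = c(350, 700))
  expect_equal(curve$oxy_fraction_pct, 100 * f_oxy, tolerance = 1e-6)
})

test_that("a constant pure-oxy series gives a flat curve with start = end", {
  series <- make_quartet_series(rep(97, 5))
  curve <- oda_timecourse(series, mode = "quartet")
  expect_equal(curve$start_pct, curve$end_pct, tolerance = 1e-12)
  one <- oda_timecourse(make_quartet_series(80), mode = "quartet")
  expect_length(one$cycle_index, 1)
  expect_identical(one$start_pct, one$end_pct)
})

test_that("deoxygenation fractions are invariant to per-cycle baseline offsets", {
  target <- seq(90, 10, length.out = 8)
  series <- make_quartet_series(target)
  shifted <- series
  set.seed(3)
  offs <- round(runif(8, -0.1, 0.3) * 2^20) / 2^20
  shifted$spectra <- lapply(seq_along(shifted$spectra), function(i) {
    sp <- shifted$spectra[[i]]
    sp$absorbance <- sp$absorbance + offs[i]
    sp
  })
  c1 <- oda_timecourse(series, mode = "quartet")
  c2 <- oda_timecourse(shifted, mode = "quartet")
  expect_equal(c1$oxy_fraction_pct, c2$oxy_fraction_pct, tolerance = 1e-12)
})

test_that("blank-like cycles are excluded with a warning; all-blank errors", {
  series <- make_quartet_series(c(90, 50, 10))
  blank <- spectrum(c(560, 576, 630, 700), rep(0.2, 4), time_h = 3)
  series$spectra <- c(series$spectra, list(blank))
  expect_warning(curve <- oda_timecourse(series, mode = "quartet"),
                 "1 cycle")
  expect_true(is.na(curve$oxy_fraction_pct[4]))
  expect_equal(curve$end_pct, 10, tolerance = 1e-9)
  all_blank <- spectrum_series(list(blank, blank), "cycle")
  expect_error(suppressWarnings(oda_timecourse(all_blank, mode = "quartet")),
               "all cycles")
})

test_that("autoxidation time course recovers a linear metHb trajectory", {
  basis <- make_basis()
  met <- seq(2, 18, by = 2) / 100
  fr <- cbind(0.9 * (1 - met), 0.1 * (1 - met), met)
  gen <- make_mixture_series(basis, fr, times = 0:8, cadence_label = "hour")
  course <- autoxidation_timecourse(gen$series, basis, window = c(350, 700))
  expect_equal(course$time_h, as.numeric(0:8))
  expect_equal(course$met_fraction_pct, 100 * met, tolerance = 1e-4)
})

test_that("first-order autoxidation rate is recovered on exact model data", {
  basis <- make_basis()
  k <- 0.05; m0 <- 1
  tt <- 0:8
  met <- (100 - (100 - m0) * exp(-k * tt)) / 100
  fr <- cbind(0.9 * (1 - met), 0.1 * (1 - met), met)
  gen <- make_mixture_series(basis, fr, times = tt, cadence_label = "hour")
  course <- autoxidation_timecourse(gen$series, basis, fit_rate = TRUE,
                                    window = c(350, 700))
  expect_equal(course$k_obs_per_h, k, tolerance = 1e-4 / k)

  # constant composition: rate indistinguishable from zero
  frc <- matrix(rep(c(0.85, 0.10, 0.05), 9), ncol = 3, byrow = TRUE)
  genc <- make_mixture_series(basis, frc, times = tt, cadence_label = "hour")
  flat <- autoxidation_timecourse(genc$series, basis, fit_rate = TRUE,
                                  window = c(350, 700))
  expect_lt(abs(flat$k_obs_per_h), 1e-8)
})

test_that("rate recovery tolerates saturation noise within 10% over seeds", {
  basis <- make_basis()
  k <- 0.05; m0 <- 1
  tt <- 0:8
  met_true <- 100 - (100 - m0) * exp(-k * tt)
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    met <- pmin(pmax(met_true + rnorm(9, sd = 0.3), 0), 100) / 100
    fr <- cbind(0.9 * (1 - met), 0.1 * (1 - met), met)
    gen <- make_mixture_series(basis, fr, times = tt, cadence_label = "hour")
    course <- autoxidation_timecourse(gen$series, basis, fit_rate = TRUE,
                                      window = c(350, 700))
    abs(course$k_obs_per_h / k - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("clearance reproduces the assay formula and its edge cases", {
  expect_equal(as.numeric(clearance(0.8, 0.2, 0.5)), 50)
  expect_equal(as.numeric(clearance(0.8, 0.2, 0.8)), 100)  # sample == blank
  expect_equal(as.numeric(clearance(0.8, 0.2, 0.2)), 0)    # sample == control
  expect_error(clearance(0.5, 0.5, 0.3), "undefined")
  over <- clearance(0.8, 0.2, 0.9)
  expect_true(attr(over, "out_of_range"))
})

test_that("clearance is invariant under a common positive rescaling", {
  set.seed(21)
  for (i in 1:50) {
    a0 <- runif(1, 0.5, 1); ac <- runif(1, 0, 0.4); at <- runif(1, 0, 1)
    cc <- runif(1, 0.1, 10)
    expect_equal(as.numeric(clearance(cc * a0, cc * ac, cc * at)),
                 as.numeric(clearance(a0, ac, at)), tolerance = 1e-10)
  }
})
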