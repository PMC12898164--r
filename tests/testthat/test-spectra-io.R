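test_that("wide and long CSV dialects round-trip spectra to 1e-12", {
  set.seed(42)
  wl <- seq(350, 700, by = 1)
  series <- spectrum_series(
    lapply(0:2, function(t) spectrum(wl, runif(length(wl)), "s1", time_h = t)),
    "hour"
  )
  for (dialect in c("long", "wide")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_spectra(series, f, dialect)
    back <- read_spectra(f, dialect, cadence_label = "hour")
    expect_length(back, 3)
    for (i in 1:3) {
      expect_equal(back$spectra[[i]]$wavelength_nm, wl)
      expect_equal(back$spectra[[i]]$absorbance, series$spectra[[i]]$absorbance,
                   tolerance = 1e-12)
      expect_equal(back$spectra[[i]]$time_h, i - 1)
    }
  }
})

test_that("wide CSV with a wavelength column and 2 samples gives 2 full-length spectra", {
  f <- withr::local_tempfile(fileext = ".csv")
  wl <- 350:700
  df <- data.frame(wavelength = wl, a = runif(351), b = runif(351))
  write.csv(df, f, row.names = FALSE)
  s <- read_spectra(f, "wide")
  expect_length(s, 2)
  expect_length(s$spectra[[1]]$wavelength_nm, 351)
})

test_that("long CSV yields one spectrum per (sample, time) with hour cadence", {
  f <- withr::local_tempfile(fileext = ".csv")
  grid <- expand.grid(wavelength = seq(500, 700, 10), time = 0:8)
  df <- data.frame(sample_id = "hba", time = grid$time,
                   wavelength = grid$wavelength, absorbance = runif(nrow(grid)))
  write.csv(df, f, row.names = FALSE)
  s <- read_spectra(f, "long", cadence_label = "hour")
  expect_length(s, 9)
  expect_equal(vapply(s$spectra, `[[`, numeric(1), "time_h"), as.numeric(0:8))
})

test_that("malformed CSVs raise errors naming the offending column or value", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(sample_id = "x", wavelength = 1:3, absorbance = runif(3)),
            f, row.names = FALSE)
  expect_error(read_spectra(f, "long"), "missing column.*time")
  write.csv(data.frame(sample_id = "x", time = 0, wavelength = c(500, 510, 520),
                       absorbance = c("0.1", "oops", "0.3")), f, row.names = FALSE)
  expect_error(read_spectra(f, "long"), "non-numeric.*absorbance.*row 2")
  write.csv(data.frame(sample_id = "x", time = 0, wavelength = c(500, 500, 520),
                       absorbance = runif(3)), f, row.names = FALSE)
  expect_error(read_spectra(f, "long"), "duplicated wavelength 500")
})

test_that("spectrum constructor enforces its invariants", {
  expect_error(spectrum(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(spectrum(500, 0.1), "at least 2")
  expect_error(spectrum(c(500, 500), c(1, 2)), "strictly increasing")
  expect_error(spectrum(c(500, 600), c(1, 2), path_length_cm = 0), "path_length")
})

test_that("extract_quartet is exact on grids containing the four wavelengths", {
  set.seed(7)
  wl <- 350:700
  ab <- runif(length(wl))
  q <- extract_quartet(spectrum(wl, ab))
  expect_identical(q$od560, ab[wl == 560])
  expect_identical(q$od576, ab[wl == 576])
  expect_identical(q$od630, ab[wl == 630])
  expect_identical(q$od700, ab[wl == 700])
})

test_that("extract_quartet interpolates linearly between neighbours", {
  # 2-nm grid lacks 576 nm: value is the midpoint of the 575/577 neighbours
  wl <- seq(351, 701, by = 2)
  ab <- numeric(length(wl))
  ab[wl == 575] <- 0.4
  ab[wl == 577] <- 0.6
  q <- extract_quartet(spectrum(wl, ab))
  expect_equal(q$od576, 0.5)
  # agreement with approx() on random irregular grids
  set.seed(11)
  for (i in 1:20) {
    wl <- sort(c(550, 710, runif(60, 550, 710)))
    ab <- rexp(length(wl))
    q <- extract_quartet(spectrum(wl, ab))
    oracle <- approx(wl, ab, xout = c(560, 576, 630, 700))$y
    expect_equal(unlist(q, use.names = FALSE), oracle, tolerance = 1e-14)
  }
})

test_that("extract_quartet rejects spectra not spanning 560-700 nm", {
  expect_error(extract_quartet(spectrum(350:650, runif(301))),
               "700 nm outside spectrum range")
})
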