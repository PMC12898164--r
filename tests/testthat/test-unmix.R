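basis <- make_basis()

test_that("a pure 3 uM oxyhemoglobin spectrum is reconstructed exactly", {
  sp <- spectrum(basis$wavelength_nm, basis$eps_oxy * 3e-6 * 1)
  u <- unmix(sp, basis, window = c(350, 700))
  expect_equal(u$c_oxy, 3e-6, tolerance = 1e-9)
  expect_equal(u$c_deoxy, 0, tolerance = 1e-12)
  expect_equal(u$c_met, 0, tolerance = 1e-12)
  expect_lt(u$residual_rms, 1e-12)
})

test_that("noise-free five-parameter recovery is exact to 1e-6 relative", {
  gen <- make_mixture_series(basis, matrix(c(0.6, 0.3, 0.1), 1),
                             total_conc_m = 3e-6, k_offset = 0.01,
                             s_scatter = 5e8, noise_sd = 0)
  truth <- gen$truth$conc_m
  for (nn in c(TRUE, FALSE)) {
    u <- unmix(gen$series$spectra[[1]], basis, nonnegative = nn,
               window = c(350, 700))
    expect_equal(u$c_oxy, truth$c_oxy[1], tolerance = 1e-6)
    expect_equal(u$c_deoxy, truth$c_deoxy[1], tolerance = 1e-6)
    expect_equal(u$c_met, truth$c_met[1], tolerance = 1e-6)
    expect_equal(u$k_offset, 0.01, tolerance = 1e-6)
    expect_equal(u$s_scatter, 5e8, tolerance = 1e-6)
    expect_equal(u$met_fraction_pct, 10, tolerance = 1e-6)
  }
})

test_that("unconstrained fit equals a brute-force normal-equations oracle on toy grids", {
  set.seed(31)
  for (i in 1:20) {
    wl <- sort(runif(20, 400, 700))
    b <- basis_set(wl, rexp(20, 1e-4), rexp(20, 1e-4), rexp(20, 1e-4))
    sp <- spectrum(wl, rnorm(20, 0.3, 0.1))
    u <- unmix(sp, b, nonnegative = FALSE, window = c(350, 700))
    X <- cbind(b$eps_oxy, b$eps_deoxy, b$eps_met, 1, (500 / wl)^4)
    beta <- solve(t(X) %*% X, t(X) %*% sp$absorbance)
    expect_equal(c(u$c_oxy, u$c_deoxy, u$c_met, u$k_offset,
                   u$s_scatter / 500^4),
                 drop(beta), tolerance = 1e-9)
  }
})

test_that("constrained residual never beats the unconstrained residual", {
  set.seed(17)
  for (i in 1:10) {
    sp <- spectrum(basis$wavelength_nm,
                   rnorm(length(basis$wavelength_nm), 0.2, 0.05))
    rc <- unmix(sp, basis, nonnegative = TRUE)$residual_rms
    ru <- unmix(sp, basis, nonnegative = FALSE)$residual_rms
    expect_gte(rc, ru - 1e-12)
  }
})

test_that("concentrations are invariant to a constant absorbance shift (K free)", {
  gen <- make_mixture_series(basis, matrix(c(0.5, 0.25, 0.25), 1), 3e-6)
  sp <- gen$series$spectra[[1]]
  u0 <- unmix(sp, basis, window = c(350, 700))
  sp$absorbance <- sp$absorbance + 0.37
  u1 <- unmix(sp, basis, window = c(350, 700))
  expect_equal(u1$c_oxy, u0$c_oxy, tolerance = 1e-8)
  expect_equal(u1$c_deoxy, u0$c_deoxy, tolerance = 1e-8)
  expect_equal(u1$c_met, u0$c_met, tolerance = 1e-8)
  expect_equal(u1$k_offset, u0$k_offset + 0.37, tolerance = 1e-8)
})

test_that("degenerate bases and insufficient overlap are rejected", {
  wl <- basis$wavelength_nm
  twin <- basis_set(wl, basis$eps_oxy, basis$eps_oxy, basis$eps_met)
  sp <- spectrum(wl, runif(length(wl)))
  expect_error(unmix(sp, twin), "rank deficient")
  zero <- basis_set(wl, basis$eps_oxy, basis$eps_deoxy, numeric(length(wl)))
  expect_error(unmix(sp, zero), "rank deficient")
  short <- spectrum(c(500, 501), c(0.1, 0.2))
  expect_error(unmix(short, basis), "fewer than 10 points")
})

test_that("metHb fraction follows the concentration ratio and errors on empty totals", {
  u <- structure(list(c_oxy = 9e-7, c_deoxy = 0, c_met = 1e-7),
                 class = "hb_unmix")
  expect_equal(met_fraction(u), 10)
  u$c_oxy <- 0; u$c_met <- 5e-6
  expect_equal(met_fraction(u), 100)
  u$c_met <- 0
  expect_error(met_fraction(u), "undefined")
})

test_that("basis CSV round-trips through read_basis/write_basis", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_basis(basis, f)
  back <- read_basis(f)
  expect_equal(back$eps_oxy, basis$eps_oxy, tolerance = 1e-12)
  expect_equal(back$eps_met, basis$eps_met, tolerance = 1e-12)
})
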