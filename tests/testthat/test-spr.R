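test_that("simulated sensorgrams follow the closed-form 1:1 solution", {
  # zero analyte: identically zero before noise
  sg0 <- simulate_sensorgram(1e5, 0.01, 100, conc = 0)
  expect_true(all(sg0$response_ru == 0))
  # at C = KD the equilibrium response is half of Rmax
  ka <- 1e5; kd <- 0.01; rmax <- 100; conc <- 1e-7  # KD = kd/ka = 1e-7 M
  half <- log(2) / kd  # dissociation half-life, ~69.31 s
  sg <- simulate_sensorgram(ka, kd, rmax, conc,
                            times = c(0, 2000, 4000, 4000 + half, 5000),
                            t_assoc_end_s = 4000, t_total_s = 5000)
  expect_equal(sg$response_ru[sg$time_s == 4000], rmax / 2, tolerance = 1e-6)
  expect_equal(sg$response_ru[4], sg$response_ru[3] / 2, tolerance = 1e-9)
})

test_that("noise-free association is nondecreasing, dissociation nonincreasing, Req bounded", {
  sg <- simulate_sensorgram(1e4, 9.03e-3, 100, 2.5e-6)
  assoc <- sg$response_ru[sg$time_s <= 240]
  dissoc <- sg$response_ru[sg$time_s >= 240]
  expect_true(all(diff(assoc) >= 0))
  expect_true(all(diff(dissoc) <= 0))
  # Req increases with concentration and never exceeds Rmax
  req <- vapply(c(0.1, 0.5, 1, 5, 50) * 1e-6, function(cc) {
    s <- simulate_sensorgram(1e4, 9.03e-3, 100, cc,
                             times = seq(0, 1e5, 1000), t_assoc_end_s = 9e4,
                             t_total_s = 1e5)
    max(s$response_ru)
  }, numeric(1))
  expect_true(all(diff(req) > 0))
  expect_true(all(req <= 100))
})

test_that("global fit round-trips the generating parameters on the dilution series", {
  gen <- make_sensorgrams(ka = 1e4, kd = 9.03e-3, rmax = 100, noise_sd = 0)
  fit <- fit_1to1(gen$sensorgrams)
  expect_equal(fit$ka_per_m_s, 1e4, tolerance = 1e-6)
  expect_equal(fit$kd_per_s, 9.03e-3, tolerance = 1e-6)
  expect_equal(fit$rmax_ru, 100, tolerance = 1e-6)
  expect_equal(fit$kd_eq_m, 9.03e-7, tolerance = 1e-6)
  # definitional identity KD = kd / ka
  expect_equal(fit$kd_eq_m * fit$ka_per_m_s, fit$kd_per_s, tolerance = 1e-12)
})

test_that("the zero-concentration curve acts as reference subtraction", {
  gen <- make_sensorgrams(ka = 1e4, kd = 9.03e-3, rmax = 100, noise_sd = 0)
  # add a common bulk artifact to every curve, recorded by the blank
  art <- 3 * sin(gen$sensorgrams[[1]]$time_s / 100)
  shifted <- lapply(gen$sensorgrams, function(sg) {
    sg$response_ru <- sg$response_ru + art
    sg
  })
  fit <- fit_1to1(shifted)
  expect_equal(fit$ka_per_m_s, 1e4, tolerance = 1e-6)
  expect_equal(fit$kd_per_s, 9.03e-3, tolerance = 1e-6)
})

test_that("rates are recovered within 5% under 1 RU noise across seeds", {
  hits <- vapply(1:100, function(s) {
    gen <- make_sensorgrams(1e4, 9.03e-3, 100, noise_sd = 1, seed = 7000 + 10 * s)
    fit <- fit_1to1(gen$sensorgrams)
    abs(fit$ka_per_m_s / 1e4 - 1) <= 0.05 &&
      abs(fit$kd_per_s / 9.03e-3 - 1) <= 0.05
  }, logical(1))
  expect_gte(sum(hits), 90)
})

test_that("a single concentration with a shared fit warns about identifiability", {
  sg <- simulate_sensorgram(1e4, 9.03e-3, 100, 2.5e-6)
  expect_warning(fit_1to1(list(sg)), "confounded")
})

test_that("sensorgram CSV round-trips and validation rejects bad schedules", {
  gen <- make_sensorgrams(noise_sd = 0)
  f <- withr::local_tempfile(fileext = ".csv")
  write_sensorgrams(gen$sensorgrams, f)
  back <- read_sensorgrams(f)
  expect_length(back, 5)
  concs <- sort(unname(vapply(back, `[[`, numeric(1), "conc_m")))
  expect_equal(concs, sort(c(5, 2.5, 1.25, 0.625, 0) * 1e-6), tolerance = 1e-12)
  expect_error(sensorgram(0:10, 0:10, 1e-6, t_assoc_end_s = 800,
                          t_total_s = 720), "t_assoc_end")
  expect_error(simulate_sensorgram(-1, 0.01, 100, 1e-6), "> 0")
})
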