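# Synthetic data with recorded ground truth ---------------------------------
#
# Every generator is deterministic under a fixed seed and returns (or writes)
# a machine-readable truth record; recovery tests elsewhere read truth only
# from these records. Per-object seeds are derived from the master seed by a
# simple counter (seed + object index), so any subset regenerates identically.

.gaussian_bands <- function(wl, bands) {
  rowSums(sapply(bands, function(b) {
    b$amp * exp(-0.5 * ((wl - b$center) / b$width)^2)
  }))
}

#' Default spectral band parameters of the synthetic basis
#'
#' Per-heme pseudo-extinction bands (center nm, Gaussian width nm, amplitude
#' M^-1 cm^-1) placed at the named features of the three hemoglobin species:
#' the oxyHb Soret band near 414 nm and Q bands at 541/577 nm, the deoxyHb
#' Soret near 430 nm with its single broad Q band at 555 nm, and metHb with
#' a blue-shifted Soret near 405 nm, a 500-nm band and the diagnostic 630-nm
#' charge-transfer band.
#'
#' @return A named list of per-species band lists.
#' @export
default_bands <- function() {
  list(
    oxy = list(list(center = 414, width = 9, amp = 1.25e5),
               list(center = 541, width = 11, amp = 1.40e4),
               list(center = 577, width = 8, amp = 1.55e4)),
    deoxy = list(list(center = 430, width = 11, amp = 1.33e5),
                 list(center = 555, width = 16, amp = 1.25e4)),
    met = list(list(center = 405, width = 10, amp = 1.50e5),
               list(center = 500, width = 14, amp = 9.0e3),
               list(center = 630, width = 13, amp = 3.9e3))
  )
}

#' Generate a synthetic basis set
#'
#' Builds pseudo-extinction curves as sums of Gaussian bands (see
#' [default_bands()]). The curves are full rank by construction, so the
#' linear deconvolution problem is well posed; they are not literature
#' extinction tables, and recovery tests against them demonstrate only that
#' the fitting machinery inverts its own forward model.
#'
#' @param wavelength_nm Wavelength grid (nm), within 350-700.
#' @param bands Per-species band list (defaults to [default_bands()]).
#' @param path_length_cm Path length (cm).
#' @return An `hb_basis`.
#' @export
make_basis <- function(wavelength_nm = seq(350, 700, by = 1),
                       bands = default_bands(), path_length_cm = 1) {
  if (min(wavelength_nm) < 350 || max(wavelength_nm) > 700) {
    stop("wavelength grid must lie within 350-700 nm", call. = FALSE)
  }
  key <- vapply(bands, function(bs) {
    paste(vapply(bs, function(b) sprintf("%g|%g|%g", b$center, b$width, b$amp),
                 character(1)), collapse = ";")
  }, character(1))
  if (anyDuplicated(key)) {
    stop("degenerate basis: two species share an identical band set", call. = FALSE)
  }
  basis_set(wavelength_nm,
            eps_oxy = .gaussian_bands(wavelength_nm, bands$oxy),
            eps_deoxy = .gaussian_bands(wavelength_nm, bands$deoxy),
            eps_met = .gaussian_bands(wavelength_nm, bands$met),
            path_length_cm = path_length_cm)
}

#' Generate a synthetic spectrum series from known species fractions
#'
#' Forward Beer-Lambert model: for each timepoint the absorbance is
#' `(eps %*% (fractions * total)) * L + K + S/lambda^4` plus additive
#' Gaussian noise. Ground-truth concentrations, offset and scattering are
#' returned in `truth`.
#'
#' @param basis An `hb_basis`.
#' @param fractions Matrix with one row per timepoint and columns
#'   `(oxy, deoxy, met)`; each row must sum to 1 and be non-negative.
#' @param total_conc_m Total heme concentration (M); default 3e-6, a typical
#'   3 uM working concentration.
#' @param times Time stamps (hours for cadence `"hour"`, cycle index for
#'   `"cycle"`); defaults to `0:(nrow(fractions)-1)`.
#' @param cadence_label `"cycle"` or `"hour"`.
#' @param noise_sd Additive absorbance noise (AU).
#' @param k_offset Baseline offset K (AU).
#' @param s_scatter Scattering magnitude S (AU nm^4).
#' @param seed Master seed; spectrum `i` uses `seed + i - 1`.
#' @param sample_id Sample label.
#' @return A list with `series` (an `hb_series`) and `truth` (list of
#'   generating parameters, including per-timepoint concentrations).
#' @export
make_mixture_series <- function(basis, fractions, total_conc_m = 3e-6,
                                times = NULL,
                                cadence_label = c("cycle", "hour"),
                                noise_sd = 0, k_offset = 0, s_scatter = 0,
                                seed = 1, sample_id = "synthetic") {
  cadence_label <- match.arg(cadence_label)
  stopifnot(inherits(basis, "hb_basis"))
  fractions <- as.matrix(fractions)
  if (ncol(fractions) != 3) stop("fractions needs 3 columns (oxy, deoxy, met)",
                                 call. = FALSE)
  if (any(fractions < 0)) stop("fractions must be non-negative", call. = FALSE)
  if (any(abs(rowSums(fractions) - 1) > 1e-9)) {
    stop("each fraction row must sum to 1", call. = FALSE)
  }
  n <- nrow(fractions)
  if (is.null(times)) times <- seq_len(n) - 1
  wl <- basis$wavelength_nm
  E <- cbind(basis$eps_oxy, basis$eps_deoxy, basis$eps_met)
  L <- basis$path_length_cm
  conc <- fractions * total_conc_m
  spectra <- lapply(seq_len(n), function(i) {
    a <- drop(E %*% conc[i, ]) * L + k_offset + s_scatter / wl^4
    if (noise_sd > 0) {
      set.seed(seed + i - 1)
      a <- a + stats::rnorm(length(a), sd = noise_sd)
    }
    spectrum(wl, a, sample_id = sample_id, time_h = times[i],
             path_length_cm = L)
  })
  list(
    series = spectrum_series(spectra, cadence_label),
    truth = list(generator = "make_mixture_series", seed = seed,
                 total_conc_m = total_conc_m, k_offset = k_offset,
                 s_scatter = s_scatter, noise_sd = noise_sd,
                 times = times,
                 fractions = stats::setNames(as.data.frame(fractions),
                                             c("oxy", "deoxy", "met")),
                 conc_m = stats::setNames(as.data.frame(conc),
                                          c("c_oxy", "c_deoxy", "c_met")))
  )
}

#' Generate a synthetic oxygen dissociation curve
#'
#' Hill-shaped saturation `SO2 = 100 p^n / (P50^n + p^n)` plus Gaussian
#' noise, clipped to \[0, 100\] with clip events counted in the truth record.
#' The default pressure grid is logarithmically spaced over 1-150 mmHg,
#' mimicking the dense low-pressure sampling of ODC analyzers.
#'
#' @param p50 True P50 (mmHg).
#' @param n True Hill coefficient.
#' @param pressures Pressure grid (mmHg); default 20 log-spaced points,
#'   1-150 mmHg.
#' @param noise_sd Saturation noise (percentage points).
#' @param seed Integer seed for the noise.
#' @param ph pH recorded on the measurement.
#' @return A list with `odc` (an `hb_odc`) and `truth`.
#' @export
make_odc <- function(p50 = 14.24, n = 2.6,
                     pressures = exp(seq(log(1), log(150), length.out = 20)),
                     noise_sd = 0, seed = 1, ph = 7.4) {
  if (!(p50 > 0 && n > 0)) stop("p50 and n must be > 0", call. = FALSE)
  if (!length(pressures)) stop("empty pressure grid", call. = FALSE)
  so2 <- 100 * pressures^n / (p50^n + pressures^n)
  clipped <- 0L
  if (noise_sd > 0) {
    set.seed(seed)
    so2 <- so2 + stats::rnorm(length(so2), sd = noise_sd)
    clipped <- sum(so2 < 0 | so2 > 100)
    so2 <- pmin(pmax(so2, 0), 100)
  }
  list(odc = odc_measurement(pressures, so2, ph = ph),
       truth = list(generator = "make_odc", seed = seed, p50 = p50, n = n,
                    ph = ph, noise_sd = noise_sd, n_clipped = clipped))
}

#' Generate a synthetic sensorgram concentration series
#'
#' One [simulate_sensorgram()] per concentration of the analyte dilution
#' series (default 5, 2.5, 1.25, 0.625 and 0 uM), with per-curve seeds
#' `seed + curve index`.
#'
#' @param ka,kd,rmax True 1:1 parameters.
#' @param concs Analyte concentrations (M).
#' @param times Sampling times (s).
#' @param t_assoc_end_s,t_total_s Phase schedule (240 s / 720 s).
#' @param noise_sd Response noise (RU).
#' @param seed Master seed.
#' @return A list with `sensorgrams` (list of `hb_sensorgram`) and `truth`.
#' @export
make_sensorgrams <- function(ka = 1e4, kd = 9.03e-3, rmax = 100,
                             concs = c(5, 2.5, 1.25, 0.625, 0) * 1e-6,
                             times = seq(0, 720, by = 1),
                             t_assoc_end_s = 240, t_total_s = 720,
                             noise_sd = 0, seed = 1) {
  sg <- lapply(seq_along(concs), function(i) {
    simulate_sensorgram(ka, kd, rmax, concs[i], times = times,
                        t_assoc_end_s = t_assoc_end_s, t_total_s = t_total_s,
                        noise_sd = noise_sd,
                        seed = if (noise_sd > 0) seed + i else NULL)
  })
  list(sensorgrams = sg,
       truth = list(generator = "make_sensorgrams", seed = seed, ka = ka,
                    kd = kd, rmax = rmax, kd_eq = kd / ka, concs_m = concs,
                    noise_sd = noise_sd))
}

#' Write a generator truth record to JSON
#'
#' @param truth A `truth` list from any generator.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
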