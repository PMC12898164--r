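# Time-course analyses ------------------------------------------------------

#' Oxygen-dissociation-assay time course
#'
#' Computes the oxygenated-hemoglobin percentage per 5-min cycle of a
#' deoxygenation assay, either from the four diagnostic wavelengths
#' (`mode = "quartet"`, via [quantify_quartet()] and [oxy_fraction()]) or by
#' full-spectrum deconvolution (`mode = "unmix"`, via [unmix()]).
#'
#' `start_pct` is read at the end of the oxygenation phase (default cycle 10,
#' i.e. 50 min of oxygenation) and `end_pct` at the last recorded cycle.
#' Cycles whose fraction is undefined (blank-like signal) are flagged `NA`
#' with a warning and excluded from start/end.
#'
#' @param series An `hb_series` with cadence `"cycle"`.
#' @param mode `"quartet"` or `"unmix"`.
#' @param basis An `hb_basis`, required when `mode = "unmix"`.
#' @param oxygenation_cycles Cycle index at which oxygenation ends.
#' @param ... Further arguments passed to [unmix()].
#' @return An object of class `hb_oda_curve`: list with `cycle_index`,
#'   `oxy_fraction_pct`, `start_pct`, `end_pct`.
#' @export
oda_timecourse <- function(series, mode = c("quartet", "unmix"), basis = NULL,
                           oxygenation_cycles = 10, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "hb_series"))
  if (series$cadence_label != "cycle") {
    stop("oda_timecourse expects a series with cadence 'cycle'", call. = FALSE)
  }
  if (mode == "unmix" && !inherits(basis, "hb_basis")) {
    stop("mode = 'unmix' requires a basis set", call. = FALSE)
  }
  frac <- vapply(series$spectra, function(sp) {
    tryCatch({
      if (mode == "quartet") {
        oxy_fraction(quantify_quartet(extract_quartet(sp)))
      } else {
        u <- unmix(sp, basis, ...)
        total <- u$c_oxy + u$c_deoxy + u$c_met
        if (total <= 0) stop("zero total concentration")
        100 * u$c_oxy / total
      }
    }, error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(frac))) {
    stop("all cycles have undefined oxygenated fraction", call. = FALSE)
  }
  if (anyNA(frac)) {
    warning(sprintf("%d cycle(s) with undefined fraction excluded", sum(is.na(frac))))
  }
  idx <- seq_along(frac)
  ok <- which(!is.na(frac))
  start_at <- min(oxygenation_cycles, max(ok))
  if (is.na(frac[start_at])) start_at <- ok[which.min(abs(ok - start_at))]
  structure(list(cycle_index = idx, oxy_fraction_pct = frac,
                 start_pct = frac[start_at], end_pct = frac[max(ok)]),
            class = "hb_oda_curve")
}

#' @export
print.hb_oda_curve <- function(x, ...) {
  cat(sprintf("<hb_oda_curve> %d cycles, OxyHb%% %.2f -> %.2f\n",
              length(x$cycle_index), x$start_pct, x$end_pct))
  invisible(x)
}

#' Autoxidation time course (metHb formation)
#'
#' Deconvolves each hourly spectrum and reports the methemoglobin percentage
#' over time. Optionally fits the pseudo-first-order relaxation
#' `metHb(t) = 100 - (100 - m0) exp(-k t)` to estimate an observed
#' autoxidation rate; the rate fit is an extension beyond the per-hour
#' percentages themselves and is off by default.
#'
#' @param series An `hb_series` with cadence `"hour"` and time stamps set.
#' @param basis An `hb_basis`.
#' @param fit_rate Fit the first-order rate (requires >= 3 timepoints).
#' @param ... Passed to [unmix()].
#' @return An object of class `hb_autox_course`: list with `time_h`,
#'   `met_fraction_pct`, and `k_obs_per_h` (`NA` unless `fit_rate`).
#' @export
autoxidation_timecourse <- function(series, basis, fit_rate = FALSE, ...) {
  stopifnot(inherits(series, "hb_series"), inherits(basis, "hb_basis"))
  if (series$cadence_label != "hour") {
    stop("autoxidation_timecourse expects a series with cadence 'hour'",
         call. = FALSE)
  }
  tt <- vapply(series$spectra, `[[`, numeric(1), "time_h")
  met <- vapply(series$spectra, function(sp) met_fraction(unmix(sp, basis, ...)),
                numeric(1))
  k_obs <- NA_real_
  if (fit_rate) {
    if (length(tt) < 3) {
      stop("rate fit needs at least 3 timepoints", call. = FALSE)
    }
    m0_start <- met[1]
    # crude log-linear start for k from the fraction still unoxidized
    u <- (100 - met) / (100 - m0_start)
    pos <- u > 0 & tt > 0
    k_start <- if (any(pos)) max(1e-6, -stats::coef(stats::lm(log(u[pos]) ~ 0 + tt[pos]))[[1]])
               else 0.01
    fit <- minpack.lm::nls.lm(
      par = c(m0 = m0_start, k = k_start),
      fn = function(p) met - (100 - (100 - p[1]) * exp(-p[2] * tt)),
      lower = c(0, -1), upper = c(100, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)
    )
    k_obs <- unname(fit$par["k"])
  }
  structure(list(time_h = tt, met_fraction_pct = met, k_obs_per_h = k_obs),
            class = "hb_autox_course")
}

#' @export
print.hb_autox_course <- function(x, ...) {
  cat(sprintf("<hb_autox_course> %d timepoints, metHb %.2f%% -> %.2f%%",
              length(x$time_h), x$met_fraction_pct[1],
              x$met_fraction_pct[length(x$met_fraction_pct)]))
  if (!is.na(x$k_obs_per_h)) cat(sprintf(", k_obs %.4g /h", x$k_obs_per_h))
  cat("\n")
  invisible(x)
}

#' Hydroxyl-radical scavenging clearance
#'
#' The o-phenanthroline--ferrous assay statistic
#' `Clearance% = 100 * (At - Ac) / (A0 - Ac)`, where `A0`, `Ac` and `At` are
#' the 536-nm absorbances of the blank, control and sample tubes. The formula
#' is applied exactly as defined; values outside \[0, 100\] are returned with
#' an `out_of_range` attribute set rather than clamped.
#'
#' @param a0 Blank-tube absorbance (AU).
#' @param ac Control-tube absorbance (AU).
#' @param at Sample-tube absorbance (AU).
#' @param floor Smallest admissible `|a0 - ac|` (default `1e-9`).
#' @return Clearance in percent, with attribute `out_of_range`.
#' @examples
#' clearance(0.8, 0.2, 0.5)  # 50%
#' @export
clearance <- function(a0, ac, at, floor = 1e-9) {
  v <- c(a0, ac, at)
  if (length(v) != 3 || !all(is.finite(v))) {
    stop("a0, ac, at must be finite scalars", call. = FALSE)
  }
  if (abs(a0 - ac) < floor) {
    stop("clearance undefined: blank and control absorbances coincide",
         call. = FALSE)
  }
  pct <- 100 * (at - ac) / (a0 - ac)
  attr(pct, "out_of_range") <- pct < 0 || pct > 100
  pct
}
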