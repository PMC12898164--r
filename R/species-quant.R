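# Four-wavelength species quantification -----------------------------------

#' Coefficient matrix of the four-wavelength species formulas
#'
#' Rows are hemoglobin species, columns the three background-corrected
#' optical-density differences `d560 = OD560 - OD700`, `d576 = OD576 - OD700`
#' and `d630 = OD630 - OD700`. Each species signal is the inner product of its
#' row with `(d560, d576, d630)`:
#' \deqn{MetHb = 2.985\,d_{630} + 0.194\,d_{576} - 0.4023\,d_{560}}
#' \deqn{Deoxy = 1.373\,d_{560} - 0.747\,d_{576} - 0.737\,d_{630}}
#' \deqn{OxyHb = 1.013\,d_{576} - 0.3269\,d_{630} - 0.7353\,d_{560}}
#' The coefficients are the published multi-wavelength calibration constants
#' for oxy-, deoxy- and methemoglobin; the common OD700 subtraction removes a
#' wavelength-independent baseline.
#'
#' @format A 3x3 numeric matrix, rows `met`, `deoxy`, `oxy`, columns
#'   `d560`, `d576`, `d630`.
#' @export
hb_quartet_coefficients <- matrix(
  c(-0.4023,  0.194,   2.985,
     1.373,  -0.747,  -0.737,
    -0.7353,  1.013,  -0.3269),
  nrow = 3, byrow = TRUE,
  dimnames = list(c("met", "deoxy", "oxy"), c("d560", "d576", "d630"))
)

#' Species signals from an OD quartet
#'
#' Applies the four-wavelength formulas ([hb_quartet_coefficients]) to the
#' diagnostic optical densities, producing unitless met-, deoxy- and
#' oxyhemoglobin signals. Negative signals (possible with noisy input) are
#' returned as computed and flagged, never clipped: clipping would silently
#' distort the oxygenated fraction, whose denominator uses the raw values.
#'
#' @param quartet An `hb_quartet` (see [extract_quartet()], [od_quartet()]).
#' @return An object of class `hb_species_signal`: list with `met_signal`,
#'   `deoxy_signal`, `oxy_signal` and logical `negative_flag`.
#' @examples
#' q <- od_quartet(0.5, 0.8, 0.1, 0)
#' quantify_quartet(q)
#' @export
quantify_quartet <- function(quartet) {
  stopifnot(inherits(quartet, "hb_quartet"))
  d <- c(quartet$od560 - quartet$od700,
         quartet$od576 - quartet$od700,
         quartet$od630 - quartet$od700)
  s <- drop(hb_quartet_coefficients %*% d)
  structure(
    list(met_signal = s[["met"]], deoxy_signal = s[["deoxy"]],
         oxy_signal = s[["oxy"]], negative_flag = any(s < 0)),
    class = "hb_species_signal"
  )
}

#' @export
print.hb_species_signal <- function(x, ...) {
  cat(sprintf("<hb_species_signal> met %.5g, deoxy %.5g, oxy %.5g%s\n",
              x$met_signal, x$deoxy_signal, x$oxy_signal,
              if (x$negative_flag) " [negative component]" else ""))
  invisible(x)
}

#' Oxygenated-hemoglobin percentage
#'
#' `OxyHb% = 100 * oxy / (met + deoxy + oxy)` on the raw (unclipped) species
#' signals. When the denominator magnitude falls below `floor` the ratio is
#' numerically meaningless (a blank well or a saturating artifact) and an
#' error is raised rather than returning a blown-up value.
#'
#' @param signal An `hb_species_signal` from [quantify_quartet()].
#' @param floor Smallest admissible denominator magnitude (default `1e-6`).
#' @return The oxygenated fraction in percent.
#' @export
oxy_fraction <- function(signal, floor = 1e-6) {
  stopifnot(inherits(signal, "hb_species_signal"))
  denom <- signal$met_signal + signal$deoxy_signal + signal$oxy_signal
  if (!is.finite(denom) || abs(denom) < floor) {
    stop(sprintf("oxygenated fraction undefined: species-signal sum %.3g below floor %g",
                 denom, floor), call. = FALSE)
  }
  100 * signal$oxy_signal / denom
}
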