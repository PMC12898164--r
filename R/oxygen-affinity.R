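# Oxygen dissociation curve analysis ----------------------------------------

#' Construct an oxygen-dissociation-curve measurement
#'
#' @param po2_mmhg Oxygen partial pressures (mmHg), >= 0, length >= 4.
#' @param so2_pct Oxygen saturations in percent. Values must lie in
#'   \[0, 100\]; small instrument excursions up to 102 are tolerated and
#'   flagged.
#' @param ph pH of the run (optional).
#' @return An object of class `hb_odc`.
#' @export
odc_measurement <- function(po2_mmhg, so2_pct, ph = NA_real_) {
  po2_mmhg <- as.numeric(po2_mmhg)
  so2_pct <- as.numeric(so2_pct)
  if (length(po2_mmhg) != length(so2_pct) || length(po2_mmhg) < 4) {
    stop("need equal-length po2 and so2 vectors with at least 4 points",
         call. = FALSE)
  }
  if (any(po2_mmhg < 0)) stop("po2 must be >= 0", call. = FALSE)
  if (any(so2_pct < 0) || any(so2_pct > 102)) {
    stop("so2 must lie in [0, 102] percent", call. = FALSE)
  }
  structure(list(po2_mmhg = po2_mmhg, so2_pct = so2_pct, ph = as.numeric(ph)[1],
                 over_100_flag = any(so2_pct > 100)),
            class = "hb_odc")
}

#' Model-free P50 by linear bracketing
#'
#' Scans the curve in order of increasing pO2 and linearly interpolates
#' between the first adjacent pair of points that brackets 50% saturation.
#' No functional form is assumed.
#'
#' @param odc An `hb_odc`.
#' @return P50 in mmHg.
#' @export
p50_model_free <- function(odc) {
  stopifnot(inherits(odc, "hb_odc"))
  ord <- order(odc$po2_mmhg)
  p <- odc$po2_mmhg[ord]
  s <- odc$so2_pct[ord]
  if (min(s) > 50 || max(s) < 50) {
    stop("saturations do not bracket 50%: P50 cannot be located", call. = FALSE)
  }
  hit <- which(s == 50)
  if (length(hit)) return(p[hit[1]])
  i <- which(diff(sign(s - 50)) != 0)[1]
  p[i] + (50 - s[i]) * (p[i + 1] - p[i]) / (s[i + 1] - s[i])
}

#' Fit a Hill saturation curve to an ODC
#'
#' Least-squares fit of the two-parameter Hill model
#' \deqn{SO_2(p) = 100\, p^n / (P_{50}^n + p^n)}
#' with the saturation asymptote fixed at 100% (instrument output is
#' normalized). Starting values come from the model-free P50 and the slope of
#' `logit(SO2)` against `log(p)`.
#'
#' @param odc An `hb_odc` with points on both sides of 50% saturation.
#' @return An object of class `hb_hill_fit`: list with `p50_mmhg`, `hill_n`,
#'   `rmse_pct` and the input `ph`.
#' @examples
#' d <- make_odc(p50 = 14.24, n = 2.6, noise_sd = 0, seed = 1)
#' fit_hill(d$odc)
#' @export
fit_hill <- function(odc) {
  stopifnot(inherits(odc, "hb_odc"))
  p50_0 <- p50_model_free(odc)  # also enforces bracketing
  p <- odc$po2_mmhg
  s <- odc$so2_pct
  use <- p > 0 & s > 0.5 & s < 99.5
  n_0 <- if (sum(use) >= 2) {
    sl <- stats::coef(stats::lm(log(s[use] / (100 - s[use])) ~ log(p[use])))[[2]]
    min(max(sl, 0.2), 6)
  } else 2
  fit <- tryCatch(
    minpack.lm::nlsLM(
      s ~ 100 * p^n / (p50^n + p^n),
      start = list(p50 = p50_0, n = n_0),
      lower = c(p50 = 1e-6, n = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) stop(sprintf("Hill fit failed to converge: %s",
                                     conditionMessage(e)), call. = FALSE)
  )
  cf <- stats::coef(fit)
  structure(list(p50_mmhg = cf[["p50"]], hill_n = cf[["n"]],
                 rmse_pct = sqrt(mean(stats::residuals(fit)^2)), ph = odc$ph),
            class = "hb_hill_fit")
}

#' @export
print.hb_hill_fit <- function(x, ...) {
  cat(sprintf("<hb_hill_fit> P50 %.3f mmHg, n %.3f, rmse %.3g%%",
              x$p50_mmhg, x$hill_n, x$rmse_pct))
  if (!is.na(x$ph)) cat(sprintf(" (pH %g)", x$ph))
  cat("\n")
  invisible(x)
}

#' Predict Hill-model saturation
#'
#' @param object An `hb_hill_fit`.
#' @param po2_mmhg Pressures at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Saturations in percent.
#' @export
predict.hb_hill_fit <- function(object, po2_mmhg, ...) {
  100 * po2_mmhg^object$hill_n /
    (object$p50_mmhg^object$hill_n + po2_mmhg^object$hill_n)
}

#' Bohr-effect analysis across pH
#'
#' Regresses `log10(P50)` on pH over a series of Hill fits and reports the
#' Bohr coefficient as the negative least-squares slope,
#' `-d log10(P50) / d pH`. A positive coefficient means oxygen affinity
#' rises (P50 falls) with increasing pH, the alkaline Bohr effect.
#'
#' @param fits A list of `hb_hill_fit` objects with distinct `ph` values
#'   (at least two).
#' @return An object of class `hb_bohr`: list with `p50_by_ph` (named numeric,
#'   names are pH values) and `bohr_coefficient`.
#' @export
bohr_analysis <- function(fits) {
  if (!length(fits) || !all(vapply(fits, inherits, logical(1), "hb_hill_fit"))) {
    stop("fits must be a list of hb_hill_fit objects", call. = FALSE)
  }
  ph <- vapply(fits, `[[`, numeric(1), "ph")
  p50 <- vapply(fits, `[[`, numeric(1), "p50_mmhg")
  if (anyNA(ph) || length(unique(ph)) < 2) {
    stop("Bohr analysis needs at least two fits with distinct pH", call. = FALSE)
  }
  slope <- stats::coef(stats::lm(log10(p50) ~ ph))[[2]]
  structure(list(p50_by_ph = stats::setNames(p50, ph),
                 bohr_coefficient = -slope),
            class = "hb_bohr")
}

#' @export
print.hb_bohr <- function(x, ...) {
  cat("<hb_bohr> P50 (mmHg) by pH:\n")
  print(round(x$p50_by_ph, 3))
  cat(sprintf("Bohr coefficient -dlog10(P50)/dpH = %.4f\n", x$bohr_coefficient))
  invisible(x)
}
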