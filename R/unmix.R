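# Full-spectrum least-squares deconvolution --------------------------------

#' Construct a basis set of molar absorptivity curves
#'
#' Holds the per-species extinction curves (M^-1 cm^-1) used by [unmix()]
#' together with the optical path length. All three curves share one grid and
#' must be non-negative.
#'
#' @param wavelength_nm Shared wavelength grid (nm), strictly increasing.
#' @param eps_oxy,eps_deoxy,eps_met Molar absorptivities (M^-1 cm^-1).
#' @param path_length_cm Optical path length L in cm (> 0, default 1).
#' @return An object of class `hb_basis`.
#' @export
basis_set <- function(wavelength_nm, eps_oxy, eps_deoxy, eps_met,
                      path_length_cm = 1) {
  n <- length(wavelength_nm)
  if (length(eps_oxy) != n || length(eps_deoxy) != n || length(eps_met) != n) {
    stop("all absorptivity curves must share the wavelength grid", call. = FALSE)
  }
  if (any(diff(wavelength_nm) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (min(eps_oxy, eps_deoxy, eps_met) < 0) {
    stop("molar absorptivities must be >= 0", call. = FALSE)
  }
  if (!is.finite(path_length_cm) || path_length_cm <= 0) {
    stop("path_length_cm must be > 0", call. = FALSE)
  }
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 eps_oxy = as.numeric(eps_oxy),
                 eps_deoxy = as.numeric(eps_deoxy),
                 eps_met = as.numeric(eps_met),
                 path_length_cm = path_length_cm),
            class = "hb_basis")
}

#' Read / write a basis-set CSV
#'
#' Columns: `wavelength_nm, eps_oxy, eps_deoxy, eps_met` (M^-1 cm^-1).
#'
#' @param path CSV path.
#' @param path_length_cm Path length attached on read (not stored in the CSV).
#' @return [read_basis()] an `hb_basis`; [write_basis()] `path` invisibly.
#' @export
read_basis <- function(path, path_length_cm = 1) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("wavelength_nm", "eps_oxy", "eps_deoxy", "eps_met")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("basis CSV is missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  basis_set(df$wavelength_nm, df$eps_oxy, df$eps_deoxy, df$eps_met,
            path_length_cm = path_length_cm)
}

#' @rdname read_basis
#' @param basis An `hb_basis`.
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "hb_basis"))
  df <- data.frame(wavelength_nm = basis$wavelength_nm, eps_oxy = basis$eps_oxy,
                   eps_deoxy = basis$eps_deoxy, eps_met = basis$eps_met)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# reference wavelength for the scattering column: (lambda_ref/lambda)^4 keeps
# the design matrix columns at comparable scale; S is converted back to
# AU nm^4 on output, so the fitted model is unchanged.
.SCATTER_REF_NM <- 500

#' Deconvolve a spectrum into hemoglobin species plus baseline and scattering
#'
#' Fits the five-parameter linear model
#' \deqn{D(\lambda) = (\epsilon_{oxy} C_{oxy} + \epsilon_{deoxy} C_{deoxy}
#'   + \epsilon_{met} C_{met}) L + K + S/\lambda^4}
#' by least squares over the fitted wavelength window. `K` is a
#' wavelength-independent instrumental offset; `S/lambda^4` is a
#' Rayleigh-type turbidity term. With `nonnegative = TRUE` (default) the
#' three concentrations and `S` are constrained to be non-negative — they are
#' physical quantities — while `K` stays free in sign.
#'
#' The basis is interpolated onto the spectrum grid (never the reverse), so
#' the measured absorbances enter the fit untouched.
#'
#' @param spectrum An `hb_spectrum`.
#' @param basis An `hb_basis`.
#' @param nonnegative Constrain concentrations and `S` to be >= 0.
#' @param window Length-2 numeric, wavelength window (nm) actually fitted.
#'   Default `c(450, 700)` avoids the easily saturated Soret region; pass the
#'   full recording range (e.g. `c(350, 700)`) to fit everything measured.
#' @return An object of class `hb_unmix`: list with concentrations `c_oxy`,
#'   `c_deoxy`, `c_met` (M), offset `k_offset` (AU), scattering magnitude
#'   `s_scatter` (AU nm^4), `residual_rms` (AU), `met_fraction_pct`, the
#'   number of fitted points `n_points`, and `nonnegative`.
#' @examples
#' b <- make_basis()
#' sp <- spectrum(b$wavelength_nm, b$eps_oxy * 3e-6)
#' unmix(sp, b, window = c(350, 700))
#' @export
unmix <- function(spectrum, basis, nonnegative = TRUE, window = c(450, 700)) {
  stopifnot(inherits(spectrum, "hb_spectrum"), inherits(basis, "hb_basis"))
  wl <- spectrum$wavelength_nm
  keep <- wl >= max(window[1], min(basis$wavelength_nm)) &
    wl <= min(window[2], max(basis$wavelength_nm))
  wl <- wl[keep]
  if (length(wl) < 10) {
    stop("spectrum and basis grids overlap on fewer than 10 points in the fit window",
         call. = FALSE)
  }
  y <- spectrum$absorbance[keep]
  L <- basis$path_length_cm
  interp <- function(e) stats::approx(basis$wavelength_nm, e, xout = wl)$y
  X <- cbind(oxy = interp(basis$eps_oxy) * L,
             deoxy = interp(basis$eps_deoxy) * L,
             met = interp(basis$eps_met) * L,
             offset = 1,
             scatter = (.SCATTER_REF_NM / wl)^4)
  if (qr(X)$rank < ncol(X)) {
    stop("degenerate basis: design matrix is rank deficient (identical or zero species curves?)",
         call. = FALSE)
  }
  if (nonnegative) {
    # K free in sign: split the offset column into +1/-1 parts so a single
    # non-negative solve covers the signed baseline.
    Xn <- cbind(X[, 1:3], pos = 1, neg = -1, X[, 5, drop = FALSE])
    fit <- pracma::lsqnonneg(Xn, y)
    beta <- c(fit$x[1:3], fit$x[4] - fit$x[5], fit$x[6])
  } else {
    beta <- qr.solve(X, y)
  }
  resid <- y - drop(X %*% beta)
  conc <- unname(beta[1:3])
  total <- sum(conc)
  structure(
    list(c_oxy = unname(conc[1]), c_deoxy = unname(conc[2]),
         c_met = unname(conc[3]), k_offset = unname(beta[4]),
         s_scatter = unname(beta[5]) * .SCATTER_REF_NM^4,
         residual_rms = sqrt(mean(resid^2)),
         met_fraction_pct = if (total > 0) 100 * conc[3] / total else NA_real_,
         negative_flag = any(conc < 0), n_points = length(y),
         nonnegative = nonnegative),
    class = "hb_unmix"
  )
}

#' @export
print.hb_unmix <- function(x, ...) {
  cat(sprintf(paste0("<hb_unmix> c_oxy %.4g M, c_deoxy %.4g M, c_met %.4g M\n",
                     "  K %.4g AU, S %.4g AU nm^4, rms %.3g AU (%d points%s)\n"),
              x$c_oxy, x$c_deoxy, x$c_met, x$k_offset, x$s_scatter,
              x$residual_rms, x$n_points,
              if (x$nonnegative) ", nonneg" else ""))
  if (!is.na(x$met_fraction_pct)) {
    cat(sprintf("  metHb fraction %.2f%%\n", x$met_fraction_pct))
  }
  invisible(x)
}

#' Methemoglobin fraction of an unmixing result
#'
#' `100 * c_met / (c_oxy + c_deoxy + c_met)`, the convention used when
#' reporting metHb content of a preparation.
#'
#' @param result An `hb_unmix` from [unmix()].
#' @return MetHb percentage of total hemoglobin.
#' @export
met_fraction <- function(result) {
  stopifnot(inherits(result, "hb_unmix"))
  total <- result$c_oxy + result$c_deoxy + result$c_met
  if (!is.finite(total) || total <= 0) {
    stop("metHb fraction undefined: total hemoglobin concentration is zero",
         call. = FALSE)
  }
  100 * result$c_met / total
}
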