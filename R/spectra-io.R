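# Spectrum containers and CSV I/O ------------------------------------------

#' Construct an absorbance spectrum
#'
#' A spectrum is a strictly increasing wavelength grid (nm) with one optical
#' density (AU) per wavelength, plus sample metadata. This is the raw input of
#' every spectral stage in the package.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param absorbance Numeric vector of optical densities (AU), same length.
#' @param sample_id Character label for the sample.
#' @param time_h Elapsed time in hours (optional, `NA` if not applicable).
#' @param ph pH of the sample (optional).
#' @param path_length_cm Optical path length in cm (> 0, default 1).
#' @return An object of class `hb_spectrum`.
#' @examples
#' sp <- spectrum(350:700, rexp(351, 10))
#' range(sp$wavelength_nm)
#' @export
spectrum <- function(wavelength_nm, absorbance, sample_id = "sample",
                     time_h = NA_real_, ph = NA_real_, path_length_cm = 1) {
  wavelength_nm <- as.numeric(wavelength_nm)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength_nm) != length(absorbance)) {
    stop("wavelength and absorbance must have equal length", call. = FALSE)
  }
  if (length(wavelength_nm) < 2) {
    stop("a spectrum needs at least 2 points", call. = FALSE)
  }
  if (anyNA(wavelength_nm) || anyNA(absorbance)) {
    stop("non-numeric or missing values in spectrum", call. = FALSE)
  }
  if (any(diff(wavelength_nm) <= 0)) {
    i <- which(diff(wavelength_nm) <= 0)[1]
    stop(sprintf("wavelengths must be strictly increasing (violation near row %d: %g nm)",
                 i + 1L, wavelength_nm[i + 1L]), call. = FALSE)
  }
  if (!is.finite(path_length_cm) || path_length_cm <= 0) {
    stop("path_length_cm must be > 0", call. = FALSE)
  }
  structure(
    list(wavelength_nm = wavelength_nm, absorbance = absorbance,
         sample_id = as.character(sample_id), time_h = as.numeric(time_h)[1],
         ph = as.numeric(ph)[1], path_length_cm = path_length_cm),
    class = "hb_spectrum"
  )
}

#' @export
print.hb_spectrum <- function(x, ...) {
  cat(sprintf("<hb_spectrum> %s: %d points, %g-%g nm", x$sample_id,
              length(x$wavelength_nm), min(x$wavelength_nm), max(x$wavelength_nm)))
  if (!is.na(x$time_h)) cat(sprintf(", t = %g h", x$time_h))
  if (!is.na(x$ph)) cat(sprintf(", pH %g", x$ph))
  cat("\n")
  invisible(x)
}

#' Construct an ordered series of spectra
#'
#' @param spectra A list of [spectrum()] objects with non-decreasing `time_h`.
#' @param cadence_label `"cycle"` for 5-min deoxygenation-assay cycles or
#'   `"hour"` for hourly autoxidation sampling.
#' @return An object of class `hb_series`.
#' @export
spectrum_series <- function(spectra, cadence_label = c("cycle", "hour")) {
  cadence_label <- match.arg(cadence_label)
  if (!length(spectra) || !all(vapply(spectra, inherits, logical(1), "hb_spectrum"))) {
    stop("spectra must be a non-empty list of hb_spectrum objects", call. = FALSE)
  }
  tt <- vapply(spectra, function(s) s$time_h, numeric(1))
  known <- tt[!is.na(tt)]
  if (length(known) > 1 && any(diff(known) < 0)) {
    stop("time stamps must be non-decreasing across the series", call. = FALSE)
  }
  structure(list(spectra = spectra, cadence_label = cadence_label),
            class = "hb_series")
}

#' @export
print.hb_series <- function(x, ...) {
  cat(sprintf("<hb_series> %d spectra, cadence '%s'\n",
              length(x$spectra), x$cadence_label))
  invisible(x)
}

#' @export
length.hb_series <- function(x) length(x$spectra)

#' Read spectra from CSV
#'
#' Two plain CSV dialects are supported. `long` has columns
#' `sample_id, time, wavelength, absorbance` (one row per measured point);
#' `wide` has a first column of wavelengths and one absorbance column per
#' sample/time, with times parsed from headers of the form `name_t<time>`.
#'
#' @param path Path to a CSV file.
#' @param dialect `"long"` or `"wide"`.
#' @param cadence_label Passed to [spectrum_series()].
#' @return An `hb_series`.
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, dialect = c("long", "wide"),
                         cadence_label = c("cycle", "hour")) {
  dialect <- match.arg(dialect)
  cadence_label <- match.arg(cadence_label)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (dialect == "long") {
    need <- c("sample_id", "time", "wavelength", "absorbance")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop(sprintf("long-dialect CSV is missing column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    for (col in c("time", "wavelength", "absorbance")) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
      if (length(bad)) {
        stop(sprintf("non-numeric value in column '%s', row %d", col, bad[1]),
             call. = FALSE)
      }
      df[[col]] <- v
    }
    key <- interaction(df$sample_id, df$time, drop = TRUE, lex.order = TRUE)
    groups <- split(df, key)
    ord <- order(vapply(groups, function(g) g$time[1], numeric(1)))
    spectra <- lapply(groups[ord], function(g) {
      g <- g[order(g$wavelength), , drop = FALSE]
      if (anyDuplicated(g$wavelength)) {
        stop(sprintf("duplicated wavelength %g nm for sample '%s'",
                     g$wavelength[which(duplicated(g$wavelength))[1]],
                     g$sample_id[1]), call. = FALSE)
      }
      spectrum(g$wavelength, g$absorbance, sample_id = g$sample_id[1],
               time_h = g$time[1])
    })
    names(spectra) <- NULL
    return(spectrum_series(spectra, cadence_label))
  }
  # wide dialect
  if (ncol(df) < 2) stop("wide-dialect CSV needs a wavelength column plus >= 1 sample column",
                         call. = FALSE)
  wl <- suppressWarnings(as.numeric(df[[1]]))
  if (anyNA(wl)) {
    stop(sprintf("non-numeric wavelength in column '%s', row %d",
                 names(df)[1], which(is.na(wl))[1]), call. = FALSE)
  }
  if (anyDuplicated(wl)) {
    stop(sprintf("duplicated wavelength %g nm in column '%s'",
                 wl[which(duplicated(wl))[1]], names(df)[1]), call. = FALSE)
  }
  ord <- order(wl)
  spectra <- lapply(names(df)[-1], function(nm) {
    ab <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(ab))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s', row %d", nm, bad[1]),
           call. = FALSE)
    }
    tm <- NA_real_
    m <- regmatches(nm, regexec("_t([0-9.]+)$", nm))[[1]]
    if (length(m) == 2) tm <- as.numeric(m[2])
    spectrum(wl[ord], ab[ord], sample_id = nm, time_h = tm)
  })
  spectrum_series(spectra, cadence_label)
}

#' Write spectra to CSV
#'
#' Inverse of [read_spectra()]; round-trips values to better than 1e-12.
#' The wide dialect requires all spectra to share one wavelength grid.
#'
#' @param series An `hb_series`.
#' @param path Output CSV path.
#' @param dialect `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(series, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(series, "hb_series"))
  if (dialect == "long") {
    rows <- do.call(rbind, lapply(series$spectra, function(s) {
      data.frame(sample_id = s$sample_id, time = s$time_h,
                 wavelength = s$wavelength_nm, absorbance = s$absorbance)
    }))
    utils::write.csv(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    grids <- lapply(series$spectra, `[[`, "wavelength_nm")
    if (!all(vapply(grids, identical, logical(1), grids[[1]]))) {
      stop("wide dialect requires a shared wavelength grid", call. = FALSE)
    }
    cols <- lapply(series$spectra, `[[`, "absorbance")
    nms <- vapply(series$spectra, function(s) {
      if (!is.na(s$time_h)) sprintf("%s_t%g", s$sample_id, s$time_h) else s$sample_id
    }, character(1))
    out <- data.frame(wavelength = grids[[1]], stats::setNames(cols, nms),
                      check.names = FALSE)
    utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# Diagnostic optical densities ----------------------------------------------

#' Extract the four diagnostic optical densities
#'
#' Returns the absorbances at 560, 576, 630 and 700 nm used by the
#' four-wavelength species formulas ([quantify_quartet()]). Values are taken
#' directly from the grid when the wavelength is present and linearly
#' interpolated between the two nearest neighbours otherwise.
#'
#' @param spectrum An `hb_spectrum` spanning at least 560-700 nm.
#' @return An object of class `hb_quartet`: a list with elements `od560`,
#'   `od576`, `od630`, `od700` (AU).
#' @export
extract_quartet <- function(spectrum) {
  stopifnot(inherits(spectrum, "hb_spectrum"))
  lambdas <- c(od560 = 560, od576 = 576, od630 = 630, od700 = 700)
  rng <- range(spectrum$wavelength_nm)
  out <- sapply(lambdas, function(l) {
    if (l < rng[1] || l > rng[2]) {
      stop(sprintf("wavelength %g nm outside spectrum range [%g, %g] nm",
                   l, rng[1], rng[2]), call. = FALSE)
    }
    hit <- which(spectrum$wavelength_nm == l)
    if (length(hit)) return(spectrum$absorbance[hit[1]])
    stats::approx(spectrum$wavelength_nm, spectrum$absorbance, xout = l)$y
  })
  structure(as.list(out), class = "hb_quartet")
}

#' Construct an OD quartet directly
#'
#' @param od560,od576,od630,od700 Optical densities (AU) at the four
#'   diagnostic wavelengths; all must be finite.
#' @return An `hb_quartet`.
#' @export
od_quartet <- function(od560, od576, od630, od700) {
  v <- c(od560, od576, od630, od700)
  if (length(v) != 4 || !all(is.finite(v))) {
    stop("all four optical densities must be finite numbers", call. = FALSE)
  }
  structure(list(od560 = od560, od576 = od576, od630 = od630, od700 = od700),
            class = "hb_quartet")
}
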