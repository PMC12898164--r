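# SPR sensorgram simulation and 1:1 global fitting --------------------------

#' Construct an SPR sensorgram
#'
#' @param time_s Time from injection (s), strictly increasing.
#' @param response_ru Response units.
#' @param conc_m Analyte concentration (M).
#' @param t_assoc_end_s End of the association phase (s, default 240).
#' @param t_total_s Total duration (s, default 720 = 240 s association +
#'   480 s dissociation).
#' @return An object of class `hb_sensorgram`.
#' @export
sensorgram <- function(time_s, response_ru, conc_m,
                       t_assoc_end_s = 240, t_total_s = 720) {
  time_s <- as.numeric(time_s)
  response_ru <- as.numeric(response_ru)
  if (length(time_s) != length(response_ru) || length(time_s) < 2) {
    stop("time and response must have equal length >= 2", call. = FALSE)
  }
  if (any(diff(time_s) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  if (!(t_assoc_end_s > 0 && t_assoc_end_s < t_total_s)) {
    stop("need 0 < t_assoc_end_s < t_total_s", call. = FALSE)
  }
  if (conc_m < 0) stop("conc_m must be >= 0", call. = FALSE)
  structure(list(time_s = time_s, response_ru = response_ru, conc_m = conc_m,
                 t_assoc_end_s = t_assoc_end_s, t_total_s = t_total_s),
            class = "hb_sensorgram")
}

# noise-free 1:1 Langmuir response at the given times
.langmuir_response <- function(ka, kd, rmax, conc, time_s, t_assoc_end_s) {
  if (conc == 0) return(numeric(length(time_s)))
  kobs <- ka * conc + kd
  req <- ka * conc * rmax / kobs
  r_end <- req * (1 - exp(-kobs * t_assoc_end_s))
  ifelse(time_s <= t_assoc_end_s,
         req * (1 - exp(-kobs * time_s)),
         r_end * exp(-kd * (time_s - t_assoc_end_s)))
}

#' Simulate a 1:1 Langmuir sensorgram
#'
#' Closed-form two-phase solution of the 1:1 interaction model. During
#' association, `R(t) = Req (1 - exp(-(ka C + kd) t))` with
#' `Req = ka C Rmax / (ka C + kd)`; after `t_assoc_end_s` the response decays
#' as `R(t_end) exp(-kd (t - t_end))`. Gaussian noise is added last.
#'
#' @param ka Association rate constant (M^-1 s^-1), > 0.
#' @param kd Dissociation rate constant (s^-1), > 0.
#' @param rmax Saturation response (RU), > 0.
#' @param conc Analyte concentration (M), >= 0.
#' @param times Sampling times (s).
#' @param t_assoc_end_s,t_total_s Phase schedule (defaults 240 s / 720 s).
#' @param noise_sd Gaussian noise standard deviation (RU).
#' @param seed Optional integer seed for the noise.
#' @return An `hb_sensorgram`.
#' @export
simulate_sensorgram <- function(ka, kd, rmax, conc, times = seq(0, 720, by = 1),
                                t_assoc_end_s = 240, t_total_s = 720,
                                noise_sd = 0, seed = NULL) {
  if (!(ka > 0 && kd > 0 && rmax > 0)) {
    stop("ka, kd and rmax must be > 0", call. = FALSE)
  }
  if (conc < 0) stop("conc must be >= 0", call. = FALSE)
  r <- .langmuir_response(ka, kd, rmax, conc, times, t_assoc_end_s)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    r <- r + stats::rnorm(length(r), sd = noise_sd)
  }
  sensorgram(times, r, conc, t_assoc_end_s, t_total_s)
}

#' Global 1:1 fit of a sensorgram concentration series
#'
#' Fits shared (global) `ka`, `kd` and `Rmax` across all non-zero
#' concentrations by Levenberg-Marquardt least squares on the closed-form
#' two-phase 1:1 model, and reports the equilibrium constant `KD = kd / ka`.
#' A zero-concentration curve, when present, is used only for reference
#' subtraction (its response, interpolated onto each curve's times, is
#' removed before fitting).
#'
#' Rates and `Rmax` are optimized on the log scale, which enforces
#' positivity and equalizes step sizes across parameters of very different
#' magnitude.
#'
#' @param sensorgrams List of `hb_sensorgram` objects sharing a schedule.
#' @param shared Fit one (ka, kd, rmax) across all curves (default). With
#'   `shared = FALSE` each curve is fitted separately and per-curve results
#'   are returned in `per_curve`.
#' @return An object of class `hb_binding_fit`: list with `ka_per_m_s`,
#'   `kd_per_s`, `rmax_ru`, `kd_eq_m`, `rmse_ru` and (if `shared = FALSE`)
#'   `per_curve`.
#' @examples
#' sg <- make_sensorgrams(ka = 1e4, kd = 9.03e-3, rmax = 100,
#'                        noise_sd = 0, seed = 1)
#' fit_1to1(sg$sensorgrams)
#' @export
fit_1to1 <- function(sensorgrams, shared = TRUE) {
  if (!length(sensorgrams) ||
      !all(vapply(sensorgrams, inherits, logical(1), "hb_sensorgram"))) {
    stop("sensorgrams must be a list of hb_sensorgram objects", call. = FALSE)
  }
  concs <- vapply(sensorgrams, `[[`, numeric(1), "conc_m")
  ref <- sensorgrams[concs == 0]
  curves <- sensorgrams[concs > 0]
  if (length(curves) < 1) stop("no non-zero concentration curves", call. = FALSE)
  if (length(curves) < 2 && shared) {
    warning("single concentration: ka and rmax are confounded in a shared fit")
  }
  if (length(ref)) {
    r0 <- ref[[1]]
    curves <- lapply(curves, function(sg) {
      bg <- stats::approx(r0$time_s, r0$response_ru, xout = sg$time_s,
                          rule = 2)$y
      sg$response_ru <- sg$response_ru - bg
      sg
    })
  }

  fit_set <- function(cs) {
    # starts: kd from log-linear dissociation tail of the strongest curve,
    # rmax from the peak response, ka from kobs at the highest concentration
    top <- cs[[which.max(vapply(cs, `[[`, numeric(1), "conc_m"))]]
    dis <- top$time_s > top$t_assoc_end_s & top$response_ru > 0
    kd0 <- if (sum(dis) >= 3) {
      t_d <- top$time_s[dis] - top$t_assoc_end_s
      max(1e-6, -stats::coef(stats::lm(log(top$response_ru[dis]) ~ t_d))[[2]])
    } else 0.01
    rmax0 <- max(1e-3, 1.5 * max(vapply(cs, function(s) max(s$response_ru),
                                        numeric(1))))
    ka0 <- max(1e-3, 1 / (top$conc_m * top$t_assoc_end_s))
    resid_fn <- function(par) {
      ka <- exp(par[1]); kd <- exp(par[2]); rmax <- exp(par[3])
      unlist(lapply(cs, function(sg) {
        sg$response_ru - .langmuir_response(ka, kd, rmax, sg$conc_m,
                                            sg$time_s, sg$t_assoc_end_s)
      }))
    }
    fit <- minpack.lm::nls.lm(
      par = log(c(ka0, kd0, rmax0)), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    )
    if (fit$info %in% c(0, 5)) {
      stop(sprintf("1:1 fit failed to converge: %s", fit$message), call. = FALSE)
    }
    est <- exp(fit$par)
    list(ka = est[1], kd = est[2], rmax = est[3],
         rmse = sqrt(mean(fit$fvec^2)))
  }

  if (shared) {
    f <- fit_set(curves)
    per_curve <- NULL
  } else {
    per_curve <- lapply(curves, function(sg) fit_set(list(sg)))
    f <- list(ka = stats::median(vapply(per_curve, `[[`, numeric(1), "ka")),
              kd = stats::median(vapply(per_curve, `[[`, numeric(1), "kd")),
              rmax = stats::median(vapply(per_curve, `[[`, numeric(1), "rmax")),
              rmse = sqrt(mean(vapply(per_curve, `[[`, numeric(1), "rmse")^2)))
  }
  structure(list(ka_per_m_s = f$ka, kd_per_s = f$kd, rmax_ru = f$rmax,
                 kd_eq_m = f$kd / f$ka, rmse_ru = f$rmse,
                 per_curve = per_curve),
            class = "hb_binding_fit")
}

#' @export
print.hb_binding_fit <- function(x, ...) {
  cat(sprintf("<hb_binding_fit> ka %.4g /M/s, kd %.4g /s, Rmax %.4g RU\n  KD = kd/ka = %.4g M (rmse %.3g RU)\n",
              x$ka_per_m_s, x$kd_per_s, x$rmax_ru, x$kd_eq_m, x$rmse_ru))
  invisible(x)
}

#' Read / write sensorgram CSV
#'
#' Columns: `time_s, response_ru, conc_m` (one file may hold several
#' concentrations).
#'
#' @param path CSV path.
#' @param t_assoc_end_s,t_total_s Schedule attached on read.
#' @return [read_sensorgrams()] a list of `hb_sensorgram`;
#'   [write_sensorgrams()] `path` invisibly.
#' @export
read_sensorgrams <- function(path, t_assoc_end_s = 240, t_total_s = 720) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("time_s", "response_ru", "conc_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("sensorgram CSV is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  lapply(split(df, df$conc_m), function(g) {
    g <- g[order(g$time_s), ]
    sensorgram(g$time_s, g$response_ru, g$conc_m[1], t_assoc_end_s, t_total_s)
  })
}

#' @rdname read_sensorgrams
#' @param sensorgrams List of `hb_sensorgram`.
#' @export
write_sensorgrams <- function(sensorgrams, path) {
  rows <- do.call(rbind, lapply(sensorgrams, function(sg) {
    data.frame(time_s = sg$time_s, response_ru = sg$response_ru,
               conc_m = sg$conc_m)
  }))
  utils::write.csv(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
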