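# MM/GBSA decomposition-table auditing --------------------------------------

#' Construct an MM/GBSA energy decomposition table
#'
#' Holds the four component means of a generalized-Born binding free-energy
#' decomposition (kcal/mol) plus, when available, the printed subtotals and
#' total and per-row standard deviations. Standard deviations are carried
#' through but never propagated: no independence assumption is made.
#'
#' @param dg_vdw Van der Waals component (kcal/mol).
#' @param dg_ele Electrostatic component (kcal/mol).
#' @param dg_polar Polar solvation component (kcal/mol).
#' @param dg_nonpolar Nonpolar solvation component (kcal/mol).
#' @param dg_gas,dg_solv,dg_total Printed subtotals/total (optional).
#' @param sds Optional named numeric of per-row standard deviations.
#' @return An object of class `hb_energy_table`.
#' @export
energy_table <- function(dg_vdw, dg_ele, dg_polar, dg_nonpolar,
                         dg_gas = NA_real_, dg_solv = NA_real_,
                         dg_total = NA_real_, sds = NULL) {
  comp <- c(dg_vdw = dg_vdw, dg_ele = dg_ele, dg_polar = dg_polar,
            dg_nonpolar = dg_nonpolar)
  if (anyNA(comp) || !all(is.finite(comp))) {
    stop("incomplete table: all four components (vdw, ele, polar, nonpolar) must be finite",
         call. = FALSE)
  }
  structure(list(dg_vdw = dg_vdw, dg_ele = dg_ele, dg_polar = dg_polar,
                 dg_nonpolar = dg_nonpolar, dg_gas = dg_gas, dg_solv = dg_solv,
                 dg_total = dg_total, sds = sds),
            class = "hb_energy_table")
}

#' Read an MM/GBSA table from CSV
#'
#' Expects columns `term, mean` and optionally `sd`. Term labels are matched
#' case-insensitively on their suffix (`vdw`, `ele`, `polar`, `nonpolar`,
#' `gas`, `solv`, `total`), so `dGvdw`, `DGvdw` and `vdw` all work.
#'
#' @param path CSV path.
#' @return An `hb_energy_table`.
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("term", "mean"), names(df))
  if (length(miss)) {
    stop(sprintf("energy CSV is missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  key <- tolower(df$term)
  pick <- function(what) {
    # nonpolar must be matched before polar
    i <- grep(paste0(what, "$"), key)
    if (what == "polar") i <- setdiff(i, grep("nonpolar$", key))
    if (length(i)) df$mean[i[1]] else NA_real_
  }
  sds <- NULL
  if ("sd" %in% names(df)) sds <- stats::setNames(df$sd, df$term)
  energy_table(dg_vdw = pick("vdw"), dg_ele = pick("ele"),
               dg_polar = pick("polar"), dg_nonpolar = pick("nonpolar"),
               dg_gas = pick("gas"), dg_solv = pick("solv"),
               dg_total = pick("total"), sds = sds)
}

#' Audit an MM/GBSA table for internal consistency
#'
#' Recomputes the additive identities of a GB decomposition:
#' `gas = vdw + ele`, `solv = polar + nonpolar`, `total = gas + solv`,
#' and flags any printed value that differs from its recomputation by more
#' than `tol`. The default tolerance, 0.0005 kcal/mol, is last-digit rounding
#' for a table printed to four decimals.
#'
#' @param table An `hb_energy_table`.
#' @param tol Consistency tolerance (kcal/mol).
#' @return An object of class `hb_energy_audit`: list with `recomputed`
#'   (named numeric: `dg_gas`, `dg_solv`, `dg_total`), `printed`, `delta`,
#'   `consistent` (named logical, `NA` where no printed value exists) and
#'   `all_consistent`.
#' @examples
#' tab <- energy_table(-25.5808, -103.3406, 106.1549, -3.2582,
#'                     dg_total = -26.0247)
#' audit_energy_table(tab)
#' @export
audit_energy_table <- function(table, tol = 0.0005) {
  stopifnot(inherits(table, "hb_energy_table"))
  gas <- table$dg_vdw + table$dg_ele
  solv <- table$dg_polar + table$dg_nonpolar
  total <- gas + solv
  recomputed <- c(dg_gas = gas, dg_solv = solv, dg_total = total)
  printed <- c(dg_gas = table$dg_gas, dg_solv = table$dg_solv,
               dg_total = table$dg_total)
  delta <- printed - recomputed
  consistent <- abs(delta) <= tol
  structure(list(recomputed = recomputed, printed = printed, delta = delta,
                 consistent = consistent, tol = tol,
                 all_consistent = all(consistent[!is.na(consistent)])),
            class = "hb_energy_audit")
}

#' @export
print.hb_energy_audit <- function(x, ...) {
  cat("<hb_energy_audit> (kcal/mol)\n")
  df <- data.frame(recomputed = x$recomputed, printed = x$printed,
                   delta = x$delta, consistent = x$consistent)
  print(df)
  cat(sprintf("all printed values consistent at tol %g: %s\n",
              x$tol, x$all_consistent))
  invisible(x)
}
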