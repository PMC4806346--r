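#' Current-voltage sweep
#'
#' Container for one two-point I-V sweep (conductive-probe AFM or STM
#' tunneling spectroscopy) together with probe metadata.
#'
#' @param voltage numeric vector, volts; must be strictly monotone.
#' @param current numeric vector, amperes; same length as `voltage`.
#' @param distance_nm probe distance from the electrode edge, nm (CP-AFM).
#' @param label free-text sample label.
#' @param temperature_K measurement temperature, K.
#' @param meta additional metadata entries (named list), e.g. ground-truth
#'   parameters recorded by the synthetic generators.
#'
#' @return An object of class `iv_curve`: a list with elements `voltage`,
#'   `current` and `meta`.
#' @export
iv_curve <- function(voltage, current, distance_nm = NA_real_, label = NULL,
                     temperature_K = NA_real_, meta = list()) {
  voltage <- as.numeric(voltage)
  current <- as.numeric(current)
  if (length(voltage) != length(current))
    stop("voltage and current must have the same length")
  if (length(voltage) < 5L)
    stop("an I-V sweep needs at least 5 points")
  if (!all(is.finite(voltage)) || !all(is.finite(current)))
    stop("voltage and current must be finite")
  dv <- diff(voltage)
  if (!(all(dv > 0) || all(dv < 0)))
    stop("voltage must be strictly monotone within a sweep")
  meta <- utils::modifyList(
    list(distance_nm = distance_nm, label = label,
         temperature_K = temperature_K),
    meta)
  structure(list(voltage = voltage, current = current, meta = meta),
            class = "iv_curve")
}

#' @export
print.iv_curve <- function(x, ...) {
  cat(sprintf("I-V sweep: %d points, V in [%.3g, %.3g] V\n",
              length(x$voltage), min(x$voltage), max(x$voltage)))
  if (is.finite(x$meta$distance_nm))
    cat(sprintf("  probe distance: %g nm\n", x$meta$distance_nm))
  if (!is.null(x$meta$label)) cat(sprintf("  label: %s\n", x$meta$label))
  if (is.finite(x$meta$temperature_K))
    cat(sprintf("  temperature: %g K\n", x$meta$temperature_K))
  invisible(x)
}

#' Read / write I-V sweeps as CSV
#'
#' Files use the two-column schema `voltage_V,current_A` with a header row.
#'
#' @param path file path.
#' @param ... metadata passed on to [iv_curve()] (`distance_nm`, `label`,
#'   `temperature_K`).
#' @return `read_iv_csv` returns an [iv_curve()]; `write_iv_csv` returns
#'   `path` invisibly.
#' @export
read_iv_csv <- function(path, ...) {
  d <- utils::read.csv(path, check.names = FALSE)
  need <- c("voltage_V", "current_A")
  if (!all(need %in% names(d)))
    stop("I-V CSV must have columns voltage_V,current_A")
  iv_curve(d$voltage_V, d$current_A, ...)
}

#' @param curve an [iv_curve()].
#' @rdname read_iv_csv
#' @export
write_iv_csv <- function(curve, path) {
  stopifnot(inherits(curve, "iv_curve"))
  utils::write.csv(
    data.frame(voltage_V = curve$voltage, current_A = curve$current),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
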