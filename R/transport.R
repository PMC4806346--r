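## CP-AFM transport analysis: ohmic fits, resistance-vs-distance laws,
## conductivity under diameter conventions, electron-transport rates.

#' Fit the ohmic (linear) resistance of an I-V sweep
#'
#' Ordinary least squares of current on voltage restricted to the low-bias
#' window `|V| <= window`, with a free intercept (tolerates amplifier
#' offset).  The fiber resistance is the reciprocal slope.  A non-positive
#' slope (insulating control, e.g. a sweep on the bare substrate) is
#' reported as a flagged failure, not an error.
#'
#' @param curve an [iv_curve()].
#' @param window half-width of the fit window, volts.  The default 0.6 V
#'   restricts the fit to the regime where single-fiber sweeps are linear.
#' @return An object of class `ohmic_fit` with elements `R` (ohms),
#'   `intercept` (amperes), `r_squared`, `slope` (siemens), `window`,
#'   `n_points`, `ok` (FALSE for a flagged non-conducting fit) and `meta`
#'   (the curve's metadata).
#' @export
fit_ohmic_resistance <- function(curve, window = 0.6) {
  stopifnot(inherits(curve, "iv_curve"), window > 0)
  sel <- abs(curve$voltage) <= window
  if (sum(sel) < 5L)
    stop(sprintf("need at least 5 points inside the +/-%g V window", window))
  v <- curve$voltage[sel]; i <- curve$current[sel]
  fit <- stats::lm(i ~ v)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  sst <- sum((i - mean(i))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  ok <- is.finite(slope) && slope > 0
  structure(list(R = if (ok) 1 / slope else NA_real_,
                 slope = slope, intercept = intercept, r_squared = r2,
                 window = window, n_points = sum(sel), ok = ok,
                 reason = if (ok) NULL else
                   "non-conducting: fitted slope <= 0 (or degenerate) in window",
                 meta = curve$meta),
            class = "ohmic_fit")
}

#' @export
print.ohmic_fit <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("Ohmic fit (+/-%g V window, %d pts): R = %.4g Ohm (R^2 = %.4f)\n",
                x$window, x$n_points, x$R, x$r_squared))
    cat(sprintf("  intercept = %.3g A\n", x$intercept))
  } else {
    cat(sprintf("Ohmic fit FLAGGED: %s\n", x$reason))
  }
  invisible(x)
}

#' @export
coef.ohmic_fit <- function(object, ...) {
  c(R = object$R, slope = object$slope, intercept = object$intercept)
}

#' @export
predict.ohmic_fit <- function(object, voltage, ...) {
  object$intercept + object$slope * voltage
}

#' Regress fiber resistance against probing distance
#'
#' Fits both candidate laws — linear (`R = R_c + slope * d`, ohmic fiber
#' with contact resistance `R_c`) by OLS on `(d, R)`, and exponential
#' (`R = A * exp(rate * d)`, trap-dominated fiber) by OLS on `(d, ln R)` —
#' and selects the one with the higher coefficient of determination (tie
#' goes to linear).  Non-positive resistances make the exponential fit
#' undefined; it is then skipped with a warning.  A negative fitted contact
#' resistance is reported with a warning, never clamped.
#'
#' @param series a [distance_series()].
#' @return An object of class `distance_fit` with elements `model`
#'   (`"linear"` or `"exponential"`), `slope` (ohm/nm), `intercept` (ohms;
#'   the contact resistance for the linear law), `rate` (1/nm), `prefactor`
#'   (ohms), `r_squared` (named vector, both models), `contact_resistance`,
#'   `negative_intercept` flag and the input `series`.
#' @export
regress_distance <- function(series) {
  stopifnot(inherits(series, "distance_series"))
  d <- series$distance_nm; R <- series$R_ohm
  if (length(d) < 3L) stop("need at least 3 points for regression")
  r2_of <- function(fit, y) {
    sst <- sum((y - mean(y))^2)
    if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  }
  lin <- stats::lm(R ~ d)
  r2_lin <- r2_of(lin, R)
  slope <- unname(stats::coef(lin)[2])
  intercept <- unname(stats::coef(lin)[1])

  rate <- prefactor <- r2_exp <- NA_real_
  if (all(R > 0)) {
    ex <- stats::lm(log(R) ~ d)
    r2_exp <- r2_of(ex, log(R))
    rate <- unname(stats::coef(ex)[2])
    prefactor <- exp(unname(stats::coef(ex)[1]))
  } else {
    warning("non-positive resistances: exponential fit skipped")
  }
  model <- if (!is.na(r2_exp) && r2_exp > r2_lin) "exponential" else "linear"
  neg <- is.finite(intercept) && intercept < 0
  if (neg)
    warning("negative fitted contact resistance (linear intercept < 0)")
  structure(list(model = model, slope = slope, intercept = intercept,
                 rate = rate, prefactor = prefactor,
                 r_squared = c(linear = r2_lin, exponential = r2_exp),
                 contact_resistance = intercept,
                 negative_intercept = neg,
                 series = series),
            class = "distance_fit")
}

#' @export
print.distance_fit <- function(x, ...) {
  cat(sprintf("Distance-resistance fit: %s model selected\n", x$model))
  cat(sprintf("  linear:      R = %.4g + %.4g * d   (R^2 = %.4f)\n",
              x$intercept, x$slope, x$r_squared["linear"]))
  if (is.finite(x$r_squared["exponential"]))
    cat(sprintf("  exponential: R = %.4g * exp(%.4g * d) (R^2 = %.4f)\n",
                x$prefactor, x$rate, x$r_squared["exponential"]))
  cat(sprintf("  contact resistance (linear intercept): %.4g Ohm%s\n",
              x$contact_resistance,
              if (x$negative_intercept) "  [WARNING: negative]" else ""))
  invisible(x)
}

#' @export
coef.distance_fit <- function(object, ...) {
  if (object$model == "linear")
    c(intercept = object$intercept, slope = object$slope)
  else c(prefactor = object$prefactor, rate = object$rate)
}

#' @export
predict.distance_fit <- function(object, distance_nm, ...) {
  if (object$model == "linear")
    object$intercept + object$slope * distance_nm
  else object$prefactor * exp(object$rate * distance_nm)
}

#' Evaluate the selected distance law at a fiber length
#'
#' For the linear law the contact (intercept) term can be included or
#' excluded; both values are always reported so the along-fiber resistance
#' and the total two-point resistance can be quoted side by side.
#'
#' @param fit a `distance_fit` from [regress_distance()].
#' @param L_nm fiber length, nm (> 0; `L_nm = 0` returns the intercept
#'   itself under the linear law).
#' @param include_intercept whether `value` includes the contact term
#'   (linear model only).
#' @return List with `value` (ohms, per `include_intercept`),
#'   `with_intercept`, `without_intercept` (linear model; `NA` otherwise)
#'   and `model`.
#' @export
resistance_at_length <- function(fit, L_nm, include_intercept = TRUE) {
  stopifnot(inherits(fit, "distance_fit"), L_nm >= 0)
  if (fit$model == "linear") {
    w <- fit$intercept + fit$slope * L_nm
    wo <- fit$slope * L_nm
    list(value = if (include_intercept) w else wo,
         with_intercept = w, without_intercept = wo, model = "linear")
  } else {
    v <- fit$prefactor * exp(fit$rate * L_nm)
    list(value = v, with_intercept = NA_real_, without_intercept = NA_real_,
         model = "exponential")
  }
}

#' Fiber diameter conventions
#'
#' The conductivity of a fiber depends on the cross-section assumed for it;
#' several diameter conventions are in use for pili: the AFM-measured
#' height of the dried, immobilized fiber (2 nm), the solvated fiber core
#' from molecular models (3.5 nm), and the tip-deconvolved STM estimate
#' including the flexible C-terminal coil (4.7 nm).  Every conductivity or
#' resistivity this package reports is labeled with its convention.
#'
#' @param name one of `"afm_height"` (2 nm), `"solvated_core"` (3.5 nm),
#'   `"stm_estimate"` (4.7 nm) or `"custom"`.
#' @param diameter_nm fiber diameter, nm; required for `"custom"`,
#'   otherwise taken from the registry.
#' @return An object of class `geometry_convention`: list with `name`,
#'   `diameter_nm` and the circular `cross_section_nm2` (`pi d^2 / 4`).
#' @export
geometry_convention <- function(name = c("afm_height", "solvated_core",
                                         "stm_estimate", "custom"),
                                diameter_nm = NULL) {
  name <- match.arg(name)
  registry <- c(afm_height = 2.0, solvated_core = 3.5, stm_estimate = 4.7)
  d <- if (name == "custom") {
    if (is.null(diameter_nm)) stop("custom convention needs diameter_nm")
    diameter_nm
  } else diameter_nm %||% unname(registry[name])
  if (!is.numeric(d) || d <= 0) stop("diameter must be positive")
  structure(list(name = name, diameter_nm = d,
                 cross_section_nm2 = pi * d^2 / 4),
            class = "geometry_convention")
}

#' @export
print.geometry_convention <- function(x, ...) {
  cat(sprintf("geometry convention '%s': d = %g nm, A = %.4g nm^2\n",
              x$name, x$diameter_nm, x$cross_section_nm2))
  invisible(x)
}

#' Conductivity and resistivity of a fiber segment
#'
#' `sigma = L / (R * A)` with circular cross-section `A = pi d^2 / 4` under
#' the stated diameter convention; `rho = 1 / sigma`.  SI internally,
#' reported in S/cm and Ohm cm.
#'
#' @param R_ohm segment resistance, ohms (> 0).
#' @param length_nm segment length, nm (> 0).
#' @param geom a [geometry_convention()].
#' @return List with `sigma_S_cm`, `rho_ohm_cm`, `convention`,
#'   `diameter_nm`.  The product `sigma * rho` is 1 by construction.
#' @export
conductivity <- function(R_ohm, length_nm, geom = geometry_convention()) {
  stopifnot(R_ohm > 0, length_nm > 0, inherits(geom, "geometry_convention"))
  A_m2 <- geom$cross_section_nm2 * 1e-18
  sigma_S_m <- (length_nm * 1e-9) / (R_ohm * A_m2)
  sigma_S_cm <- sigma_S_m / 100
  list(sigma_S_cm = sigma_S_cm, rho_ohm_cm = 1 / sigma_S_cm,
       convention = geom$name, diameter_nm = geom$diameter_nm)
}

#' Electron transport rate through a resistance at a bias
#'
#' `rate = V / (R * e)` electrons per second, with `e` the elementary
#' charge.
#'
#' @param R_ohm resistance, ohms (> 0).
#' @param bias_V applied bias, volts.
#' @return electrons per second (numeric scalar).
#' @export
electron_rate <- function(R_ohm, bias_V) {
  stopifnot(R_ohm > 0)
  bias_V / (R_ohm * E_CHARGE)
}

#' Ratio of two rates in orders of magnitude
#'
#' Used to compare the single-fiber electron transport rate against the
#' cellular rate of Fe(III) oxide respiration.
#'
#' @param rate,reference_rate positive rates in the same units.
#' @return List with `orders` (`log10(rate / reference_rate)`) and
#'   `orders_int` (rounded to the nearest integer).
#' @export
rate_ratio_orders <- function(rate, reference_rate) {
  stopifnot(rate > 0, reference_rate > 0)
  o <- log10(rate / reference_rate)
  list(orders = o, orders_int = as.integer(round(o)))
}

#' Transport summary for one fiber
#'
#' Bundles the headline per-fiber quantities: resistance per micrometer,
#' conductivity and resistivity under a stated diameter convention, and the
#' electron transport rate at a stated bias.
#'
#' @param R_ohm resistance of the measured segment, ohms.
#' @param length_nm segment length, nm.
#' @param geom a [geometry_convention()].
#' @param bias_V bias for the electron-rate calculation, volts (default
#'   100 mV, the potential drop available between the inner-membrane
#'   quinone pool and extracellular Fe(III) acceptors).
#' @return An object of class `transport_summary`.
#' @export
transport_summary <- function(R_ohm, length_nm, geom = geometry_convention(),
                              bias_V = 0.1) {
  cond <- conductivity(R_ohm, length_nm, geom)
  structure(list(R_per_um = R_ohm / (length_nm / 1000),
                 sigma_S_cm = cond$sigma_S_cm,
                 rho_ohm_cm = cond$rho_ohm_cm,
                 convention = cond$convention,
                 diameter_nm = cond$diameter_nm,
                 electron_rate = electron_rate(R_ohm, bias_V),
                 bias_V = bias_V),
            class = "transport_summary")
}

#' @export
print.transport_summary <- function(x, ...) {
  cat(sprintf("Transport summary ('%s' convention, d = %g nm):\n",
              x$convention, x$diameter_nm))
  cat(sprintf("  R per um:      %.3g Ohm/um\n", x$R_per_um))
  cat(sprintf("  conductivity:  %.2g S/cm\n", x$sigma_S_cm))
  cat(sprintf("  resistivity:   %.2g Ohm cm\n", x$rho_ohm_cm))
  cat(sprintf("  electron rate: %.1g e/s at %g mV\n",
              x$electron_rate, 1000 * x$bias_V))
  invisible(x)
}
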