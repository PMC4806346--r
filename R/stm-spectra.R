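## STM tunneling spectroscopy and topography: sweep averaging, smoothed
## differential conductance, gap detection/classification, topographic
## periodicities and tip-deconvolution.

#' Average repeated tunneling sweeps
#'
#' Pointwise mean current over replicate sweeps.  Sweeps on different
#' voltage grids are resampled by linear interpolation onto the first
#' sweep's grid restricted to the common voltage range; disjoint ranges
#' are an error.
#'
#' @param spectra list of [iv_curve()] sweeps (>= 1).
#' @return An [iv_curve()] whose `meta$n_sweeps` records the number
#'   averaged.
#' @export
average_sweeps <- function(spectra) {
  if (inherits(spectra, "iv_curve")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, logical(1), "iv_curve")))
  if (length(spectra) == 1L) {
    out <- spectra[[1]]
    out$meta$n_sweeps <- 1L
    return(out)
  }
  lo <- max(vapply(spectra, function(s) min(s$voltage), numeric(1)))
  hi <- min(vapply(spectra, function(s) max(s$voltage), numeric(1)))
  if (lo >= hi) stop("sweeps have disjoint voltage ranges")
  grid <- spectra[[1]]$voltage
  grid <- grid[grid >= lo & grid <= hi]
  cur <- vapply(spectra, function(s)
    stats::approx(s$voltage, s$current, xout = grid)$y, numeric(length(grid)))
  out <- iv_curve(grid, rowMeans(cur),
                  temperature_K = spectra[[1]]$meta$temperature_K,
                  label = spectra[[1]]$meta$label,
                  meta = spectra[[1]]$meta)
  out$meta$n_sweeps <- length(spectra)
  out
}

#' Smoothed differential conductance dI/dV
#'
#' Local-polynomial (Savitzky-Golay) smoothing-differentiation of the
#' averaged current on its uniform voltage grid, via [signal::sgolayfilt()]
#' with derivative order 1.  The `(window_points - 1)/2` edge points on
#' each side, where the filter's one-sided fits are unreliable, are trimmed
#' and the trim recorded.
#'
#' @param spec an [iv_curve()] on a uniform voltage grid.
#' @param window_points odd filter window length (default 9).
#' @param poly_order local polynomial order (default 2).
#' @return An object of class `didv`: list with `voltage` (trimmed grid),
#'   `didv` (siemens), `window_points`, `poly_order`, `trimmed` (points
#'   removed per edge) and `temperature_K`.
#' @export
differential_conductance <- function(spec, window_points = 9L,
                                     poly_order = 2L) {
  stopifnot(inherits(spec, "iv_curve"))
  n <- length(spec$voltage)
  if (window_points %% 2L != 1L) stop("window_points must be odd")
  if (window_points > n) stop("window larger than the sweep")
  if (poly_order >= window_points) stop("poly_order must be < window_points")
  dv <- diff(spec$voltage)
  if (max(abs(dv - dv[1])) > 1e-9 * abs(dv[1]))
    stop("voltage grid must be uniform; resample first")
  g <- signal::sgolayfilt(spec$current, p = poly_order, n = window_points,
                          m = 1, ts = dv[1])
  k <- (window_points - 1L) %/% 2L
  keep <- (k + 1L):(n - k)
  ## propagate the raw current noise (white; estimated from successive
  ## differences) through the known derivative kernel
  sigma_i <- stats::mad(diff(spec$current, differences = 2)) / sqrt(6)
  kern <- signal::sgolay(p = poly_order, n = window_points, m = 1)
  wrow <- kern[k + 1L, ] / dv[1]
  structure(list(voltage = spec$voltage[keep], didv = g[keep],
                 window_points = window_points, poly_order = poly_order,
                 trimmed = k, noise_sd = sigma_i * sqrt(sum(wrow^2)),
                 temperature_K = spec$meta$temperature_K),
            class = "didv")
}

#' @export
print.didv <- function(x, ...) {
  cat(sprintf(
    "dI/dV: %d points (window %d, order %d, %d edge points trimmed/side)\n",
    length(x$voltage), x$window_points, x$poly_order, x$trimmed))
  invisible(x)
}

#' Detect a conductance gap in a dI/dV spectrum
#'
#' Finds the largest contiguous voltage interval over which `|dI/dV|` stays
#' at the noise floor (zero differential conductance), the signature of a
#' band gap.  With `noise_floor = "auto"` the threshold is three times the
#' dI/dV noise level carried by the `didv` object (raw current noise
#' propagated through the derivative kernel), floored at `floor_frac` of
#' the maximum `|dI/dV|` so a noiseless spectrum still has a usable
#' threshold.  The
#' gap is reported as present only if its width reaches `min_width`;
#' single-point dropouts inside a gap are bridged.  Because a derivative
#' filter of half-width k can only read zero slope k samples inside a flat
#' plateau, the threshold-crossing edges are expanded outward by the
#' filter half-width (`support_correction`).
#'
#' The auto threshold scales with the data, so detection is invariant
#' under global current rescaling.
#'
#' @param didv a `didv` object from [differential_conductance()].
#' @param noise_floor `"auto"` or an absolute threshold in siemens.
#' @param min_width minimum reportable gap width, volts (default 0.05).
#' @param floor_frac absolute-floor fraction of max |dI/dV| for the auto
#'   threshold.
#' @param support_correction expand the reported edges outward by the
#'   smoothing filter's half-width (default TRUE).
#' @return An object of class `gap_report`: list with `present`, `lower`,
#'   `upper`, `width` (volts) and `threshold` (siemens).
#' @export
detect_gap <- function(didv, noise_floor = "auto", min_width = 0.05,
                       floor_frac = 0.005, support_correction = TRUE) {
  stopifnot(inherits(didv, "didv"))
  g <- didv$didv; v <- didv$voltage
  n <- length(g)
  if (identical(noise_floor, "auto")) {
    noise <- didv$noise_sd %||% 0
    threshold <- max(3 * noise, floor_frac * max(abs(g)))
  } else {
    threshold <- as.numeric(noise_floor)
  }
  below <- abs(g) <= threshold
  ## the smoothed derivative is correlated over the filter window, so noise
  ## exceedances inside a gap come in short clumps; bridge above-threshold
  ## interruptions shorter than the window (gap edges are sustained rises)
  r <- rle(below)
  interior <- seq_along(r$values)[-c(1L, length(r$values))]
  fix <- interior[!r$values[interior] &
                    r$lengths[interior] < didv$window_points]
  if (length(fix)) {
    r$values[fix] <- TRUE
    below <- inverse.rle(r)
    r <- rle(below)
  }
  if (!any(r$values)) {
    return(structure(list(present = FALSE, lower = NA_real_,
                          upper = NA_real_, width = 0,
                          threshold = threshold, min_width = min_width),
                     class = "gap_report"))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  widths <- v[ends[runs]] - v[starts[runs]]
  bestrun <- runs[which.max(widths)]
  i0 <- starts[bestrun]; i1 <- ends[bestrun]
  ## refine edges at the threshold crossings of the smoothed curve
  lower <- if (i0 > 1L) {
    f <- (threshold - abs(g[i0 - 1])) / (abs(g[i0]) - abs(g[i0 - 1]))
    v[i0 - 1] + f * (v[i0] - v[i0 - 1])
  } else v[i0]
  upper <- if (i1 < n) {
    f <- (threshold - abs(g[i1 + 1])) / (abs(g[i1]) - abs(g[i1 + 1]))
    v[i1 + 1] + f * (v[i1] - v[i1 + 1])
  } else v[i1]
  if (!is.finite(lower)) lower <- v[i0]
  if (!is.finite(upper)) upper <- v[i1]
  if (support_correction) {
    half <- didv$trimmed * stats::median(diff(v))
    lower <- lower - half
    upper <- upper + half
  }
  width <- upper - lower
  structure(list(present = width >= min_width, lower = lower, upper = upper,
                 width = width, threshold = threshold,
                 min_width = min_width),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  if (x$present)
    cat(sprintf("gap: %.3g V (%.3g to %.3g V), threshold %.3g S\n",
                x$width, x$lower, x$upper, x$threshold))
  else cat(sprintf("no gap (threshold %.3g S, min width %.3g V)\n",
                   x$threshold, x$min_width))
  invisible(x)
}

#' Classify a tunneling spectrum from its gap report
#'
#' Conductors show finite differential conductance throughout; a sub-volt
#' gap (e.g. the hundreds-of-millivolt gap of redox conductors at
#' cryogenic temperature) is `"gapped_conducting"`; a gap of a volt or
#' more is the insulator signature.
#'
#' @param gap a `gap_report`.
#' @param insulator_gap_V gap width at and above which the spectrum is
#'   called insulating (default 1 V).
#' @return `"conducting"`, `"gapped_conducting"` or `"insulating"`.
#' @export
classify_spectrum <- function(gap, insulator_gap_V = 1.0) {
  stopifnot(inherits(gap, "gap_report"))
  if (!gap$present) "conducting"
  else if (gap$width < insulator_gap_V) "gapped_conducting"
  else "insulating"
}

#' Thermal voltage k_B T / e
#'
#' @param T_K temperature, kelvin (> 0).
#' @return thermal voltage in millivolts.
#' @export
thermal_voltage <- function(T_K) {
  stopifnot(all(T_K > 0))
  K_BOLTZ * T_K / E_CHARGE * 1000
}

#' Detect periodicities in a topographic height profile
#'
#' Autocorrelation of the mean-subtracted heights on the uniform sampling
#' grid; local maxima of the normalized autocorrelation above a prominence
#' threshold are reported as periods (peak lag times the sampling step),
#' sorted by score.  Mean subtraction makes the result invariant under a
#' constant height offset.
#'
#' @param profile a [topography_profile()] with uniform sampling.
#' @param max_period largest period searched, nm.  The profile must be at
#'   least four times this long.
#' @param prominence minimum normalized autocorrelation at a peak.
#' @return Data frame with columns `period_nm` and `score`, ordered by
#'   decreasing score (zero rows when nothing is periodic).
#' @export
find_periodicities <- function(profile, max_period = 30, prominence = 0.2) {
  stopifnot(inherits(profile, "topography_profile"))
  x <- profile$position_nm; h <- profile$height_nm
  dx <- diff(x)
  if (max(abs(dx - dx[1])) > 1e-9 * dx[1])
    stop("profile must be uniformly sampled")
  step <- dx[1]
  if ((max(x) - min(x)) < 4 * max_period)
    stop("profile shorter than 4 x max_period")
  lag_max <- floor(max_period / step)
  ac <- as.vector(stats::acf(h - mean(h), lag.max = lag_max,
                             plot = FALSE, demean = FALSE)$acf)
  ## ac[1] is lag 0; search interior local maxima
  peaks <- integer(0)
  for (k in 3:(length(ac) - 1)) {
    if (ac[k] > ac[k - 1] && ac[k] >= ac[k + 1] && ac[k] >= prominence)
      peaks <- c(peaks, k)
  }
  if (!length(peaks))
    return(data.frame(period_nm = numeric(0), score = numeric(0)))
  out <- data.frame(period_nm = (peaks - 1) * step, score = ac[peaks])
  out[order(-out$score), , drop = FALSE]
}

#' Tip-deconvolved fiber diameter from apparent scan width
#'
#' Scanning-probe images broaden narrow features by the tip geometry.
#' Under a spherical-tip/cylindrical-feature contact model the apparent
#' full width is `W = 4 * sqrt(R_tip * r)` for a cylinder of radius `r`,
#' so the true radius is recovered as `r = (W/4)^2 / R_tip`.
#'
#' @param apparent_width_nm apparent full width of the feature, nm.
#' @param tip_radius_nm tip radius of curvature, nm.
#' @param apparent_height_nm apparent height, nm (recorded; unused by this
#'   model).
#' @return List with `diameter_nm`, `radius_nm`, `consistent` (FALSE when
#'   the recovered radius exceeds half the apparent width, i.e. the model
#'   geometry is violated) and `model`.
#' @export
deconvolve_width <- function(apparent_width_nm, tip_radius_nm,
                             apparent_height_nm = NA_real_) {
  stopifnot(apparent_width_nm > 0, tip_radius_nm > 0)
  r <- (apparent_width_nm / 4)^2 / tip_radius_nm
  list(diameter_nm = 2 * r, radius_nm = r,
       consistent = r <= apparent_width_nm / 2,
       apparent_height_nm = apparent_height_nm,
       model = "sphere_on_cylinder")
}

#' Forward tip-convolution model
#'
#' Apparent full width of a cylinder of radius `radius_nm` imaged with a
#' spherical tip: `W = 4 * sqrt(R_tip * r)`.
#'
#' @param radius_nm cylinder radius, nm.
#' @param tip_radius_nm tip radius, nm.
#' @return apparent width, nm.
#' @export
convolve_width <- function(radius_nm, tip_radius_nm) {
  stopifnot(radius_nm >= 0, tip_radius_nm >= 0)
  4 * sqrt(tip_radius_nm * radius_nm)
}
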