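## Seeded synthetic-data generators.  Every generator takes an explicit
## integer seed, leaves the caller's RNG stream untouched, and records its
## ground-truth parameters in the returned object's metadata so round-trip
## tests can compare recovered against planted values.

#' Generate a synthetic ohmic I-V sweep
#'
#' Emulates a CP-AFM sweep on a conducting fiber: `I = V/R` plus additive
#' i.i.d. Gaussian current noise.
#'
#' @param R fiber resistance, ohms (> 0).
#' @param v_range half-range of the symmetric sweep, volts (sweep covers
#'   `-v_range .. +v_range`).
#' @param n_points number of samples (>= 5).
#' @param noise_sd Gaussian current noise standard deviation, amperes.
#' @param seed integer seed; fully determines the output.
#' @param distance_nm,label optional probe metadata.
#' @return An [iv_curve()] whose `meta$truth` records the generator inputs.
#' @export
gen_ohmic_iv <- function(R, v_range = 1, n_points = 201, noise_sd = 0,
                         seed = 1L, distance_nm = NA_real_,
                         label = "synthetic ohmic") {
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("R must be a single positive resistance in ohms")
  if (n_points < 5L) stop("n_points must be >= 5")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  v <- seq(-v_range, v_range, length.out = n_points)
  i <- v / R
  if (noise_sd > 0) i <- i + with_seed(seed, stats::rnorm(n_points, 0, noise_sd))
  iv_curve(v, i, distance_nm = distance_nm, label = label,
           meta = list(truth = list(kind = "ohmic_iv", R = R,
                                    noise_sd = noise_sd, seed = seed)))
}

#' Current noise that yields a target in-window ohmic fit quality
#'
#' Returns the additive Gaussian current noise standard deviation for which
#' the expected coefficient of determination of the in-window ohmic fit of
#' [gen_ohmic_iv()] output equals `r2`.  Used to calibrate fixtures to the
#' fit-quality band typical of single-fiber CP-AFM sweeps (R^2 of 0.98-0.99).
#'
#' @inheritParams gen_ohmic_iv
#' @param window half-width of the fit window, volts.
#' @param r2 target coefficient of determination.
#' @return noise standard deviation, amperes.
#' @export
iv_noise_for_r2 <- function(R, v_range = 1, n_points = 201, window = 0.6,
                            r2 = 0.985) {
  stopifnot(R > 0, r2 > 0, r2 < 1)
  v <- seq(-v_range, v_range, length.out = n_points)
  vin <- v[abs(v) <= window]
  (1 / R) * stats::sd(vin) * sqrt((1 - r2) / r2)
}

#' Generate a synthetic space-charge-limited-transport I-V sweep
#'
#' Below the crossover voltage `V_C` the curve is ohmic (`I = V/R_ohmic`);
#' above it the current follows the power law `I = alpha * |V|^b * sign(V)`
#' with `alpha = V_C^(1-b) / R_ohmic`, which makes the curve continuous at
#' the crossover.  The curve is antisymmetric in V.
#'
#' @param R_ohmic below-crossover resistance, ohms.
#' @param V_C crossover voltage, volts (`0 < V_C < v_max`).
#' @param b power-law exponent (>= 1); 2 for trap-free SCLT, > 2 when
#'   charge traps limit the injected current.
#' @param v_max half-range of the sweep, volts.
#' @inheritParams gen_ohmic_iv
#' @return An [iv_curve()]; `meta$truth` records `R_ohmic`, `V_C`, `b` and
#'   the implied `alpha`.
#' @export
gen_sclt_iv <- function(R_ohmic, V_C, b, v_max = 1, n_points = 201,
                        noise_sd = 0, seed = 1L, distance_nm = NA_real_,
                        label = "synthetic SCLT") {
  stopifnot(R_ohmic > 0, b >= 1, noise_sd >= 0, n_points >= 5)
  if (!(V_C > 0 && V_C < v_max))
    stop("V_C must lie strictly inside the sweep range (0 < V_C < v_max)")
  alpha <- V_C^(1 - b) / R_ohmic
  v <- seq(-v_max, v_max, length.out = n_points)
  i <- ifelse(abs(v) <= V_C, v / R_ohmic, sign(v) * alpha * abs(v)^b)
  if (noise_sd > 0) i <- i + with_seed(seed, stats::rnorm(n_points, 0, noise_sd))
  iv_curve(v, i, distance_nm = distance_nm, label = label,
           meta = list(truth = list(kind = "sclt_iv", R_ohmic = R_ohmic,
                                    V_C = V_C, b = b, alpha = alpha,
                                    noise_sd = noise_sd, seed = seed)))
}

#' Assemble a resistance-versus-distance series
#'
#' @param distance_nm probing distances, nm (positive, >= 3 points).
#' @param R_ohm fitted resistances, ohms.
#' @param r_squared optional per-point ohmic-fit quality.
#' @param label fiber label.
#' @param meta additional metadata list.
#' @return An object of class `distance_series`: a data frame with columns
#'   `distance_nm`, `R_ohm`, `r_squared` plus `label`/`meta` attributes.
#' @export
distance_series <- function(distance_nm, R_ohm, r_squared = NA_real_,
                            label = NULL, meta = list()) {
  if (length(distance_nm) < 3L)
    stop("a distance series needs at least 3 points")
  if (any(distance_nm <= 0)) stop("distances must be positive")
  if (length(distance_nm) != length(R_ohm))
    stop("distance_nm and R_ohm must have the same length")
  d <- data.frame(distance_nm = as.numeric(distance_nm),
                  R_ohm = as.numeric(R_ohm),
                  r_squared = rep_len(as.numeric(r_squared),
                                      length(distance_nm)))
  structure(d, label = label, meta = meta,
            class = c("distance_series", "data.frame"))
}

#' Generate a synthetic resistance-versus-distance series
#'
#' Two laws are supported, mirroring the two behaviours seen along single
#' fibers: `linear` — `R(d) = intercept + slope * d` (ohmic fiber with a
#' contact term); `exponential` — `R(d) = intercept * exp(rate * d)`
#' (cumulative charge-trap scattering).  Additive Gaussian noise on R.
#'
#' @param model `"linear"` or `"exponential"`.
#' @param slope_or_rate slope in ohm/nm (linear) or rate in 1/nm
#'   (exponential).
#' @param intercept intercept in ohms (linear: contact resistance;
#'   exponential: prefactor).
#' @param distances probing distances, nm (>= 3, positive).
#' @param noise_sd Gaussian noise on R, ohms.
#' @param seed integer seed.
#' @param label fiber label.
#' @return A [distance_series()] with planted truth in its `meta` attribute.
#' @export
gen_distance_series <- function(model = c("linear", "exponential"),
                                slope_or_rate, intercept, distances,
                                noise_sd = 0, seed = 1L, label = NULL) {
  model <- match.arg(model)
  if (length(distances) < 3L)
    stop("a distance series needs at least 3 points")
  if (any(distances <= 0)) stop("distances must be positive")
  stopifnot(noise_sd >= 0)
  R <- switch(model,
              linear      = intercept + slope_or_rate * distances,
              exponential = intercept * exp(slope_or_rate * distances))
  if (noise_sd > 0)
    R <- R + with_seed(seed, stats::rnorm(length(distances), 0, noise_sd))
  distance_series(distances, R, label = label,
                  meta = list(truth = list(kind = "distance_series",
                                           model = model,
                                           slope_or_rate = slope_or_rate,
                                           intercept = intercept,
                                           noise_sd = noise_sd, seed = seed)))
}

## --- helical fiber with aromatic ring proxies --------------------------

ring_atom_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")

## planar 6-carbon hexagon (bond length 1.4 A -> circumradius 1.4 A),
## ring plane perpendicular to z
ring_template <- function() {
  ang <- (0:5) * pi / 3
  cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
}

rot_z <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

#' Generate a synthetic helical fiber trajectory with aromatic ring proxies
#'
#' Builds an idealized type IV pilus-like fiber: `n_subunits` subunits
#' placed on a helix (`rise` per subunit along z, `twist` about z, subunit
#' centers at `radius` from the axis), each carrying pseudo-residues whose
#' side chains are 6-carbon planar hexagons (1.4 Angstrom bond length) —
#' minimal ring proxies for tyrosine/phenylalanine.  Setting
#' `remove_ring_at` replaces that residue's ring carbons with a single
#' beta-carbon in every subunit (an alanine-like substitution, emulating an
#' aromatic-to-alanine mutant fiber).  Frames are independently jittered
#' copies of the base geometry.
#'
#' @param n_subunits number of subunits (>= 2).
#' @param rise helical rise per subunit, Angstrom.
#' @param twist helical twist per subunit, degrees.
#' @param aromatics_per_subunit list of length-3 numeric offsets (Angstrom)
#'   of each pseudo-residue's ring center from the subunit center, in the
#'   subunit's local frame; names `"TYR"`/`"PHE"` set residue identity
#'   (unnamed entries alternate TYR, PHE, ...).
#' @param remove_ring_at residue index (within each subunit) whose ring is
#'   replaced by a lone beta-carbon, or `NULL` for the unmutated fiber.
#' @param jitter_sd per-atom, per-frame Gaussian positional noise, Angstrom.
#' @param n_frames number of frames (>= 1).
#' @param seed integer seed.
#' @param radius distance of subunit centers from the helix axis, Angstrom.
#' @return An object of class `fiber_trajectory`: list with `atoms` (data
#'   frame: `chain`, `resno`, `resname`, `name`, `element`), `coords`
#'   (`n_atoms x 3 x n_frames` array, Angstrom) and `meta`.
#' @export
gen_fiber <- function(n_subunits = 6, rise = 10, twist = 60,
                      aromatics_per_subunit = list(TYR = c(0, 0, 0),
                                                   PHE = c(4.5, 0, 4)),
                      remove_ring_at = NULL, jitter_sd = 0, n_frames = 1,
                      seed = 1L, radius = 10) {
  stopifnot(n_subunits >= 2, n_frames >= 1, jitter_sd >= 0)
  n_res <- length(aromatics_per_subunit)
  if (n_res < 1L) stop("need at least one aromatic pseudo-residue")
  if (!is.null(remove_ring_at) &&
      (remove_ring_at < 1L || remove_ring_at > n_res))
    stop("remove_ring_at must index a residue in aromatics_per_subunit")
  resnames <- names(aromatics_per_subunit)
  if (is.null(resnames)) resnames <- rep("", n_res)
  alt <- rep(c("TYR", "PHE"), length.out = n_res)
  resnames <- ifelse(resnames == "", alt, resnames)

  atoms <- list(); xyz <- list()
  for (s in seq_len(n_subunits)) {
    Rz <- rot_z((s - 1) * twist)
    center <- c(radius * cos((s - 1) * twist * pi / 180),
                radius * sin((s - 1) * twist * pi / 180),
                (s - 1) * rise)
    for (r in seq_len(n_res)) {
      off <- as.numeric(aromatics_per_subunit[[r]])
      ring_center <- center + as.vector(Rz %*% off)
      removed <- !is.null(remove_ring_at) && r == remove_ring_at
      if (removed) {
        coords <- matrix(ring_center, 1, 3)
        nm <- "CB"; rn <- "ALA"
      } else {
        coords <- sweep(ring_template() %*% t(Rz), 2, ring_center, `+`)
        nm <- ring_atom_names; rn <- resnames[r]
      }
      atoms[[length(atoms) + 1L]] <- data.frame(
        chain = LETTERS[((s - 1) %% 26) + 1], resno = r, resname = rn,
        name = nm, element = "C", stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1L]] <- coords
    }
  }
  atoms <- do.call(rbind, atoms)
  base <- do.call(rbind, xyz)
  n_atoms <- nrow(base)
  coords <- with_seed(seed, {
    out <- array(0, dim = c(n_atoms, 3, n_frames))
    for (f in seq_len(n_frames)) {
      jit <- if (jitter_sd > 0)
        matrix(stats::rnorm(n_atoms * 3, 0, jitter_sd), n_atoms, 3) else 0
      out[, , f] <- base + jit
    }
    out
  })
  structure(list(atoms = atoms, coords = coords,
                 meta = list(truth = list(kind = "fiber",
                                          n_subunits = n_subunits,
                                          rise = rise, twist = twist,
                                          remove_ring_at = remove_ring_at,
                                          jitter_sd = jitter_sd,
                                          seed = seed))),
            class = "fiber_trajectory")
}

#' @export
print.fiber_trajectory <- function(x, ...) {
  cat(sprintf("fiber trajectory: %d atoms, %d frame(s), %d chain(s)\n",
              nrow(x$atoms), dim(x$coords)[3], length(unique(x$atoms$chain))))
  invisible(x)
}

#' Write a fiber trajectory as a multi-MODEL PDB file
#'
#' Frames become `MODEL`/`ENDMDL` blocks; chains identify subunits;
#' coordinates are in Angstrom.
#'
#' @param traj a `fiber_trajectory` (see [gen_fiber()]).
#' @param path output file path.
#' @return `path`, invisibly.  `fiber_pdb_text` returns the PDB text as a
#'   character vector of lines.
#' @export
write_fiber_pdb <- function(traj, path) {
  writeLines(fiber_pdb_text(traj), path)
  invisible(path)
}

#' @rdname write_fiber_pdb
#' @export
fiber_pdb_text <- function(traj) {
  stopifnot(inherits(traj, "fiber_trajectory"))
  a <- traj$atoms
  n_frames <- dim(traj$coords)[3]
  out <- character(0)
  for (f in seq_len(n_frames)) {
    xyz <- traj$coords[, , f, drop = FALSE]
    name4 <- ifelse(nchar(a$name) < 4L, sprintf(" %-3s", a$name), a$name)
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)), name4, a$resname, a$chain, a$resno,
      xyz[, 1, 1], xyz[, 2, 1], xyz[, 3, 1], a$element)
    out <- c(out, sprintf("MODEL     %4d", f), lines, "ENDMDL")
  }
  c(out, "END")
}

#' Generate synthetic STM tunneling I-V sweeps
#'
#' The underlying differential conductance is
#' `g(V) = conduct_scale * (1 + curvature * V^2)` outside the gap interval
#' and exactly zero inside it; the current is the integral of `g` from 0.
#' With `gap_width = 0` the current is a smooth odd polynomial with nonzero
#' slope everywhere (a gapless conductor); with `gap_width > 0` the current
#' is flat across the gap (zero differential conductance), as in
#' cryogenic-temperature spectra of redox conductors or wide-gap insulators.
#'
#' @param gap_width width of the zero-conductance interval, volts (>= 0).
#' @param gap_center center of the gap, volts.
#' @param conduct_scale baseline conductance, siemens.
#' @param n_sweeps number of noisy replicate sweeps.
#' @param v_range half-range of the sweep, volts.
#' @param curvature cubic nonlinearity coefficient, 1/V^2.
#' @param temperature_K recorded measurement temperature.
#' @inheritParams gen_ohmic_iv
#' @return A list of [iv_curve()] objects (length `n_sweeps`).
#' @export
gen_stm_iv <- function(gap_width = 0, gap_center = 0, conduct_scale = 1e-9,
                       n_sweeps = 1, v_range = 1, n_points = 201,
                       noise_sd = 0, seed = 1L, curvature = 1,
                       temperature_K = 298, label = "synthetic STM") {
  stopifnot(gap_width >= 0, conduct_scale > 0, n_sweeps >= 1, noise_sd >= 0)
  v <- seq(-v_range, v_range, length.out = n_points)
  a <- gap_center - gap_width / 2
  b <- gap_center + gap_width / 2
  G <- function(x) conduct_scale * (x + curvature * x^3 / 3)
  ## antiderivative of the gapped conductance
  Gg <- function(x) {
    ifelse(x <= a, G(x),
           ifelse(x >= b, G(x) - (G(b) - G(a)), G(a)))
  }
  i0 <- Gg(v) - Gg(0)
  with_seed(seed, {
    lapply(seq_len(n_sweeps), function(k) {
      i <- i0
      if (noise_sd > 0) i <- i + stats::rnorm(n_points, 0, noise_sd)
      iv_curve(v, i, label = label, temperature_K = temperature_K,
               meta = list(truth = list(kind = "stm_iv",
                                        gap_width = gap_width,
                                        gap_center = gap_center,
                                        conduct_scale = conduct_scale,
                                        curvature = curvature,
                                        noise_sd = noise_sd, seed = seed,
                                        sweep = k)))
    })
  })
}

#' Generate a synthetic 1-D topographic height profile
#'
#' Sum of sinusoids plus Gaussian height noise, emulating periodic
#' substructure along a fiber imaged by scanning-probe microscopy.
#'
#' @param periods spatial periods, nm (each must exceed `2 * sampling`).
#' @param amplitudes per-period amplitudes, nm (recycled).
#' @param length profile length, nm.
#' @param sampling sampling step, nm.
#' @param noise_sd Gaussian height noise, nm.
#' @param seed integer seed.
#' @return An object of class `topography_profile`: data frame with columns
#'   `position_nm`, `height_nm`; `sampling_nm` and `meta` attributes.
#' @export
gen_topography <- function(periods = numeric(0), amplitudes = 1,
                           length = 200, sampling = 0.5, noise_sd = 0,
                           seed = 1L) {
  stopifnot(sampling > 0, noise_sd >= 0)
  if (length(periods) && any(periods <= 2 * sampling))
    stop("all periods must exceed 2 * sampling (Nyquist-resolvable)")
  x <- seq(0, length, by = sampling)
  h <- rep(0, length(x))
  if (length(periods)) {
    amplitudes <- rep_len(amplitudes, length(periods))
    for (k in seq_along(periods))
      h <- h + amplitudes[k] * sin(2 * pi * x / periods[k])
  }
  if (noise_sd > 0) h <- h + with_seed(seed, stats::rnorm(length(x), 0, noise_sd))
  topography_profile(x, h,
                     meta = list(truth = list(kind = "topography",
                                              periods = periods,
                                              amplitudes = amplitudes,
                                              noise_sd = noise_sd,
                                              seed = seed)))
}

#' Topographic height profile container
#'
#' @param position_nm monotone increasing positions, nm.
#' @param height_nm heights, nm.
#' @param meta metadata list.
#' @return A `topography_profile` data frame.
#' @export
topography_profile <- function(position_nm, height_nm, meta = list()) {
  stopifnot(length(position_nm) == length(height_nm))
  if (is.unsorted(position_nm, strictly = TRUE))
    stop("positions must be strictly increasing")
  structure(data.frame(position_nm = position_nm, height_nm = height_nm),
            meta = meta,
            class = c("topography_profile", "data.frame"))
}

#' Generate a synthetic optical spectrum
#'
#' Gaussian mixture on a wavelength grid: each component is
#' `height * exp(-(lambda - center)^2 / (2 width^2))`.  Used to emulate
#' absorption or fluorescence-emission spectra with or without cofactor
#' bands (flavin, heme Soret, quinone).
#'
#' @param components list of numeric triples `c(center_nm, width_nm,
#'   height)`; an empty list gives a flat (zero) spectrum.
#' @param range wavelength range, nm (length-2).
#' @param n_points grid size.
#' @param noise_sd additive Gaussian signal noise.
#' @param seed integer seed.
#' @param mode `"absorption"` or `"emission"`.
#' @param excitation_nm excitation wavelength (emission mode).
#' @return An object of class `optical_spectrum`: data frame with columns
#'   `wavelength_nm`, `signal`; `mode` attribute.
#' @export
gen_optical <- function(components = list(), range = c(200, 700),
                        n_points = 501, noise_sd = 0, seed = 1L,
                        mode = c("absorption", "emission"),
                        excitation_nm = NA_real_) {
  mode <- match.arg(mode)
  stopifnot(length(range) == 2, range[2] > range[1], noise_sd >= 0)
  for (cmp in components) {
    if (length(cmp) != 3) stop("each component is c(center, width, height)")
    if (cmp[1] < range[1] || cmp[1] > range[2])
      stop("component centers must lie within the wavelength range")
  }
  wl <- seq(range[1], range[2], length.out = n_points)
  sig <- rep(0, n_points)
  for (cmp in components)
    sig <- sig + cmp[3] * exp(-(wl - cmp[1])^2 / (2 * cmp[2]^2))
  if (noise_sd > 0) sig <- sig + with_seed(seed, stats::rnorm(n_points, 0, noise_sd))
  optical_spectrum(wl, sig, mode = mode, excitation_nm = excitation_nm,
                   meta = list(truth = list(kind = "optical",
                                            components = components,
                                            noise_sd = noise_sd,
                                            seed = seed)))
}

#' Optical spectrum container
#'
#' @param wavelength_nm monotone increasing wavelengths, nm.
#' @param signal absorbance (unitless) or fluorescence counts.
#' @param mode `"absorption"` or `"emission"`.
#' @param excitation_nm excitation wavelength for emission spectra.
#' @param meta metadata list.
#' @return An `optical_spectrum` data frame.
#' @export
optical_spectrum <- function(wavelength_nm, signal,
                             mode = c("absorption", "emission"),
                             excitation_nm = NA_real_, meta = list()) {
  mode <- match.arg(mode)
  stopifnot(length(wavelength_nm) == length(signal),
            all(is.finite(signal)))
  if (is.unsorted(wavelength_nm, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  structure(data.frame(wavelength_nm = wavelength_nm, signal = signal),
            mode = mode, excitation_nm = excitation_nm, meta = meta,
            class = c("optical_spectrum", "data.frame"))
}

#' Validate and assemble an elemental-concentration table
#'
#' Pass-through with schema validation for inductively-coupled-plasma
#' elemental analysis results.
#'
#' @param rows a data frame with columns `element` (character) and `ppm`
#'   (non-negative micrograms per mL), or a list of `list(element, ppm)`
#'   pairs.
#' @return An `elemental_table` data frame.
#' @export
gen_elemental <- function(rows) {
  if (is.list(rows) && !is.data.frame(rows))
    rows <- do.call(rbind, lapply(rows, function(r)
      data.frame(element = as.character(r[[1]]), ppm = as.numeric(r[[2]]))))
  if (!is.data.frame(rows) || !all(c("element", "ppm") %in% names(rows)))
    stop("elemental rows must have columns element, ppm")
  if (!is.numeric(rows$ppm) || any(!is.finite(rows$ppm)) || any(rows$ppm < 0))
    stop("ppm values must be finite and non-negative")
  if (any(!nzchar(as.character(rows$element))))
    stop("element symbols must be non-empty")
  structure(data.frame(element = as.character(rows$element),
                       ppm = rows$ppm),
            class = c("elemental_table", "data.frame"))
}
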