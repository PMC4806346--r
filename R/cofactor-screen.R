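## Optical cofactor screening (flavin, heme, quinone, tyrosine/tyrosinate
## bands) and elemental atoms-per-subunit conversion.

#' Detect peaks in an optical spectrum
#'
#' Local maxima whose topographic prominence reaches `prominence_frac`
#' times the signal range.
#'
#' @param spec an [optical_spectrum()] with at least 10 samples.
#' @param prominence_frac minimum prominence as a fraction of the signal
#'   range (default 0.05).
#' @return An object of class `peak_list`: data frame with columns
#'   `center_nm`, `height`, `prominence`, plus a `mode` attribute.
#' @export
detect_peaks <- function(spec, prominence_frac = 0.05) {
  stopifnot(inherits(spec, "optical_spectrum"))
  y <- spec$signal; x <- spec$wavelength_nm
  n <- length(y)
  if (n < 10L) stop("need at least 10 samples")
  rng <- diff(range(y))
  idx <- which(diff(sign(diff(y))) == -2) + 1L   # strict local maxima
  if (!length(idx) || rng == 0) {
    out <- data.frame(center_nm = numeric(0), height = numeric(0),
                      prominence = numeric(0))
    return(structure(out, mode = attr(spec, "mode"), class =
                       c("peak_list", "data.frame")))
  }
  prom <- vapply(idx, function(i) {
    h <- y[i]
    left <- if (i > 1) {
      higher <- which(y[1:(i - 1)] > h)
      lo <- if (length(higher)) (max(higher) + 1):(i - 1) else 1:(i - 1)
      min(y[lo])
    } else h
    right <- if (i < n) {
      higher <- which(y[(i + 1):n] > h)
      hi <- if (length(higher)) (i + 1):(i + min(higher) - 1) else (i + 1):n
      min(y[hi])
    } else h
    h - max(left, right)
  }, numeric(1))
  keep <- prom >= prominence_frac * rng
  out <- data.frame(center_nm = x[idx[keep]], height = y[idx[keep]],
                    prominence = prom[keep])
  out <- out[order(-out$prominence), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, mode = attr(spec, "mode"),
            class = c("peak_list", "data.frame"))
}

#' Reference cofactor band table
#'
#' Band centers (nm) used by [screen_cofactors()]: tyrosine absorbs near
#' 270 nm and emits near 300 nm; its ionized form tyrosinate emits
#' red-shifted near 340 nm; flavins absorb at ~360 and ~450 nm (both
#' required); oxidized c-type cytochrome heme shows the Soret band at
#' 406 nm and a broad band at 528 nm (both required); quinone/flavin
#' fluorescence falls in a configurable emission window.
#'
#' @param quinone_emission_band length-2 emission window, nm.
#' @return Nested list of band definitions.
#' @export
cofactor_bands <- function(quinone_emission_band = c(400, 550)) {
  list(tyrosine   = list(absorption = 270, emission = 300, require_all = FALSE),
       tyrosinate = list(emission = 340, require_all = TRUE),
       flavin     = list(absorption = c(360, 450), require_all = TRUE),
       heme       = list(absorption = c(406, 528), require_all = TRUE),
       quinone    = list(emission_window = quinone_emission_band))
}

#' Screen peak lists for redox-cofactor signatures
#'
#' Matches detected absorption/emission peaks against the cofactor band
#' table within a wavelength tolerance.  Flavin and heme require all of
#' their bands (the absence argument rests on the absence of both);
#' tyrosine is flagged on either its absorption or its emission band; the
#' quinone flag fires on any emission peak inside the configured window.
#' Adding peaks can only turn flags on, never off.
#'
#' @param absorption,emission `peak_list` objects (at least one).
#' @param tolerance_nm band-match tolerance, nm (default 10).
#' @param bands band table from [cofactor_bands()].
#' @return An object of class `cofactor_flags`: list with `flags` (named
#'   logical: tyrosine, tyrosinate, flavin, heme, quinone), `evidence`
#'   (per-flag matched/unmatched bands) and `tolerance_nm`.
#' @export
screen_cofactors <- function(absorption = NULL, emission = NULL,
                             tolerance_nm = 10, bands = cofactor_bands()) {
  if (is.null(absorption) && is.null(emission))
    stop("need at least one peak list")
  centers <- function(pl) if (is.null(pl)) numeric(0) else pl$center_nm
  abs_c <- centers(absorption); em_c <- centers(emission)
  match_band <- function(target, cs)
    vapply(target, function(t) any(abs(cs - t) <= tolerance_nm), logical(1))

  evidence <- list(); flags <- logical(0)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (!is.null(b$emission_window)) {
      hit <- em_c[em_c >= b$emission_window[1] & em_c <= b$emission_window[2]]
      flags[nm] <- length(hit) > 0
      evidence[[nm]] <- list(window = b$emission_window, matched = hit)
      next
    }
    hits <- c(if (!is.null(b$absorption))
                stats::setNames(match_band(b$absorption, abs_c),
                                paste0("abs_", b$absorption)),
              if (!is.null(b$emission))
                stats::setNames(match_band(b$emission, em_c),
                                paste0("em_", b$emission)))
    flags[nm] <- if (isTRUE(b$require_all)) all(hits) else any(hits)
    evidence[[nm]] <- list(matched = names(hits)[hits],
                           unmatched = names(hits)[!hits])
  }
  structure(list(flags = flags, evidence = evidence,
                 tolerance_nm = tolerance_nm),
            class = "cofactor_flags")
}

#' @export
print.cofactor_flags <- function(x, ...) {
  cat("Cofactor screen (tolerance", x$tolerance_nm, "nm):\n")
  for (nm in names(x$flags))
    cat(sprintf("  %-10s %s\n", nm, if (x$flags[nm]) "DETECTED" else "absent"))
  invisible(x)
}

#' Elemental atoms per pilin subunit
#'
#' Converts an element's measured concentration and the protein
#' concentration of the same preparation into a molar ratio:
#' `atoms/subunit = (ppm / M_element) / (protein / M_pilin)`, i.e. moles
#' of element per mole of pilin.  With replicate ppm values the standard
#' deviation is propagated to the result (the conversion is linear in
#' ppm).  Dilution-invariant: rescaling both concentrations by the same
#' factor leaves the result unchanged.
#'
#' @param element_ppm element concentration(s), micrograms/mL; a vector of
#'   replicates propagates uncertainty.
#' @param element_molar_mass g/mol.
#' @param protein_conc protein concentration, micrograms/mL (> 0).
#' @param pilin_mass_da pilin subunit mass, Da (default 6568.51, the
#'   predicted mature Geobacter pilin).
#' @return List with `atoms_per_subunit`, `sd` (NA with a single
#'   replicate), `n_replicates` and the inputs.
#' @export
atoms_per_subunit <- function(element_ppm, element_molar_mass, protein_conc,
                              pilin_mass_da = 6568.51) {
  stopifnot(all(element_ppm >= 0), element_molar_mass > 0,
            pilin_mass_da > 0)
  if (protein_conc <= 0) stop("protein concentration must be positive")
  pilin_molar <- protein_conc / pilin_mass_da     # umol-equivalents per mL
  atoms <- (mean(element_ppm) / element_molar_mass) / pilin_molar
  s <- if (length(element_ppm) >= 2L)
    (stats::sd(element_ppm) / element_molar_mass) / pilin_molar
  else NA_real_
  list(atoms_per_subunit = atoms, sd = s,
       n_replicates = length(element_ppm),
       inputs = list(element_molar_mass = element_molar_mass,
                     protein_conc = protein_conc,
                     pilin_mass_da = pilin_mass_da))
}

#' Convert a molecular mass from daltons to micrograms
#'
#' `1 Da = 1.66053906660e-24 g`.
#'
#' @param mass_da mass in daltons (> 0).
#' @return mass in micrograms.
#' @export
dalton_to_microgram <- function(mass_da) {
  stopifnot(all(mass_da > 0))
  mass_da * DALTON_G * 1e6
}

#' Cellular respiration rate in electrons per cell per second
#'
#' One electron is transferred per Fe(III) reduced to Fe(II), so the
#' electron rate is the molar Fe(III) reduction rate times Avogadro's
#' number.
#'
#' @param fe_reduction_rate mol Fe(III) per cell per second (>= 0).
#' @return electrons per cell per second.
#' @export
respiration_electron_rate <- function(fe_reduction_rate) {
  stopifnot(all(fe_reduction_rate >= 0))
  fe_reduction_rate * AVOGADRO
}

#' Compare a fiber transport rate with the cellular respiration rate
#'
#' Delegates to [rate_ratio_orders()].
#'
#' @param pilus_rate single-fiber electron transport rate, e/s.
#' @param respiration_rate cellular respiration rate, e/cell/s.
#' @return List with `orders` and `orders_int` (see [rate_ratio_orders()]).
#' @export
compare_to_respiration <- function(pilus_rate, respiration_rate) {
  rate_ratio_orders(pilus_rate, respiration_rate)
}
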