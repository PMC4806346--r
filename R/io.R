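## Plain-text readers/writers for the remaining tabular formats.

#' Read / write topography, optical and elemental CSV tables
#'
#' Schemas: topography `position_nm,height_nm`; optical
#' `wavelength_nm,signal`; elemental `element,ppm`.  All with header rows.
#'
#' @param path file path.
#' @param ... extra arguments passed to the corresponding constructor.
#' @return The corresponding container object, or `path` invisibly for the
#'   writers.
#' @export
read_topography_csv <- function(path, ...) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("position_nm", "height_nm") %in% names(d)))
    stop("topography CSV must have columns position_nm,height_nm")
  topography_profile(d$position_nm, d$height_nm, ...)
}

#' @param profile a [topography_profile()].
#' @rdname read_topography_csv
#' @export
write_topography_csv <- function(profile, path) {
  utils::write.csv(data.frame(position_nm = profile$position_nm,
                              height_nm = profile$height_nm),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_topography_csv
#' @export
read_optical_csv <- function(path, ...) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("wavelength_nm", "signal") %in% names(d)))
    stop("optical CSV must have columns wavelength_nm,signal")
  optical_spectrum(d$wavelength_nm, d$signal, ...)
}

#' @param spec an [optical_spectrum()].
#' @rdname read_topography_csv
#' @export
write_optical_csv <- function(spec, path) {
  utils::write.csv(data.frame(wavelength_nm = spec$wavelength_nm,
                              signal = spec$signal),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_topography_csv
#' @export
read_elemental_csv <- function(path) {
  gen_elemental(utils::read.csv(path, check.names = FALSE))
}

#' @param tab an `elemental_table`.
#' @rdname read_topography_csv
#' @export
write_elemental_csv <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a contact census as TSV
#'
#' One row per residue pair per frame with the minimum carbon-carbon
#' distance, contact flag and intramolecular/intermolecular scope.
#'
#' @param census a `contact_census`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contacts_tsv <- function(census, path) {
  stopifnot(inherits(census, "contact_census"))
  utils::write.table(census$records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write an analysis result as JSON
#'
#' Thin wrapper over [jsonlite::write_json()] with scalars unboxed and
#' full numeric precision.
#'
#' @param x a list (e.g. a fit summary).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
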