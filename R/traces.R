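#' Concentration trace
#'
#' A time series of the molar concentration of one chemical species, the
#' common currency between the spectroscopic conversion step and kinetic
#' fitting. Concentrations are stored in mol L^-1 throughout the package.
#'
#' @param times Numeric vector of sampling times in seconds, strictly
#'   increasing.
#' @param concentration Numeric vector of molar concentrations (mol L^-1),
#'   same length as `times`, all non-negative.
#' @param species Species label, typically `"amine"` or `"imine"`.
#' @param x0 Initial concentration of the limiting reactant (mol L^-1).
#'   Required before kinetic fitting; may be `NA` for raw imine traces.
#' @param time_offset Dead time in seconds added to all times (for
#'   acquisitions that start a known delay after mixing). Default 0.
#' @param metadata Named list of free-form labels (sample id, solvent,
#'   temperature, ...).
#'
#' @return An object of class `conc_trace`: a data frame with columns
#'   `time_s` and `concentration_M` plus attributes `species`, `x0` and
#'   `metadata`.
#' @export
#' @examples
#' tr <- concentration_trace(seq(0, 100, 10), rep(5e-4, 11),
#'                           species = "amine", x0 = 5e-4)
#' head(tr)
concentration_trace <- function(times, concentration,
                                species = c("amine", "imine"),
                                x0 = NA_real_, time_offset = 0,
                                metadata = list()) {
  species <- match.arg(species)
  times <- as.numeric(times) + time_offset
  concentration <- as.numeric(concentration)
  if (length(times) != length(concentration))
    stop("`times` and `concentration` must have the same length")
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  if (any(!is.finite(concentration)) || any(concentration < -1e-15))
    stop("concentrations must be finite and non-negative")
  concentration[concentration < 0] <- 0
  if (!is.na(x0) && x0 <= 0)
    stop("`x0` must be positive")
  out <- data.frame(time_s = times, concentration_M = concentration)
  structure(out,
            species = species, x0 = x0, metadata = metadata,
            class = c("conc_trace", "data.frame"))
}

#' @export
print.conc_trace <- function(x, ...) {
  cat(sprintf("<conc_trace> species = %s, n = %d, x0 = %s M\n",
              attr(x, "species"), nrow(x),
              format(attr(x, "x0"), digits = 4)))
  print.data.frame(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}

#' Read / write a concentration trace from CSV
#'
#' The on-disk format is a CSV with a `time_s` column and one concentration
#' column named `concentration_M`, `concentration_mM` or `concentration_uM`;
#' the unit suffix is honoured and values are converted to mol L^-1.
#'
#' @param path File path.
#' @param species,x0 Passed to [concentration_trace()].
#' @return `read_concentration_trace()` returns a `conc_trace`;
#'   `write_concentration_trace()` returns `path` invisibly.
#' @export
read_concentration_trace <- function(path, species = "amine", x0 = NA_real_) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df))
    stop("CSV must contain a `time_s` column: ", path)
  unit_cols <- c(concentration_M = 1, concentration_mM = 1e-3,
                 concentration_uM = 1e-6)
  hit <- intersect(names(unit_cols), names(df))
  if (length(hit) != 1L)
    stop("CSV must contain exactly one of: ",
         paste(names(unit_cols), collapse = ", "))
  concentration_trace(df$time_s, df[[hit]] * unit_cols[[hit]],
                      species = species, x0 = x0)
}

#' @rdname read_concentration_trace
#' @param trace A `conc_trace` object.
#' @export
write_concentration_trace <- function(trace, path) {
  df <- data.frame(time_s = trace$time_s,
                   concentration_M = trace$concentration_M)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Spectral series
#'
#' Raw UV-Vis acquisition: an absorbance matrix over a wavelength grid and a
#' time grid, as produced by a scanning spectrophotometer sampling the full
#' spectrum at fixed intervals after mixing.
#'
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param times Strictly increasing acquisition times (s since mixing).
#' @param absorbance Matrix of absorbance values (a.u.), `length(times)` rows
#'   by `length(wavelengths)` columns.
#' @param path_length Optical path length in cm, > 0.
#' @param metadata Named list of free-form labels.
#' @return An object of class `spectral_series`.
#' @export
spectral_series <- function(wavelengths, times, absorbance,
                            path_length = 1, metadata = list()) {
  wavelengths <- as.numeric(wavelengths)
  times <- as.numeric(times)
  absorbance <- as.matrix(absorbance)
  if (any(diff(wavelengths) <= 0)) stop("`wavelengths` must be strictly increasing")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (!identical(dim(absorbance), c(length(times), length(wavelengths))))
    stop("`absorbance` must be a [time x wavelength] matrix matching the grids")
  if (!is.finite(path_length) || path_length <= 0)
    stop("`path_length` must be positive")
  structure(list(wavelengths = wavelengths, times = times,
                 absorbance = absorbance, path_length = path_length,
                 metadata = metadata),
            class = "spectral_series")
}

#' @export
print.spectral_series <- function(x, ...) {
  cat(sprintf(
    "<spectral_series> %d spectra x %d wavelengths (%.4g-%.4g nm), l = %g cm\n",
    length(x$times), length(x$wavelengths),
    min(x$wavelengths), max(x$wavelengths), x$path_length))
  invisible(x)
}

#' @rdname spectral_series
#' @param path File path. The CSV layout is one `time_s` column followed by
#'   one column per wavelength, named by the wavelength in nm.
#' @export
read_spectral_series <- function(path, path_length = 1, metadata = list()) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_s")
    stop("first CSV column must be `time_s`: ", path)
  wl <- as.numeric(names(df)[-1])
  if (any(is.na(wl)))
    stop("wavelength columns must be named by their wavelength in nm")
  spectral_series(wl, df$time_s, as.matrix(df[, -1, drop = FALSE]),
                  path_length = path_length, metadata = metadata)
}

#' @rdname spectral_series
#' @param series A `spectral_series` object.
#' @export
write_spectral_series <- function(series, path) {
  df <- data.frame(time_s = series$times, check.names = FALSE)
  ab <- as.data.frame(series$absorbance)
  names(ab) <- format(series$wavelengths, trim = TRUE, scientific = FALSE)
  utils::write.csv(cbind(df, ab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
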