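#' Background-correct a UV-Vis kinetic series at one detection wavelength
#'
#' Extracts the absorbance trace at the grid wavelength nearest to the
#' requested detection wavelength and subtracts the first spectrum, so the
#' trace reports the change in absorbance caused by imine formation on top
#' of the (static) reactant background. No interpolation between grid points
#' is performed; the wavelength actually used is reported.
#'
#' @param series A [spectral_series()].
#' @param detection_wavelength Requested detection wavelength (nm). Must lie
#'   within the acquired wavelength range.
#' @return A list with `times` (s), `absorbance` (background-corrected a.u.,
#'   zero at the first time point), `wavelength_used` (nm, the nearest grid
#'   point) and `path_length` (cm).
#' @export
#' @examples
#' s <- spectral_series(200:300, c(0, 30, 60),
#'                      matrix(0.1, 3, 101))
#' preprocess_uvvis(s, 240)$wavelength_used
preprocess_uvvis <- function(series, detection_wavelength) {
  stopifnot(inherits(series, "spectral_series"))
  wl <- series$wavelengths
  if (detection_wavelength < min(wl) || detection_wavelength > max(wl))
    stop(sprintf(
      "detection wavelength %g nm outside the acquired range [%g, %g] nm",
      detection_wavelength, min(wl), max(wl)))
  if (length(series$times) < 2L)
    stop("at least two spectra are required for background correction")
  j <- which.min(abs(wl - detection_wavelength))
  a <- series$absorbance[, j]
  list(times = series$times,
       absorbance = a - a[1L],
       wavelength_used = wl[j],
       path_length = series$path_length)
}

#' Calibrate molar absorptivity from paired concentration/absorbance points
#'
#' Ordinary least-squares fit of the Beer-Lambert law A = epsilon * c * l.
#' The slope of A against c*l is the molar absorptivity. The line is not
#' forced through the origin; the intercept is estimated and reported
#' separately, with a warning when it is significant (|intercept| more than
#' 3 times its standard error), which usually signals an uncorrected
#' background.
#'
#' @param concentration Molar concentrations (mol L^-1), at least two
#'   distinct values.
#' @param absorbance Absorbance readings (a.u.), same length.
#' @param path_length Optical path length in cm (default 1).
#' @return An object of class `absorptivity_calibration`: list with
#'   `epsilon` (L mol^-1 cm^-1), `intercept`, `intercept_se`, `fit_r2`,
#'   `detection_wavelength` (optional, NA unless supplied), `path_length`
#'   and the calibration points. `epsilon <= 0` is flagged via `valid`.
#' @param detection_wavelength Optional wavelength (nm) the calibration
#'   applies to, recorded for provenance.
#' @export
#' @examples
#' cal <- fit_molar_absorptivity(c(0, 1e-4, 2e-4, 5e-4),
#'                               c(0, 0.187, 0.374, 0.935))
#' cal$epsilon  # 1870
fit_molar_absorptivity <- function(concentration, absorbance,
                                   path_length = 1,
                                   detection_wavelength = NA_real_) {
  concentration <- as.numeric(concentration)
  absorbance <- as.numeric(absorbance)
  if (length(concentration) < 2L || length(absorbance) != length(concentration))
    stop("need >= 2 paired calibration points")
  if (any(concentration < 0)) stop("concentrations must be non-negative")
  if (stats::var(concentration) == 0)
    stop("degenerate calibration design: all concentrations equal")
  cl <- concentration * path_length
  fit <- stats::lm(absorbance ~ cl)
  # exact synthetic calibrations are legitimate; silence the perfect-fit note
  sm <- suppressWarnings(summary(fit))
  epsilon <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  intercept_se <- sm$coefficients[1L, 2L]
  if (is.finite(intercept_se) && intercept_se > 0 &&
      abs(intercept) > 3 * intercept_se)
    warning(sprintf(
      "calibration intercept %.3g is > 3x its standard error (%.3g); check background correction",
      intercept, intercept_se))
  r2 <- if (stats::var(absorbance) == 0) 1 else sm$r.squared
  structure(list(epsilon = epsilon,
                 intercept = intercept,
                 intercept_se = intercept_se,
                 fit_r2 = r2,
                 detection_wavelength = detection_wavelength,
                 path_length = path_length,
                 calibration_points = data.frame(
                   concentration_M = concentration,
                   absorbance = absorbance),
                 valid = is.finite(epsilon) && epsilon > 0),
            class = "absorptivity_calibration")
}

#' @export
print.absorptivity_calibration <- function(x, ...) {
  cat(sprintf(
    "<absorptivity_calibration> epsilon = %.4g L mol^-1 cm^-1 (r2 = %.4f)%s\n",
    x$epsilon, x$fit_r2, if (x$valid) "" else " [INVALID]"))
  invisible(x)
}

#' Convert a background-corrected absorbance trace to an imine concentration
#' trace
#'
#' Inverts the Beer-Lambert law, c(t) = A(t) / (epsilon * l). Small negative
#' values arising from instrument noise are clipped to zero; the number of
#' clipped points is recorded in the trace metadata as `n_clipped`.
#'
#' @param trace A list with `times` and `absorbance` (as returned by
#'   [preprocess_uvvis()]), or a numeric absorbance vector together with
#'   `times`.
#' @param calibration An [fit_molar_absorptivity()] result, or a single
#'   positive number taken as epsilon directly.
#' @param times Sampling times, only needed when `trace` is a bare numeric
#'   vector.
#' @param path_length Path length in cm; defaults to the value carried by
#'   `trace`/`calibration`, else 1.
#' @return A `conc_trace` with `species = "imine"`.
#' @export
absorbance_to_concentration <- function(trace, calibration, times = NULL,
                                        path_length = NULL) {
  if (is.numeric(trace)) {
    if (is.null(times)) stop("`times` required for a bare absorbance vector")
    trace <- list(times = times, absorbance = trace)
  }
  if (inherits(calibration, "absorptivity_calibration")) {
    epsilon <- calibration$epsilon
    if (is.null(path_length)) path_length <- calibration$path_length
  } else {
    epsilon <- as.numeric(calibration)
  }
  if (is.null(path_length)) path_length <- trace$path_length %||% 1
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("molar absorptivity must be positive for Beer-Lambert inversion")
  conc <- trace$absorbance / (epsilon * path_length)
  n_clipped <- sum(conc < 0)
  conc[conc < 0] <- 0
  concentration_trace(trace$times, conc, species = "imine",
                      metadata = list(n_clipped = n_clipped,
                                      epsilon = epsilon,
                                      path_length = path_length))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Amine consumption trace from a measured imine trace
#'
#' The kinetic model fits the disappearance of the amine; the measured
#' quantity is the imine. Under equimolar 1:1 stoichiometry the remaining
#' amine is x(t) = x0 - [Im](t), clipped to [0, x0].
#'
#' @param imine A `conc_trace` with species `"imine"`.
#' @param x0 Known initial amine concentration (mol L^-1), > 0.
#' @param tolerance Relative tolerance on [Im] exceeding `x0` before a
#'   warning is raised (default 0.02); offending points are clipped either
#'   way.
#' @return A `conc_trace` with species `"amine"` and `x0` recorded.
#' @export
#' @examples
#' im <- concentration_trace(c(0, 60, 120), c(0, 1e-4, 1.4e-4),
#'                           species = "imine")
#' amine_consumption_trace(im, x0 = 5e-4)
amine_consumption_trace <- function(imine, x0, tolerance = 0.02) {
  stopifnot(inherits(imine, "conc_trace"))
  if (!is.finite(x0) || x0 <= 0) stop("`x0` must be positive")
  im <- imine$concentration_M
  over <- im > x0 * (1 + tolerance)
  if (any(over))
    warning(sprintf(
      "%d imine point(s) exceed x0 by more than %.1f%%; clipped",
      sum(over), 100 * tolerance))
  x <- pmin(pmax(x0 - im, 0), x0)
  concentration_trace(imine$time_s, x, species = "amine", x0 = x0,
                      metadata = c(attr(imine, "metadata"),
                                   list(n_over_x0 = sum(over))))
}

#' Serial-dilution bookkeeping for a Schiff-test standard series
#'
#' Computes the final concentration of each standard after a sequence of
#' dilution steps, each defined by an aliquot volume taken forward and the
#' total volume after dilution. Each final concentration is
#' stock * prod(aliquot / total).
#'
#' @param stock_concentrations Stock concentrations (mol L^-1), one per
#'   standard.
#' @param steps A data frame (or list coercible to one) with columns
#'   `aliquot` and `total`: the volume carried into each step and the total
#'   volume after that step (any single consistent volume unit). An empty
#'   data frame means no dilution.
#' @return Final concentrations (mol L^-1), same length as
#'   `stock_concentrations`.
#' @export
#' @examples
#' # 500 uL sample + 2500 uL reagent, then 100 uL diluted to 1000 uL:
#' schiff_standard_concentrations(
#'   c(20e-3, 10e-3, 5e-3, 2e-3, 0.5e-3),
#'   data.frame(aliquot = c(500, 100), total = c(3000, 1000)))
schiff_standard_concentrations <- function(stock_concentrations, steps) {
  steps <- as.data.frame(steps)
  if (nrow(steps) == 0L) return(as.numeric(stock_concentrations))
  if (!all(c("aliquot", "total") %in% names(steps)))
    stop("`steps` needs `aliquot` and `total` columns")
  if (any(steps$aliquot <= 0) || any(steps$total <= 0))
    stop("volumes must be positive")
  if (any(steps$aliquot > steps$total))
    stop("aliquot volume exceeds the total volume after dilution")
  factor <- prod(steps$aliquot / steps$total)
  as.numeric(stock_concentrations) * factor
}

#' Degree of oxidation from a measured aldehyde concentration
#'
#' For periodate-oxidized polysaccharides each oxidized uronic-acid unit
#' carries two aldehyde functions, so the fraction of oxidized units is
#' DOx = [CHO] / (2 [unit]).
#'
#' @param measured_aldehyde Aldehyde-function concentration (mol L^-1).
#' @param uronic_unit_concentration Total uronic-unit concentration
#'   (mol L^-1).
#' @return DOx as a fraction in [0, 1].
#' @export
#' @examples
#' degree_of_oxidation(10.1e-3, 50.5e-3)  # 0.10
degree_of_oxidation <- function(measured_aldehyde, uronic_unit_concentration) {
  if (measured_aldehyde < 0 || uronic_unit_concentration <= 0)
    stop("concentrations must be non-negative ([unit] > 0)")
  dox <- measured_aldehyde / (2 * uronic_unit_concentration)
  if (dox > 1 + 1e-12)
    stop(sprintf(
      "inconsistent inputs: DOx = %.3g > 1 (more aldehydes than 2 per unit)",
      dox))
  min(dox, 1)
}

#' Reactive aldehyde concentration of a macromer solution
#'
#' For a functionalized macromer dissolved at mass `m` in volume `V`, with
#' average monomer molecular weight `M_unit` and a fraction `D_f` of units
#' carrying an aldehyde, the reactive aldehyde concentration is
#' c = m / (M_unit * V) * D_f, i.e. one reactive aldehyde equivalent per
#' functionalized unit. (This one-per-unit convention is distinct from the
#' two-aldehydes-per-oxidized-unit counting used by the Schiff-test DOx; see
#' [degree_of_oxidation()].)
#'
#' @param mass Macromer mass (g).
#' @param volume Solution volume (L).
#' @param degree_of_functionalization Fraction of monomer units carrying an
#'   aldehyde, in (0, 1].
#' @param unit_molar_mass Average monomer molecular weight (g mol^-1).
#'   Default 198, the effective value for 2 wt% oxidized alginate at
#'   DOx = 10% giving 10.1 mM.
#' @return Aldehyde concentration (mol L^-1).
#' @export
#' @examples
#' macromer_aldehyde_concentration(0.02, 0.001, 0.10)  # 10.1 mM
macromer_aldehyde_concentration <- function(mass, volume,
                                            degree_of_functionalization,
                                            unit_molar_mass = 198) {
  if (mass < 0 || volume <= 0 || unit_molar_mass <= 0)
    stop("mass, volume and unit molar mass must be positive")
  if (degree_of_functionalization < 0 || degree_of_functionalization > 1)
    stop("`degree_of_functionalization` must be a fraction in [0, 1]")
  mass / (unit_molar_mass * volume) * degree_of_functionalization
}

#' Cross-linker molecule concentration for a target amine ratio
#'
#' Formulation bookkeeping for multifunctional cross-linkers: to dose
#' `chi_am` equivalents of amine functions against an aldehyde pool of
#' concentration `ald0`, the required concentration of the cross-linker
#' molecule is chi_am * ald0 / functionality (a homobifunctional
#' cross-linker carries two amine functions, so half the molar amount).
#'
#' @param chi_am Target amine-function ratio relative to aldehyde
#'   functions.
#' @param ald0 Aldehyde-function concentration (mol L^-1).
#' @param functionality Amine functions per cross-linker molecule
#'   (default 2).
#' @return Cross-linker molecule concentration (mol L^-1).
#' @export
#' @examples
#' crosslinker_concentration(0.5, 10e-3)  # 2.5 mM
crosslinker_concentration <- function(chi_am, ald0, functionality = 2) {
  if (chi_am < 0 || ald0 <= 0 || functionality < 1)
    stop("invalid formulation inputs")
  chi_am * ald0 / functionality
}
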