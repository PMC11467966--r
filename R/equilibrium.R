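#' Single-ligand binding equilibrium
#'
#' Equilibrium imine concentration for one aldehyde and one amine mixed at
#' initial concentrations `ald0` and `am0` with association constant `Keq`
#' (L mol^-1). `[Im]` is the smaller root of
#' x^2 - (ald0 + am0 + 1/Keq) x + ald0 * am0 = 0, computed in the
#' numerically stable product form so that near-saturating `Keq` does not
#' lose precision.
#'
#' @param ald0 Initial aldehyde-function concentration (mol L^-1), > 0.
#' @param am0 Initial amine-function concentration (mol L^-1), >= 0.
#' @param Keq Association equilibrium constant (L mol^-1), >= 0. `Keq = 0`
#'   (or `am0 = 0`) gives no imine; `Keq = Inf` gives `min(ald0, am0)`.
#' @return Equilibrium imine concentration in [0, min(ald0, am0)].
#'   Vectorized over all arguments.
#' @export
#' @examples
#' single_ligand_equilibrium(10.1e-3, 10.1e-3, 1e4)  # ~9.144e-3
single_ligand_equilibrium <- function(ald0, am0, Keq) {
  if (any(ald0 <= 0)) stop("`ald0` must be positive")
  if (any(am0 < 0) || any(Keq < 0)) stop("`am0` and `Keq` must be non-negative")
  n <- max(length(ald0), length(am0), length(Keq))
  ald0 <- rep_len(ald0, n); am0 <- rep_len(am0, n); Keq <- rep_len(Keq, n)
  im <- numeric(n)
  pos <- Keq > 0 & am0 > 0
  inf <- pos & !is.finite(Keq)
  im[inf] <- pmin(ald0[inf], am0[inf])
  i <- pos & !inf
  b <- ald0[i] + am0[i] + 1 / Keq[i]
  # smaller root via 2c / (b + sqrt(b^2 - 4c)): stable when roots are close
  disc <- pmax(b^2 - 4 * ald0[i] * am0[i], 0)
  im[i] <- 2 * ald0[i] * am0[i] / (b + sqrt(disc))
  im
}

#' Ideal maximum fraction of cross-linked aldehydes
#'
#' For a bifunctional amine cross-linker, an aldehyde contributes an
#' elastically relevant cross-link only when it is bound to an amine arm
#' whose sibling arm is also bound. Treating arm occupancies as
#' independent, the cross-linked fraction of aldehydes is the product of
#' the aldehyde-bound and amine-bound fractions,
#' \deqn{\chi_{XL}^{Ald} = \frac{[Im]}{[Ald]_0} \cdot \frac{[Im]}{[Am]_0},}
#' with `[Im]` from [single_ligand_equilibrium()].
#'
#' @param ald0 Initial aldehyde-function concentration (mol L^-1).
#' @param chi_am Amine-function ratio [Am]0/[Ald]0, >= 0.
#' @param Keq Association constant (L mol^-1).
#' @return Cross-linked aldehyde fraction in [0, 1]; 0 when `chi_am = 0`.
#'   Vectorized.
#' @export
#' @examples
#' crosslinked_fraction(10.1e-3, 1, 1e4)  # ~0.82
#' crosslinked_fraction(10.1e-3, 1, 1e2)  # ~0.15
crosslinked_fraction <- function(ald0, chi_am, Keq) {
  if (any(chi_am < 0)) stop("`chi_am` must be non-negative")
  n <- max(length(ald0), length(chi_am), length(Keq))
  ald0 <- rep_len(ald0, n); chi_am <- rep_len(chi_am, n)
  Keq <- rep_len(Keq, n)
  out <- numeric(n)
  i <- chi_am > 0
  am0 <- ald0[i] * chi_am[i]
  im <- single_ligand_equilibrium(ald0[i], am0, Keq[i])
  out[i] <- (im / ald0[i]) * (im / am0)
  out
}

#' Cross-linked fraction versus amine ratio, at fixed Keq
#'
#' Evaluates [crosslinked_fraction()] over a grid of amine ratios,
#' producing the characteristic curve that rises towards stoichiometry and
#' - for strong binders - drops sharply beyond it as cross-links are
#' replaced by singly bound pendant amines (saturation softening).
#'
#' @param Keq Association constant (L mol^-1), scalar.
#' @param ald0 Initial aldehyde concentration (mol L^-1). Default 10.1 mM,
#'   a 2 wt% oxidized-alginate formulation.
#' @param chi_grid Amine-ratio grid, within [0, 2]. Default 0 to 1.4.
#' @return A `crosslink_surface` (1-D): data frame with `chi_am` and
#'   `chi_xl`, with `Keq` and `ald0` as attributes.
#' @export
fraction_vs_ratio_curve <- function(Keq, ald0 = 10.1e-3,
                                    chi_grid = seq(0, 1.4, length.out = 141)) {
  if (any(chi_grid < 0) || any(chi_grid > 2))
    stop("`chi_grid` must lie within [0, 2]")
  out <- data.frame(chi_am = chi_grid,
                    chi_xl = crosslinked_fraction(ald0, chi_grid, Keq))
  structure(out, Keq = Keq, ald0 = ald0,
            class = c("crosslink_surface", "data.frame"))
}

#' Equilibrium bound fraction of reactive groups
#'
#' The bound fraction [Im]/[X]0 at equilibrium for equimolar reactive
#' partners ([X]0 = [Am]0 = [Ald]0), as a function of Keq and/or of the
#' concentration regime. Under the analytic model this is the equimolar
#' single-ligand solution; the curve keeps its shape in log10(Keq) and only
#' shifts along the Keq axis when `x0` changes (the product Keq * x0 sets
#' the bound fraction). Alternative isotherm expressions can be registered
#' via [register_isotherm_model()] and selected by name.
#'
#' @param Keq Association constant(s) (L mol^-1).
#' @param x0 Equimolar reactive-group concentration(s) (mol L^-1), > 0.
#'   Vectorized jointly with `Keq` (recycled).
#' @param model Name of a registered isotherm model; `"analytic"` is built
#'   in.
#' @return Bound fraction(s) in [0, 1].
#' @export
#' @examples
#' bound_fraction_isotherm(1e4, 10.1e-3)           # ~0.905
#' bound_fraction_isotherm(10^seq(1, 7, 0.5))       # sweep over Keq
bound_fraction_isotherm <- function(Keq, x0 = 10.1e-3, model = "analytic") {
  if (any(x0 <= 0)) stop("`x0` must be positive")
  fn <- .isotherm_registry[[model]]
  if (is.null(fn))
    stop("unknown isotherm model '", model, "'; registered models: ",
         paste(names(.isotherm_registry), collapse = ", "))
  fn(Keq = Keq, x0 = x0)
}

.isotherm_registry <- new.env(parent = emptyenv())
.isotherm_registry$analytic <- function(Keq, x0)
  single_ligand_equilibrium(rep_len(x0, max(length(Keq), length(x0))),
                            x0, Keq) / x0

#' Register an alternative binding-isotherm model
#'
#' Plug-in point for other treatments of the equilibrium bound fraction
#' (e.g. force-sensitive or distribution-based expressions from transient
#' network theories). The registered function must accept `Keq` and `x0`
#' and return the bound fraction.
#'
#' @param name Model name.
#' @param fn Function of (`Keq`, `x0`) returning [Im]/[X]0.
#' @return `name`, invisibly.
#' @export
register_isotherm_model <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  .isotherm_registry[[name]] <- fn
  invisible(name)
}

#' @rdname register_isotherm_model
#' @export
isotherm_models <- function() ls(.isotherm_registry)

#' Correlate a thermodynamic descriptor with log-transformed rate or
#' equilibrium constants
#'
#' Ordinary least squares of log10(REC) against a dimensionless free-energy
#' descriptor (e.g. a reaction or activation free energy divided by RT),
#' paired by amine identity. Used to ask whether computed energies predict
#' measured reactivity.
#'
#' @param descriptor Named numeric vector (names = amine ids).
#' @param rec Named numeric vector of rate or equilibrium constants, same
#'   ids (order-free); values must be positive (they are log10-transformed
#'   here).
#' @return List with `slope`, `intercept`, `r_squared`, `n` and the fitted
#'   `lm` object.
#' @export
correlate_descriptor_vs_log_rec <- function(descriptor, rec) {
  if (is.null(names(descriptor)) || is.null(names(rec)))
    stop("both vectors must be named by amine identity")
  ids <- intersect(names(descriptor), names(rec))
  if (length(ids) < 3L)
    stop("need >= 3 amines common to both vectors; got ", length(ids))
  if (length(ids) < length(descriptor) || length(ids) < length(rec))
    if (!setequal(names(descriptor), names(rec)))
      warning("identities not fully matched; using the ",
              length(ids), " common amines")
  x <- descriptor[ids]
  y <- log10(rec[ids])
  if (any(!is.finite(y))) stop("rate constants must be positive and finite")
  fit <- stats::lm(y ~ x)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r_squared = suppressWarnings(summary(fit))$r.squared,
       n = length(ids), fit = fit)
}
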