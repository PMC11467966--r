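#' Network model specification
#'
#' Classical rubber-elasticity relations between the shear storage modulus
#' and the concentration of elastically active chain segments ve:
#' affine, G' = ve R T (all junctions displace with the bulk), and phantom,
#' G' = (1 - 2/f) ve R T, where the junction-fluctuation correction depends
#' on the junction functionality f. As f grows the phantom prediction
#' converges to the affine one.
#'
#' @param kind `"affine"` or `"phantom"`.
#' @param f Junction functionality (arms per junction); required >= 3 for
#'   the phantom model, ignored for affine.
#' @param temperature Absolute temperature (K). Default 293.15 K (20 C).
#' @return A `network_model` list.
#' @export
network_model <- function(kind = c("affine", "phantom"), f = NULL,
                          temperature = 293.15) {
  kind <- match.arg(kind)
  if (temperature <= 0) stop("`temperature` must be positive (K)")
  if (kind == "phantom") {
    if (is.null(f) || f < 3)
      stop("phantom model requires junction functionality f >= 3")
  }
  structure(list(kind = kind, f = f, temperature = temperature),
            class = "network_model")
}

model_prefactor <- function(model) {
  if (model$kind == "affine") 1 else 1 - 2 / model$f
}

#' Elastically active chain concentration from the shear storage modulus
#'
#' Inverts the affine (G' = ve R T) or phantom (G' = (1 - 2/f) ve R T)
#' relation. With G' in Pa and R T in J mol^-1, ve comes out in mol m^-3
#' and is converted to mol L^-1.
#'
#' @param G_prime Shear storage modulus (Pa), >= 0.
#' @param model A [network_model()]; defaults to affine at 293.15 K.
#' @return ve in mol L^-1.
#' @export
#' @examples
#' ve_from_modulus(2200)  # ~9.0e-4 M (0.90 mM)
ve_from_modulus <- function(G_prime, model = network_model()) {
  if (any(G_prime < 0)) stop("`G_prime` must be non-negative")
  stopifnot(inherits(model, "network_model"))
  ve_m3 <- G_prime / (model_prefactor(model) * .R_GAS * model$temperature)
  ve_m3 / 1000  # mol m^-3 -> mol L^-1
}

#' Shear storage modulus from the elastically active chain concentration
#'
#' Exact algebraic inverse of [ve_from_modulus()].
#'
#' @param ve Elastically active chain concentration (mol L^-1), >= 0.
#' @inheritParams ve_from_modulus
#' @return G' in Pa.
#' @export
#' @examples
#' modulus_from_ve(ve_from_modulus(2200))  # 2200
modulus_from_ve <- function(ve, model = network_model()) {
  if (any(ve < 0)) stop("`ve` must be non-negative")
  stopifnot(inherits(model, "network_model"))
  ve * 1000 * model_prefactor(model) * .R_GAS * model$temperature
}

#' Predicted shear-modulus series for a formulation titration
#'
#' Given a series of competitive formulations (e.g. a fixed dose of one
#' cross-linker with increasing amounts of a second), predicts the shear
#' modulus of each relative to the first, under the proportionality of G'
#' to the cross-linked fraction: G'_i = anchor_G * chi_i / chi_1. The
#' alternative `"per_amine_index"` mode scales instead with the per-amine
#' squared-bound-fraction index (see [per_amine_crosslink_index()]); the
#' two modes bracket how strictly "cross-link" is counted and neither is
#' claimed exact.
#'
#' @param series A list of [competitive_equilibrium()] states, ordered;
#'   the first is the anchor formulation.
#' @param anchor_G Measured (or assumed) G' of the first formulation (Pa),
#'   > 0.
#' @param mode `"total_fraction"` (default) or `"per_amine_index"`.
#' @return Data frame with `chi_total` (or `index`), and `G_predicted_Pa`.
#' @export
relative_softening_prediction <- function(series, anchor_G,
                                          mode = c("total_fraction",
                                                   "per_amine_index")) {
  mode <- match.arg(mode)
  if (!length(series)) stop("`series` must be non-empty")
  if (!all(vapply(series, inherits, TRUE, "competitive_state")))
    stop("`series` must be a list of competitive_state objects")
  if (anchor_G <= 0) stop("`anchor_G` must be positive")
  metric <- vapply(series, function(st) {
    if (mode == "total_fraction") total_crosslinked_fraction(st)
    else per_amine_crosslink_index(
      c(st$im1, st$im2), c(st$a1_0, st$a2_0))
  }, 0)
  if (metric[1L] <= 0)
    stop("anchor formulation has zero cross-linked fraction")
  data.frame(chi_metric = metric,
             G_predicted_Pa = anchor_G * metric / metric[1L])
}
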