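#' Packaged DFT reactivity descriptors for the amine series
#'
#' Computed thermodynamic descriptors of imine formation between each
#' amine nucleophile (hydroxylamines, hydrazides, semicarbazides, ...) and
#' a model aldehyde: nucleophilicity index, natural charge on the reacting
#' nitrogen, and Gibbs free energies for formation (dG1*) and breakdown
#' (dG2*) of the tetrahedral intermediate and for the overall reaction
#' (drG). Shipped as a read-only table; free energies are additionally
#' returned rendered dimensionless by division with RT at 298.15 K, the
#' form used for correlation against log-transformed rate constants.
#'
#' @return Data frame keyed by `amine` with kcal mol^-1 columns and their
#'   `_over_RT` counterparts.
#' @seealso [correlate_descriptor_vs_log_rec()]
#' @export
dft_descriptors <- function() {
  df <- utils::read.delim(
    system.file("extdata", "dft_descriptors.tsv", package = "dynimine"),
    stringsAsFactors = FALSE)
  rt <- .R_GAS * .T_DFT
  for (col in c("dG1", "dG2", "drG"))
    df[[paste0(col, "_over_RT")]] <- df[[paste0(col, "_kcal_mol")]] *
      .KCAL_J / rt
  df$amine <- as.character(df$amine)
  df
}

#' Packaged rate-and-equilibrium-constant tables
#'
#' Measured rate and equilibrium constants of dynamic imine formation for
#' combinations of three aldehyde backbones (1: small molecule, 2:
#' oxidized alginate, 3: synthetic copolymer with pendant aldehydes) and
#' amine nucleophiles 4-9, determined by UV-Vis kinetics in PBS at 20 C
#' (`source = "uvvis"`), plus the UV-Vis/NMR method-comparison subset
#' (`source = "method_comparison"`). Values are stored as printed (scaled
#' units) and returned converted to base SI-like units: `k1` in
#' L mol^-1 s^-1, `k_minus1` in s^-1, `Keq` in L mol^-1, with matching
#' `*_u` uncertainty columns, the fitting pathway and the aggregation
#' convention for each row.
#'
#' @param source `"uvvis"` (the full screen) or `"method_comparison"`.
#' @return Data frame of constants in base units.
#' @export
#' @examples
#' recs <- rec_table()
#' subset(recs, aldehyde == 2 & amine == 5)
rec_table <- function(source = c("uvvis", "method_comparison")) {
  source <- match.arg(source)
  file <- switch(source, uvvis = "rec_uvvis.tsv",
                 method_comparison = "rec_method_comparison.tsv")
  df <- utils::read.delim(
    system.file("extdata", file, package = "dynimine"),
    stringsAsFactors = FALSE, na.strings = "NA")
  df$k1 <- df$k1_1e2_L_mol_s * 1e-2
  df$k1_u <- df$k1_u_1e2 * 1e-2
  df$k_minus1 <- df$k_minus1_1e6_s * 1e-6
  df$k_minus1_u <- df$k_minus1_u_1e6 * 1e-6
  df$Keq <- df$Keq_1e3_L_mol * 1e3
  df$Keq_u <- df$Keq_u_1e3 * 1e3
  if ("amine" %in% names(df)) df$amine <- as.character(df$amine)
  if ("aldehyde" %in% names(df)) df$aldehyde <- as.character(df$aldehyde)
  df
}
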