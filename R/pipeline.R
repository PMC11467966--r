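#' Run the raw-series-to-rate-constants pipeline
#'
#' Composes the spectroscopic and kinetic stages in measurement order for a
#' batch of acquisitions: background-correct each spectral series at the
#' detection wavelength, invert Beer-Lambert with the supplied molar
#' absorptivity, form the amine consumption trace, fit the kinetic model,
#' and aggregate replicate fits per group into a rate-constant table.
#' Every per-trace decision (wavelength actually used, clipped points,
#' constrained-pathway triggers) is recorded in the returned log.
#'
#' @param config A list (or path to a JSON file) with fields:
#'   \describe{
#'     \item{traces}{data frame with columns `path` (spectral-series CSV),
#'       `x0` (initial amine concentration, mol L^-1), `epsilon`
#'       (L mol^-1 cm^-1) and `group` (replicate group label).}
#'     \item{detection_wavelength}{nm, default 240.}
#'     \item{model}{fitting pathway for [fit_kinetics()], default
#'       `"auto"`.}
#'     \item{offset}{offset handling for [fit_kinetics()], default
#'       `"free"`: background correction anchors each trace to its noisy
#'       first spectrum, which the free offset absorbs.}
#'     \item{aggregation}{replicate convention for
#'       [aggregate_replicates()], default `"per_replicate_mean"`.}
#'     \item{output_dir}{optional; when set, the REC table (TSV), per-fit
#'       JSON dumps and the resolved config are written there.}
#'   }
#' @return List with `rec_table` (one row per group), `fits` (list of
#'   [fit_kinetics()] results per group), `log` (character vector) and
#'   `config` (the resolved configuration).
#' @export
run_rec_pipeline <- function(config) {
  config <- resolve_config(config, list(detection_wavelength = 240,
                                        model = "auto", offset = "free",
                                        aggregation = "per_replicate_mean",
                                        output_dir = NULL))
  tr <- config$traces
  if (is.null(tr) || !all(c("path", "x0", "epsilon", "group") %in% names(tr)))
    stop("stage `config`: `traces` must have columns path, x0, epsilon, group")
  tr <- as.data.frame(tr)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  fits <- list()
  for (i in seq_len(nrow(tr))) {
    row <- tr[i, ]
    if (is.na(row$x0) || row$x0 <= 0)
      stop("stage `input`: missing or invalid x0 for trace ", row$path)
    series <- tryCatch(read_spectral_series(row$path),
                       error = function(e)
                         stop("stage `read`: ", row$path, ": ",
                              conditionMessage(e)))
    pre <- tryCatch(preprocess_uvvis(series, config$detection_wavelength),
                    error = function(e)
                      stop("stage `preprocess`: ", row$path, ": ",
                           conditionMessage(e)))
    note("%s: detection wavelength %g nm (requested %g)", row$path,
         pre$wavelength_used, config$detection_wavelength)
    im <- absorbance_to_concentration(pre, row$epsilon,
                                      path_length = series$path_length)
    ncl <- attr(im, "metadata")$n_clipped
    if (ncl > 0) note("%s: %d negative concentration(s) clipped",
                      row$path, ncl)
    am <- amine_consumption_trace(im, row$x0)
    fit <- tryCatch(fit_kinetics(am, model = config$model,
                                 offset = config$offset),
                    error = function(e)
                      stop("stage `fit`: ", row$path, ": ",
                           conditionMessage(e)))
    if (fit$method == "constrained_fit" && config$model == "auto")
      note("%s: constrained pathway engaged (k_minus1 poorly determined)",
           row$path)
    fits[[i]] <- fit
  }

  groups <- split(seq_len(nrow(tr)), tr$group)
  rec_rows <- lapply(names(groups), function(g) {
    agg <- aggregate_replicates(fits[groups[[g]]], mode = config$aggregation)
    data.frame(group = g, n_replicates = agg$n_replicates,
               k1 = agg$k1, k1_u = agg$k1_uncertainty,
               k_minus1 = agg$k_minus1, k_minus1_u = agg$k_minus1_uncertainty,
               Keq = agg$Keq, Keq_u = agg$Keq_uncertainty,
               method = agg$method, aggregation = agg$aggregation)
  })
  rec <- do.call(rbind, rec_rows)
  rownames(rec) <- NULL

  out <- list(rec_table = rec,
              fits = stats::setNames(lapply(groups, function(ii) fits[ii]),
                                     names(groups)),
              log = log, config = config)
  if (!is.null(config$output_dir)) write_rec_outputs(out, config)
  out
}

resolve_config <- function(config, defaults) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("stage `config`: config must be a list or JSON path")
  utils::modifyList(defaults, config)
}

write_rec_outputs <- function(out, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(out$rec_table,
                     file.path(config$output_dir, "rec_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  dump <- lapply(out$fits, function(fl) lapply(fl, function(f)
    list(k1 = coef(f)[["k1"]], k_minus1 = coef(f)[["k_minus1"]],
         Keq = f$Keq, method = f$method, converged = f$converged,
         sse = f$sse)))
  jsonlite::write_json(dump, file.path(config$output_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  prov <- c(list(package_version = as.character(
    utils::packageVersion("dynimine"))),
    config[setdiff(names(config), "traces")])
  jsonlite::write_json(prov,
                       file.path(config$output_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Run the equilibrium-to-mechanics prediction pipeline
#'
#' From a set of equilibrium constants (by default the packaged UV-Vis REC
#' table), computes the figure-level prediction artifacts: cross-linked
#' fraction versus amine ratio curves for a ladder of Keq values, the
#' competitive softening map with its maximal-softening location, the
#' equimolar bound-fraction isotherm, and (optionally) a predicted modulus
#' series for a titration schedule.
#'
#' @param config A list (or JSON path) with optional fields `ald0`
#'   (default 10.1e-3 M), `Keq_ladder` (default 10^(1:7)), `chi_grid`,
#'   `map_grid_points` (default 121), `titration` (a list with `Keq1`,
#'   `Keq2`, `chi1`, `chi2_schedule`, `anchor_G`), `output_dir`.
#' @return List with `fraction_curves` (long data frame), `softening`
#'   (a [softening_map()]), `isotherm` (data frame), and `titration`
#'   (predicted modulus data frame or NULL).
#' @export
run_prediction_pipeline <- function(config = list()) {
  config <- resolve_config(config, list(
    ald0 = 10.1e-3, Keq_ladder = 10^(1:7),
    chi_grid = seq(0, 1.4, length.out = 141),
    map_grid_points = 121, titration = NULL, output_dir = NULL))
  if (!length(config$Keq_ladder))
    stop("stage `config`: empty Keq ladder")

  curves <- do.call(rbind, lapply(config$Keq_ladder, function(K) {
    cv <- fraction_vs_ratio_curve(K, config$ald0, config$chi_grid)
    data.frame(Keq = K, chi_am = cv$chi_am, chi_xl = cv$chi_xl)
  }))

  g <- 10^seq(1, 7, length.out = config$map_grid_points)
  softening <- softening_map(g, g, ald0 = config$ald0)

  keq_iso <- 10^seq(0, 8, length.out = 161)
  isotherm <- data.frame(Keq = keq_iso,
                         bound_fraction = bound_fraction_isotherm(
                           keq_iso, config$ald0))

  titr <- NULL
  if (!is.null(config$titration)) {
    tc <- config$titration
    states <- lapply(tc$chi2_schedule, function(chi2)
      competitive_equilibrium(config$ald0, tc$chi1 * config$ald0,
                              chi2 * config$ald0, tc$Keq1, tc$Keq2))
    titr <- cbind(chi1 = tc$chi1, chi2 = tc$chi2_schedule,
                  relative_softening_prediction(states, tc$anchor_G))
  }

  out <- list(fraction_curves = curves, softening = softening,
              isotherm = isotherm, titration = titr, config = config)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, name)
      utils::write.csv(df, file.path(config$output_dir, name),
                       row.names = FALSE, quote = FALSE)
    w(curves, "fraction_vs_ratio.csv")
    w(isotherm, "bound_fraction_isotherm.csv")
    map_long <- expand.grid(Keq1 = softening$Keq1, Keq2 = softening$Keq2)
    map_long$delta_chi <- as.vector(softening$delta_chi)
    w(map_long, "softening_map.csv")
    jsonlite::write_json(softening$max_softening,
                         file.path(config$output_dir,
                                   "max_softening.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(titr)) w(titr, "predicted_moduli.csv")
  }
  out
}
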