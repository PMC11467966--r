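#' Aggregate replicate kinetic fits into one set of rate constants
#'
#' Replicate measurements of the same reaction are combined in one of three
#' conventions, and the convention always travels with the result, because
#' they give genuinely different Keq values:
#' \describe{
#'   \item{`"per_replicate_mean"` (default)}{each parameter is the mean
#'     across replicates with its standard deviation; Keq is the mean of the
#'     per-replicate ratios k1/k_minus1 (not the ratio of the means), with
#'     the SD of those ratios as uncertainty. With a single replicate the
#'     fit's own standard errors are reported instead.}
#'   \item{`"ratio_of_means"`}{Keq = mean(k1) / mean(k_minus1), uncertainty
#'     by first-order propagation of the parameter SDs. Note this can
#'     differ markedly from the mean of ratios when replicates scatter.}
#'   \item{`"global"`}{one simultaneous least-squares fit of (k1, k_minus1)
#'     across all replicate traces, with standard errors from the joint
#'     covariance. Requires all replicates to share `x0` unless
#'     `allow_mixed_x0 = TRUE`.}
#' }
#'
#' @param fits A list of [fit_kinetics()] results (length >= 1).
#' @param mode Aggregation convention, see Details.
#' @param allow_mixed_x0 Permit a global fit across traces with different
#'   initial concentrations (each trace keeps its own `x0` in the model).
#' @return An object of class `rate_constants`: list with `k1`, `k_minus1`,
#'   `Keq` and their uncertainties, `method` (fit pathway of the
#'   replicates), `aggregation` and `n_replicates`.
#' @export
#' @examples
#' tt <- seq(0, 7200, 30)
#' fits <- lapply(c(0.055, 0.061), function(k1) {
#'   x <- reversible_equimolar_solution(tt, k1, 5e-5, 5e-4)
#'   fit_kinetics(concentration_trace(tt, x, species = "amine", x0 = 5e-4))
#' })
#' aggregate_replicates(fits)
aggregate_replicates <- function(fits,
                                 mode = c("per_replicate_mean",
                                          "ratio_of_means", "global"),
                                 allow_mixed_x0 = FALSE) {
  mode <- match.arg(mode)
  if (!length(fits)) stop("need at least one fit")
  if (!all(vapply(fits, inherits, TRUE, "imine_fit")))
    stop("`fits` must be a list of imine_fit objects")
  k1s <- vapply(fits, function(f) coef(f)[["k1"]], 0)
  kms <- vapply(fits, function(f) coef(f)[["k_minus1"]], 0)
  method <- unique(vapply(fits, function(f) f$method, ""))
  method <- if (length(method) == 1L) method else "mixed"
  n <- length(fits)

  out <- switch(mode,
    per_replicate_mean = {
      ratios <- ifelse(kms > 0, k1s / kms, Inf)
      if (n == 1L) {
        list(k1 = k1s, k1_u = fits[[1L]]$se[["k1"]],
             km = kms, km_u = fits[[1L]]$se[["k_minus1"]],
             keq = ratios, keq_u = fits[[1L]]$Keq_se)
      } else {
        list(k1 = mean(k1s), k1_u = stats::sd(k1s),
             km = mean(kms), km_u = stats::sd(kms),
             keq = mean(ratios), keq_u = stats::sd(ratios))
      }
    },
    ratio_of_means = {
      m1 <- mean(k1s); mm <- mean(kms)
      s1 <- if (n > 1L) stats::sd(k1s) else fits[[1L]]$se[["k1"]]
      sm <- if (n > 1L) stats::sd(kms) else fits[[1L]]$se[["k_minus1"]]
      keq <- if (mm > 0) m1 / mm else Inf
      keq_u <- if (mm > 0 && all(is.finite(c(s1, sm))))
        sqrt((s1 / mm)^2 + (m1 * sm / mm^2)^2) else NA_real_
      list(k1 = m1, k1_u = s1, km = mm, km_u = sm,
           keq = keq, keq_u = keq_u)
    },
    global = global_fit(fits, allow_mixed_x0))

  structure(list(k1 = out$k1, k_minus1 = out$km, Keq = out$keq,
                 k1_uncertainty = out$k1_u,
                 k_minus1_uncertainty = out$km_u,
                 Keq_uncertainty = out$keq_u,
                 method = method, aggregation = mode, n_replicates = n),
            class = "rate_constants")
}

global_fit <- function(fits, allow_mixed_x0) {
  x0s <- vapply(fits, function(f) f$x0, 0)
  if (length(unique(x0s)) > 1L && !allow_mixed_x0)
    stop("replicates have different x0; set allow_mixed_x0 = TRUE to fit anyway")
  resid_fn <- function(p) {
    unlist(lapply(fits, function(f)
      reversible_equimolar_solution(f$times, p[1L], p[2L], f$x0) -
        f$trace$concentration_M))
  }
  p0 <- c(mean(vapply(fits, function(f) coef(f)[["k1"]], 0)),
          max(mean(vapply(fits, function(f) coef(f)[["k_minus1"]], 0)),
              1e-12))
  ctrl <- minpack.lm::nls.lm.control(maxfev = 10000, ptol = 1e-12,
                                     ftol = 1e-12)
  res <- run_lm(p0, lower = c(0, 0), resid_fn, ctrl,
                scales = list(c(1, 1), c(0.3, 3), c(3, 0.3)))
  if (is.null(res)) stop("global fit failed")
  sv <- lm_se_vcov(res)
  k <- c(k1 = res$par[1L], k_minus1 = res$par[2L])
  keq <- keq_from_fit(k, stats::setNames(sv$se, names(k)), sv$vc)
  list(k1 = k[["k1"]], k1_u = sv$se[1L],
       km = k[["k_minus1"]], km_u = sv$se[2L],
       keq = keq$value, keq_u = keq$se)
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf("Rate and equilibrium constants (%s, %s, n = %d)\n",
              x$method, x$aggregation, x$n_replicates))
  cat(sprintf("  k1       = %.4g +/- %.2g L mol^-1 s^-1\n",
              x$k1, x$k1_uncertainty))
  cat(sprintf("  k_minus1 = %.4g +/- %.2g s^-1\n",
              x$k_minus1, x$k_minus1_uncertainty))
  cat(sprintf("  Keq      = %.4g +/- %.2g L mol^-1\n",
              x$Keq, x$Keq_uncertainty))
  invisible(x)
}
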