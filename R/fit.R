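#' Fit the imine-formation kinetic model to an amine consumption trace
#'
#' The central estimator of the package. Fits the reversible equimolar
#' bimolecular second-order model (see
#' [reversible_equimolar_solution()]) to a measured amine concentration
#' trace by bounded nonlinear least squares, returning the forward and
#' reverse rate constants and the equilibrium constant Keq = k1 / k_minus1
#' with first-order propagated uncertainty.
#'
#' Three fitting pathways are available:
#' \describe{
#'   \item{`"reversible"`}{free two-parameter fit of (k1, k_minus1).}
#'   \item{`"irreversible"`}{one-parameter fit of x(t) = x0/(1 + k1 x0 t);
#'     appropriate when no hydrolysis is detectable over the observation
#'     window.}
#'   \item{`"constrained"`}{two-step fit for reactions whose reverse rate is
#'     too small to co-estimate: k1 is first determined from the
#'     irreversible model, then held fixed while k_minus1 alone is fitted
#'     in the reversible model. If k_minus1 collapses onto its lower bound
#'     the reaction is flagged as possibly irreversible.}
#'   \item{`"auto"` (default)}{runs the free reversible fit and falls back
#'     to the constrained pathway when the relative standard error of
#'     k_minus1 exceeds `constraint_trigger`.}
#' }
#'
#' Starting values default to a linearized irreversible estimate of k1 from
#' the first 10% of the trace and a detailed-balance estimate of k_minus1
#' from the final plateau; the optimizer is restarted from a small
#' deterministic grid of scaled starts and the best sum of squares kept.
#'
#' @param trace A `conc_trace` with species `"amine"` and `x0` set (see
#'   [concentration_trace()], [amine_consumption_trace()]). Equimolar
#'   amine/aldehyde conditions are assumed.
#' @param model Fitting pathway, see Details.
#' @param start Optional named numeric starting values (`k1`, `k_minus1`).
#' @param constraint_trigger Relative standard error of k_minus1 above which
#'   `"auto"` escalates to the constrained pathway (default 1, i.e. 100%).
#' @param offset `"fixed"` (default) pins the trace to x0 at t = 0, the
#'   strict two-parameter model. `"free"` adds a concentration offset as a
#'   nuisance parameter. Traces obtained by subtracting a noisy first
#'   spectrum are anchored to that spectrum's noise realization, a
#'   common-mode error the strict model cannot absorb; freeing the offset
#'   restores independent residuals and calibrated standard errors for
#'   such data.
#' @param max_evals Maximum residual evaluations per optimizer run.
#' @param ptol Parameter convergence tolerance.
#' @return An object of class `imine_fit` with `coef()`, `vcov()`,
#'   `predict()`, `fitted()`, `residuals()`, `plot()`, `simulate()`,
#'   `print()` and `summary()` methods. Key fields: `coefficients`
#'   (k1, k_minus1), `se`, `Keq`, `Keq_se`, `method`, `fixed`, `converged`,
#'   `possibly_irreversible`, `sse`.
#' @export
#' @examples
#' tt <- seq(0, 7200, 30)
#' x <- reversible_equimolar_solution(tt, 0.058, 5.2e-5, 5e-4)
#' tr <- concentration_trace(tt, x, species = "amine", x0 = 5e-4)
#' fit <- fit_kinetics(tr)
#' coef(fit)
fit_kinetics <- function(trace,
                         model = c("auto", "reversible", "irreversible",
                                   "constrained"),
                         start = NULL, constraint_trigger = 1,
                         offset = c("fixed", "free"),
                         max_evals = 10000, ptol = 1e-12) {
  model <- match.arg(model)
  use_offset <- match.arg(offset) == "free"
  stopifnot(inherits(trace, "conc_trace"))
  if (identical(attr(trace, "species"), "imine"))
    stop("fit expects an amine consumption trace; see amine_consumption_trace()")
  x0 <- attr(trace, "x0")
  if (is.na(x0) || x0 <= 0)
    stop("trace must carry a positive `x0` (initial amine concentration)")
  t <- trace$time_s - trace$time_s[1L]
  x <- trace$concentration_M
  n_min <- if (model == "constrained") 3L else 5L
  if (length(t) < n_min)
    stop(sprintf("at least %d points are required for fitting", n_min))

  # degenerate flat trace: nothing reacted
  if (max(x) - min(x) <= 1e-12 * x0) {
    return(new_imine_fit(
      trace = trace, t = t, k = c(k1 = 0, k_minus1 = 0),
      se = c(k1 = NA_real_, k_minus1 = NA_real_), vc = NULL,
      fixed = list(), model = model, method = "free_fit",
      converged = TRUE, degenerate = TRUE))
  }

  init <- default_start(t, x, x0)
  if (!is.null(start)) init[names(start)] <- start

  ctrl <- minpack.lm::nls.lm.control(maxfev = max_evals, ptol = ptol,
                                     ftol = ptol)

  out <- switch(model,
    irreversible = fit_irreversible_path(t, x, x0, init, ctrl, use_offset),
    constrained  = fit_constrained_path(t, x, x0, init, ctrl, use_offset),
    reversible   = fit_free_path(t, x, x0, init, ctrl, use_offset),
    auto = {
      free <- fit_free_path(t, x, x0, init, ctrl, use_offset)
      rel_se <- free$se[["k_minus1"]] / free$k[["k_minus1"]]
      if (!is.finite(rel_se) || rel_se > constraint_trigger)
        fit_constrained_path(t, x, x0, init, ctrl, use_offset)
      else free
    })

  new_imine_fit(trace = trace, t = t, k = out$k, se = out$se, vc = out$vc,
                fixed = out$fixed, model = model, method = out$method,
                converged = out$converged, degenerate = FALSE,
                possibly_irreversible = isTRUE(out$possibly_irreversible),
                offset = out$offset %||% 0,
                offset_se = out$offset_se %||% NA_real_)
}

# linearized starting values (internal)
default_start <- function(t, x, x0) {
  n <- length(t)
  i_head <- seq_len(max(3L, ceiling(0.1 * n)))
  xs <- pmax(x[i_head], 1e-3 * x0)
  y <- 1 / xs - 1 / x0
  k1 <- sum(y * t[i_head]) / max(sum(t[i_head]^2), .Machine$double.eps)
  if (!is.finite(k1) || k1 <= 0) k1 <- 1 / (x0 * max(t[n], 1))
  x_eq <- mean(x[seq.int(max(1L, n - max(3L, ceiling(0.05 * n)) + 1L), n)])
  x_eq <- min(max(x_eq, 1e-6 * x0), (1 - 1e-6) * x0)
  km <- k1 * x_eq^2 / (x0 - x_eq)
  c(k1 = k1, k_minus1 = max(km, 1e-12))
}

# run nls.lm over a deterministic grid of scaled starts; keep the best SSE
run_lm <- function(par0, lower, resid_fn, ctrl, scales) {
  best <- NULL
  for (s in scales) {
    p <- pmax(par0 * s, lower)
    res <- tryCatch(
      minpack.lm::nls.lm(par = p, lower = lower, fn = resid_fn,
                         control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  best
}

lm_se_vcov <- function(res, extra_df = 0L) {
  p <- length(res$par)
  n <- length(res$fvec)
  s2 <- res$deviance / max(n - p - extra_df, 1L)
  vc <- tryCatch(s2 * solve(res$hessian), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, p) else sqrt(pmax(diag(vc), 0))
  list(se = se, vc = vc, converged = res$info %in% 1:4)
}

# centre residuals to profile out a constant offset analytically; the
# projected Jacobian yields the correct covariance of the remaining
# parameters (Schur complement of the full problem)
profile_offset <- function(r) r - mean(r)

fit_free_path <- function(t, x, x0, init, ctrl, use_offset = FALSE) {
  model_fn <- function(p)
    reversible_equimolar_solution(t, p[1L], p[2L], x0) - x
  resid_fn <- if (use_offset) function(p) profile_offset(model_fn(p))
              else model_fn
  par0 <- unname(init[c("k1", "k_minus1")])
  scales <- list(c(1, 1), c(0.3, 3), c(3, 0.3))
  res <- run_lm(par0, lower = c(0, 0), resid_fn, ctrl, scales)
  if (is.null(res)) stop("reversible fit failed from all starting points")
  sv <- lm_se_vcov(res, extra_df = as.integer(use_offset))
  k <- c(k1 = res$par[1L], k_minus1 = res$par[2L])
  se <- stats::setNames(sv$se, names(k))
  if (!sv$converged)
    warning("reversible fit did not converge; parameters reported as-is")
  off <- if (use_offset) -mean(model_fn(res$par)) else 0
  off_se <- if (use_offset)
    sqrt(res$deviance / max(length(t) - 3L, 1L) / length(t)) else NA_real_
  list(k = k, se = se, vc = sv$vc, fixed = list(), method = "free_fit",
       converged = sv$converged, offset = off, offset_se = off_se)
}

fit_irreversible_path <- function(t, x, x0, init, ctrl,
                                  use_offset = FALSE) {
  model_fn <- function(p)
    irreversible_second_order_solution(t, p[1L], x0) - x
  resid_fn <- if (use_offset) function(p) profile_offset(model_fn(p))
              else model_fn
  res <- run_lm(init[["k1"]], lower = 0, resid_fn, ctrl,
                scales = list(1, 0.3, 3))
  if (is.null(res)) stop("irreversible fit failed from all starting points")
  sv <- lm_se_vcov(res, extra_df = as.integer(use_offset))
  k <- c(k1 = res$par[1L], k_minus1 = 0)
  se <- c(k1 = sv$se[1L], k_minus1 = NA_real_)
  off <- if (use_offset) -mean(model_fn(res$par)) else 0
  off_se <- if (use_offset)
    sqrt(res$deviance / max(length(t) - 2L, 1L) / length(t)) else NA_real_
  list(k = k, se = se, vc = NULL, fixed = list(),
       method = "irreversible_fit", converged = sv$converged,
       offset = off, offset_se = off_se)
}

fit_constrained_path <- function(t, x, x0, init, ctrl,
                                 use_offset = FALSE,
                                 irreversible_window = 0.15) {
  # step 1: irreversible k1 from the early-time window, where the reverse
  # flux is still negligible and the irreversible approximation is valid
  n <- length(t)
  i_w <- seq_len(min(n, max(5L, ceiling(irreversible_window * n))))
  step1 <- fit_irreversible_path(t[i_w], x[i_w], x0, init, ctrl,
                                 use_offset)
  k1_fix <- step1$k[["k1"]]
  model_fn <- function(p)
    reversible_equimolar_solution(t, k1_fix, p[1L], x0) - x
  resid_fn <- if (use_offset) function(p) profile_offset(model_fn(p))
              else model_fn
  km0 <- max(init[["k_minus1"]], 1e-12)
  res <- run_lm(km0, lower = 0, resid_fn, ctrl,
                scales = list(1, 0.1, 10))
  if (is.null(res)) stop("constrained k_minus1 fit failed")
  sv <- lm_se_vcov(res, extra_df = as.integer(use_offset))
  km <- res$par[1L]
  at_bound <- km <= 1e-14 || km <= 1e-10 * k1_fix * x0
  k <- c(k1 = k1_fix, k_minus1 = km)
  se <- c(k1 = step1$se[["k1"]], k_minus1 = sv$se[1L])
  off <- if (use_offset) -mean(model_fn(res$par)) else 0
  off_se <- if (use_offset)
    sqrt(res$deviance / max(n - 2L, 1L) / n) else NA_real_
  list(k = k, se = se, vc = NULL,
       fixed = list(k1 = k1_fix), method = "constrained_fit",
       converged = sv$converged && step1$converged,
       possibly_irreversible = at_bound,
       offset = off, offset_se = off_se)
}

new_imine_fit <- function(trace, t, k, se, vc, fixed, model, method,
                          converged, degenerate = FALSE,
                          possibly_irreversible = FALSE,
                          offset = 0, offset_se = NA_real_) {
  x0 <- attr(trace, "x0")
  fitted <- reversible_equimolar_solution(t, k[["k1"]], k[["k_minus1"]],
                                          x0) + offset
  resid <- trace$concentration_M - fitted
  keq <- keq_from_fit(k, se, vc)
  structure(list(coefficients = k, se = se, vcov = vc,
                 Keq = keq$value, Keq_se = keq$se,
                 offset = offset, offset_se = offset_se,
                 fixed = fixed, model = model, method = method,
                 converged = converged, degenerate = degenerate,
                 possibly_irreversible = possibly_irreversible,
                 x0 = x0, trace = trace, times = t,
                 fitted.values = fitted, residuals = resid,
                 sse = sum(resid^2), n = length(t)),
            class = "imine_fit")
}

# Keq = k1/k_minus1 with first-order uncertainty propagation
keq_from_fit <- function(k, se, vc) {
  k1 <- k[["k1"]]; km <- k[["k_minus1"]]
  if (km <= 0) return(list(value = Inf, se = NA_real_))
  keq <- k1 / km
  g <- c(1 / km, -k1 / km^2)
  v <- if (!is.null(vc) && all(is.finite(vc))) {
    drop(t(g) %*% vc %*% g)
  } else if (all(is.finite(se))) {
    sum(g^2 * se^2)
  } else NA_real_
  list(value = keq, se = if (is.finite(v)) sqrt(max(v, 0)) else NA_real_)
}

#' @export
coef.imine_fit <- function(object, ...) object$coefficients

#' @export
vcov.imine_fit <- function(object, ...) object$vcov

#' @export
fitted.imine_fit <- function(object, ...) object$fitted.values

#' @export
residuals.imine_fit <- function(object, ...) object$residuals

#' @export
deviance.imine_fit <- function(object, ...) object$sse

#' Predict amine concentration from a fitted kinetic model
#'
#' @param object An `imine_fit`.
#' @param newdata Optional list or data frame with a `times` (or `time_s`)
#'   component, seconds from the start of the reaction. Defaults to the
#'   fitted time grid.
#' @param ... Unused.
#' @return Predicted amine concentration (mol L^-1).
#' @export
predict.imine_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times
       else newdata$times %||% newdata$time_s
  if (is.null(t)) stop("`newdata` must contain `times` or `time_s`")
  k <- object$coefficients
  reversible_equimolar_solution(t, k[["k1"]], k[["k_minus1"]], object$x0) +
    object$offset
}

#' Simulate noisy replicate traces from a fitted kinetic model
#'
#' Draws Gaussian noise with the fit's residual standard deviation around
#' the fitted curve, on the original time grid, mimicking re-measurement of
#' the same reaction.
#'
#' @param object An `imine_fit`.
#' @param nsim Number of simulated traces.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` `conc_trace` objects.
#' @export
simulate.imine_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(object$sse / max(object$n - 2L, 1L))
  lapply(seq_len(nsim), function(i) {
    y <- pmin(pmax(object$fitted.values + stats::rnorm(object$n, 0, sigma),
                   0), object$x0)
    concentration_trace(object$times, y, species = "amine", x0 = object$x0)
  })
}

#' @export
print.imine_fit <- function(x, ...) {
  cat(sprintf("Imine formation kinetics (%s)\n", x$method))
  cat(sprintf("  k1      = %.4g +/- %.2g L mol^-1 s^-1%s\n",
              x$coefficients[["k1"]], x$se[["k1"]],
              if (length(x$fixed)) " [fixed in step 2]" else ""))
  cat(sprintf("  k_minus1 = %.4g +/- %.2g s^-1\n",
              x$coefficients[["k_minus1"]], x$se[["k_minus1"]]))
  cat(sprintf("  Keq     = %.4g +/- %.2g L mol^-1\n", x$Keq, x$Keq_se))
  if (x$offset != 0)
    cat(sprintf("  offset  = %.3g +/- %.2g M (nuisance)\n",
                x$offset, x$offset_se))
  if (!x$converged) cat("  ! fit did not converge\n")
  if (x$degenerate) cat("  ! degenerate (flat) trace: no reaction observed\n")
  if (x$possibly_irreversible)
    cat("  ! k_minus1 at lower bound: reaction possibly irreversible\n")
  invisible(x)
}

#' @export
summary.imine_fit <- function(object, ...) {
  k <- object$coefficients
  tab <- cbind(Estimate = c(k, Keq = object$Keq),
               `Std. Error` = c(object$se, Keq = object$Keq_se))
  structure(list(coefficients = tab, method = object$method,
                 fixed = object$fixed, converged = object$converged,
                 degenerate = object$degenerate,
                 possibly_irreversible = object$possibly_irreversible,
                 sigma = sqrt(object$sse / max(object$n - 2L, 1L)),
                 sse = object$sse, n = object$n, x0 = object$x0,
                 x_eq = equilibrium_amine(k[["k1"]], k[["k_minus1"]],
                                          object$x0)),
            class = "summary.imine_fit")
}

#' @export
print.summary.imine_fit <- function(x, ...) {
  cat(sprintf(
    "Reversible equimolar second-order fit (%s), n = %d, x0 = %.4g M\n",
    x$method, x$n, x$x0))
  stats::printCoefmat(x$coefficients, digits = 4)
  cat(sprintf("Residual sigma: %.3g M on %d points (SSE %.3g)\n",
              x$sigma, x$n, x$sse))
  cat(sprintf("Equilibrium amine: %.4g M\n", x$x_eq))
  if (length(x$fixed))
    cat(sprintf("Fixed parameters: %s\n",
                paste(names(x$fixed), format(unlist(x$fixed), digits = 4),
                      sep = " = ", collapse = ", ")))
  if (!x$converged) cat("Warning: fit did not converge\n")
  if (x$possibly_irreversible)
    cat("Note: k_minus1 at lower bound; reaction possibly irreversible\n")
  invisible(x)
}

#' Plot a fitted kinetic trace
#'
#' Data points with the fitted reversible second-order curve and the
#' equilibrium asymptote.
#'
#' @param x An `imine_fit`.
#' @param ... Further arguments to [plot()].
#' @export
plot.imine_fit <- function(x, ...) {
  plot(x$times, x$trace$concentration_M,
       xlab = "time (s)", ylab = "amine concentration (M)",
       col = grDevices::adjustcolor("black", 0.6), pch = 16, cex = 0.6, ...)
  tt <- seq(min(x$times), max(x$times), length.out = 300)
  graphics::lines(tt, predict(x, list(times = tt)), col = "firebrick",
                  lwd = 2)
  k <- x$coefficients
  graphics::abline(h = equilibrium_amine(k[["k1"]], k[["k_minus1"]], x$x0),
                   lty = 3, col = "grey40")
  invisible(x)
}
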