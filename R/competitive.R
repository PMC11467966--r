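#' Competitive two-amine binding equilibrium (exact cubic solution)
#'
#' Two amine cross-linkers compete for a common pool of aldehyde
#' functions. Writing the dissociation constants K_i = 1/Keq_i, the free
#' aldehyde concentration `[Ald]` at equilibrium is the physically valid
#' root of the cubic
#' \deqn{[Ald]^3 + a [Ald]^2 + b [Ald] + c = 0}
#' with
#' \deqn{a = K_1 + K_2 + [A_1]_0 + [A_2]_0 - [Ald]_0}
#' \deqn{b = K_1 K_2 + K_1([A_2]_0 - [Ald]_0) + K_2([A_1]_0 - [Ald]_0)}
#' \deqn{c = -K_1 K_2 [Ald]_0,}
#' the exact closed form for two ligands competing for one binding partner.
#' Each imine then follows from
#' \deqn{[Im_i] = [A_i]_0 \, [Ald] / (K_i + [Ald]).}
#' The root is evaluated by the trigonometric formula for three real roots
#' and polished by Newton iteration on the aldehyde mass balance, with a
#' general polynomial-root fallback for degenerate coefficient regimes.
#'
#' @param ald0 Initial aldehyde-function concentration (mol L^-1), > 0.
#' @param a1_0,a2_0 Initial amine-function concentrations (mol L^-1),
#'   >= 0.
#' @param Keq1,Keq2 Association constants (L mol^-1) of the two imines.
#'   (Converted internally to dissociation constants.)
#' @param allow_excess Permit total amine ratio (a1_0 + a2_0)/ald0 > 1.
#'   By default amine excess is rejected, since past saturation the
#'   cross-linked-fraction interpretation changes regime.
#' @return An object of class `competitive_state`: list with `ald_free`,
#'   `im1`, `im2`, `a1_free`, `a2_free` and the input system. Mass
#'   balances hold to 1e-10 relative.
#' @export
#' @examples
#' st <- competitive_equilibrium(10.1e-3, 5.05e-3, 5.05e-3,
#'                               Keq1 = 1e3, Keq2 = 1e3)
#' st$im1 + st$im2   # equals the one-ligand solution at am0 = 10.1 mM
competitive_equilibrium <- function(ald0, a1_0, a2_0, Keq1, Keq2,
                                    allow_excess = FALSE) {
  if (ald0 <= 0) stop("`ald0` must be positive")
  if (a1_0 < 0 || a2_0 < 0 || Keq1 < 0 || Keq2 < 0)
    stop("amine concentrations and Keq's must be non-negative")
  if (!allow_excess && (a1_0 + a2_0) > ald0 * (1 + 1e-12))
    stop("total amine ratio exceeds 1; set allow_excess = TRUE to override")
  kd1 <- keq_to_kd(Keq1)
  kd2 <- keq_to_kd(Keq2)
  # canonical ligand ordering makes the solution exactly symmetric under
  # relabelling (floating-point summation order no longer depends on it)
  swapped <- kd1 > kd2 || (kd1 == kd2 && a1_0 > a2_0)
  if (swapped) {
    p <- competitive_free_aldehyde(ald0, a2_0, a1_0, kd2, kd1)
  } else {
    p <- competitive_free_aldehyde(ald0, a1_0, a2_0, kd1, kd2)
  }
  im1 <- a1_0 * p / (kd1 + p)
  im2 <- a2_0 * p / (kd2 + p)
  # mass-balance verification (should always pass after polishing)
  if (abs(p + im1 + im2 - ald0) > 1e-10 * ald0)
    stop("no physically valid root found (mass balance violated); ",
         "inputs: ald0 = ", ald0, ", a1_0 = ", a1_0, ", a2_0 = ", a2_0)
  structure(list(ald_free = p, im1 = im1, im2 = im2,
                 a1_free = a1_0 - im1, a2_free = a2_0 - im2,
                 ald0 = ald0, a1_0 = a1_0, a2_0 = a2_0,
                 Keq1 = Keq1, Keq2 = Keq2),
            class = "competitive_state")
}

# Keq (association, L/mol) -> dissociation constant with a floor that keeps
# the cubic non-degenerate at effectively infinite affinity
keq_to_kd <- function(Keq) {
  if (Keq == 0) return(Inf)
  max(1 / Keq, 1e-16)
}

# vectorized free-aldehyde solver; all arguments recycled
competitive_free_aldehyde <- function(p0, a1, a2, kd1, kd2) {
  n <- max(length(p0), length(a1), length(a2), length(kd1), length(kd2))
  p0 <- rep_len(p0, n); a1 <- rep_len(a1, n); a2 <- rep_len(a2, n)
  kd1 <- rep_len(kd1, n); kd2 <- rep_len(kd2, n)

  # an infinite Kd means that amine never binds: drop it from the balance
  a1e <- ifelse(is.finite(kd1), a1, 0)
  a2e <- ifelse(is.finite(kd2), a2, 0)
  k1 <- ifelse(is.finite(kd1), kd1, 1)
  k2 <- ifelse(is.finite(kd2), kd2, 1)

  a <- k1 + k2 + a1e + a2e - p0
  b <- k1 * k2 + k1 * (a2e - p0) + k2 * (a1e - p0)
  cc <- -k1 * k2 * p0

  q <- a^2 - 3 * b
  p <- rep(NA_real_, n)
  ok <- q > 0
  if (any(ok)) {
    arg <- (-2 * a[ok]^3 + 9 * a[ok] * b[ok] - 27 * cc[ok]) /
      (2 * sqrt(q[ok]^3))
    arg <- pmin(pmax(arg, -1), 1)
    theta <- acos(arg)
    p[ok] <- -a[ok] / 3 + (2 / 3) * sqrt(q[ok]) * cos(theta / 3)
  }
  bad <- !ok | !is.finite(p) | p < 0 | p > p0 * (1 + 1e-6)
  for (i in which(bad)) {   # rare: fall back to general root finding
    rts <- Re(polyroot(c(cc[i], b[i], a[i], 1)))
    rts <- rts[abs(Im(polyroot(c(cc[i], b[i], a[i], 1)))) <
                 1e-8 * max(abs(rts), 1)]
    cand <- rts[rts >= -1e-12 * p0[i] & rts <= p0[i] * (1 + 1e-6)]
    if (!length(cand))
      stop("no cubic root in [0, ald0] for instance ", i)
    p[i] <- max(min(cand[1L], p0[i]), 0)
  }
  p <- pmin(pmax(p, 0), p0)

  # Newton polish on the mass balance
  # g(P) = P + a1 P/(k1+P) + a2 P/(k2+P) - p0
  for (iter in 1:20) {
    g <- p + a1e * p / (k1 + p) + a2e * p / (k2 + p) - p0
    if (all(abs(g) <= 1e-14 * p0)) break
    dg <- 1 + a1e * k1 / (k1 + p)^2 + a2e * k2 / (k2 + p)^2
    p <- pmin(pmax(p - g / dg, 0), p0)
  }
  p
}

#' @export
print.competitive_state <- function(x, ...) {
  cat("Competitive two-amine equilibrium\n")
  cat(sprintf("  free aldehyde: %.4g M of %.4g M\n", x$ald_free, x$ald0))
  cat(sprintf("  imine 1: %.4g M (Keq = %.3g), imine 2: %.4g M (Keq = %.3g)\n",
              x$im1, x$Keq1, x$im2, x$Keq2))
  invisible(x)
}

#' Total cross-linked aldehyde fraction of a competitive system
#'
#' Applies the single-amine cross-linked-fraction form to each amine's
#' equilibrium imine concentration (with the full initial aldehyde pool)
#' and sums the contributions:
#' \deqn{\chi_{XL}^{Ald,total} = \sum_i
#'   \frac{[Im_i]}{[Ald]_0} \cdot \frac{[Im_i]}{[A_i]_0}.}
#' Cross-links only form between arms of the same cross-linker, so mixed
#' imines do not count; this is what makes a weakly binding competitor able
#' to lower the total even while raising total imine content.
#'
#' @param state A [competitive_equilibrium()] result.
#' @return Total cross-linked aldehyde fraction in [0, 1].
#' @export
total_crosslinked_fraction <- function(state) {
  stopifnot(inherits(state, "competitive_state"))
  tot <- 0
  if (state$a1_0 > 0)
    tot <- tot + (state$im1 / state$ald0) * (state$im1 / state$a1_0)
  if (state$a2_0 > 0)
    tot <- tot + (state$im2 / state$ald0) * (state$im2 / state$a2_0)
  tot
}

# vectorized total chi for grids (internal)
total_chi_grid <- function(ald0, a1_0, a2_0, kd1, kd2) {
  p <- competitive_free_aldehyde(ald0, a1_0, a2_0, kd1, kd2)
  n <- length(p)
  ald0 <- rep_len(ald0, n); a1_0 <- rep_len(a1_0, n)
  a2_0 <- rep_len(a2_0, n)
  kd1 <- rep_len(kd1, n); kd2 <- rep_len(kd2, n)
  im1 <- a1_0 * p / (kd1 + p)
  im2 <- a2_0 * p / (kd2 + p)
  t1 <- t2 <- numeric(n)
  i1 <- a1_0 > 0
  t1[i1] <- im1[i1]^2 / (ald0[i1] * a1_0[i1])
  i2 <- a2_0 > 0
  t2[i2] <- im2[i2]^2 / (ald0[i2] * a2_0[i2])
  t1 + t2
}

#' Map the competitive softening regime
#'
#' Computes the change in total cross-linked aldehyde fraction when 0.5
#' equivalents of a second amine cross-linker (A2) are added to a gel
#' already containing 0.5 equivalents of a first (A1):
#' Delta-chi(K1, K2) = chi_total(0.5 + 0.5) - chi(0.5 only), over log-spaced
#' grids of both equilibrium constants. Negative cells are the softening
#' regime - adding cross-linker removes cross-links. The location of
#' maximal softening (most negative Delta-chi) is found by iterative local
#' grid refinement to two significant figures in each Keq.
#'
#' @param Keq1_grid,Keq2_grid Association-constant grids (L mol^-1);
#'   default 121 log-spaced points spanning 1e1 to 1e7.
#' @param chi1,chi2 Amine equivalents of A1 (present initially) and A2
#'   (added), defaults 0.5 and 0.5.
#' @param ald0 Initial aldehyde concentration (mol L^-1), default 10.1 mM.
#' @param refine Refine the argmin by local regridding (default TRUE).
#' @return An object of class `softening_map`: list with `Keq1`, `Keq2`,
#'   `delta_chi` (matrix [K1 x K2]), and `max_softening` = list(Keq1, Keq2,
#'   delta_chi) at the refined argmin.
#' @export
#' @examples
#' sm <- softening_map(10^seq(1, 7, length.out = 25),
#'                     10^seq(1, 7, length.out = 25), refine = FALSE)
#' range(sm$delta_chi)
softening_map <- function(Keq1_grid = 10^seq(1, 7, length.out = 121),
                          Keq2_grid = 10^seq(1, 7, length.out = 121),
                          chi1 = 0.5, chi2 = 0.5, ald0 = 10.1e-3,
                          refine = TRUE) {
  if (!length(Keq1_grid) || !length(Keq2_grid))
    stop("Keq grids must be non-empty")
  if (any(Keq1_grid <= 0) || any(Keq2_grid <= 0))
    stop("Keq grids must be positive")
  a1 <- chi1 * ald0
  a2 <- chi2 * ald0

  dchi_fun <- function(K1, K2) {
    # chi of the single-amine baseline depends on K1 only
    base <- crosslinked_fraction(ald0, chi1, K1)
    kd1 <- pmax(1 / K1, 1e-16)
    kd2 <- pmax(1 / K2, 1e-16)
    total_chi_grid(ald0, a1, a2, kd1, kd2) - base
  }

  grid <- expand.grid(K1 = Keq1_grid, K2 = Keq2_grid)
  dchi <- matrix(dchi_fun(grid$K1, grid$K2),
                 nrow = length(Keq1_grid), ncol = length(Keq2_grid))

  idx <- arrayInd(which.min(dchi), dim(dchi))
  best <- list(Keq1 = Keq1_grid[idx[1L]], Keq2 = Keq2_grid[idx[2L]],
               delta_chi = min(dchi))

  if (refine) {
    # local 10x regridding around the current argmin until the location is
    # stable to two significant figures in each Keq
    span1 <- diff(range(log10(Keq1_grid))) / max(length(Keq1_grid) - 1L, 1L)
    span2 <- diff(range(log10(Keq2_grid))) / max(length(Keq2_grid) - 1L, 1L)
    for (pass in 1:4) {
      g1 <- 10^seq(log10(best$Keq1) - span1, log10(best$Keq1) + span1,
                   length.out = 41)
      g2 <- 10^seq(log10(best$Keq2) - span2, log10(best$Keq2) + span2,
                   length.out = 41)
      sub <- expand.grid(K1 = g1, K2 = g2)
      v <- dchi_fun(sub$K1, sub$K2)
      j <- which.min(v)
      best <- list(Keq1 = sub$K1[j], Keq2 = sub$K2[j], delta_chi = v[j])
      span1 <- span1 / 10
      span2 <- span2 / 10
      if (10^span1 - 1 < 5e-3 && 10^span2 - 1 < 5e-3) break
    }
  }

  structure(list(Keq1 = Keq1_grid, Keq2 = Keq2_grid, delta_chi = dchi,
                 chi1 = chi1, chi2 = chi2, ald0 = ald0,
                 max_softening = best),
            class = "softening_map")
}

#' @export
print.softening_map <- function(x, ...) {
  cat(sprintf(
    "Softening map (%d x %d grid, chi = %.2g + %.2g, ald0 = %.4g M)\n",
    length(x$Keq1), length(x$Keq2), x$chi1, x$chi2, x$ald0))
  cat(sprintf("  delta-chi range: [%.4g, %.4g]\n",
              min(x$delta_chi), max(x$delta_chi)))
  cat(sprintf(
    "  maximal softening: delta-chi = %.4g at Keq(A1) = %.3g, Keq(A2) = %.3g\n",
    x$max_softening$delta_chi, x$max_softening$Keq1, x$max_softening$Keq2))
  invisible(x)
}

#' Per-amine squared-bound-fraction cross-link index
#'
#' An aggregate cross-link index for a mixed-cross-linker formulation:
#' the sum over amines of the squared bound fraction, sum_i (im_i/a_i0)^2.
#' Squaring reflects that both arms of a bifunctional cross-linker must be
#' bound to make a cross-link; summing per amine reflects that imines of
#' different cross-linkers cannot pair with one another. Comparing the
#' index between two formulations gives a relative cross-link change even
#' when the total imine content moves the other way.
#'
#' @param imine_concs Equilibrium imine concentration per amine (mol L^-1).
#' @param initial_concs Initial amine-function concentration per amine
#'   (mol L^-1), same length. Zero entries must have zero imine.
#' @return Sum of squared bound fractions.
#' @export
#' @examples
#' per_amine_crosslink_index(c(0.8, 0), c(1, 1))    # 0.64
#' per_amine_crosslink_index(c(0.6, 0.5), c(1, 1))  # 0.61
per_amine_crosslink_index <- function(imine_concs, initial_concs) {
  if (length(imine_concs) != length(initial_concs))
    stop("vectors must have the same length")
  if (any(initial_concs == 0 & imine_concs > 0))
    stop("imine present for an amine with zero initial concentration")
  if (any(imine_concs > initial_concs * (1 + 1e-9)))
    stop("imine concentration exceeds the initial amine concentration")
  f <- ifelse(initial_concs > 0, imine_concs / initial_concs, 0)
  sum(f^2)
}
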