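#' Reversible equimolar second-order kinetics: closed-form amine
#' concentration
#'
#' For an amine and aldehyde mixed at equal initial concentration `x0`, with
#' forward rate `k1` (L mol^-1 s^-1) and reverse rate `k_minus1` (s^-1), the
#' remaining amine x(t) obeys
#' \deqn{dx/dt = -k_1 x^2 + k_{-1} (x_0 - x), \quad x(0) = x_0.}
#' Factoring the right-hand side as \eqn{-k_1 (x - a)(x - b)} with `a`, `b`
#' the roots of \eqn{x^2 + (k_{-1}/k_1) x - (k_{-1}/k_1) x_0 = 0}
#' (`a` is the equilibrium concentration, `b < 0`), the solution is
#' \deqn{x(t) = \frac{a (x_0 - b) - b (x_0 - a) e^{-k_1 (a - b) t}}
#'                    {(x_0 - b) - (x_0 - a) e^{-k_1 (a - b) t}}.}
#' The irreversible limit `k_minus1 = 0` reduces to
#' \eqn{x(t) = x_0 / (1 + k_1 x_0 t)}, and `k1 = 0` leaves `x0` unchanged.
#'
#' @param t Time(s) in seconds, >= 0 (vectorized).
#' @param k1 Forward rate constant (L mol^-1 s^-1), >= 0.
#' @param k_minus1 Reverse rate constant (s^-1), >= 0.
#' @param x0 Initial amine (= aldehyde) concentration (mol L^-1), > 0.
#' @return Amine concentration x(t), same length as `t`. Monotone
#'   non-increasing from `x0` towards [equilibrium_amine()].
#' @seealso [irreversible_second_order_solution()], [equilibrium_amine()]
#' @export
#' @examples
#' reversible_equimolar_solution(c(0, 3600, 7200),
#'                               k1 = 0.058, k_minus1 = 5.2e-5, x0 = 5e-4)
reversible_equimolar_solution <- function(t, k1, k_minus1, x0) {
  if (any(t < 0)) stop("`t` must be non-negative")
  if (k1 < 0 || k_minus1 < 0) stop("rate constants must be non-negative")
  if (x0 <= 0) stop("`x0` must be positive")
  if (k1 == 0) return(rep(x0, length(t)))
  if (k_minus1 == 0) return(irreversible_second_order_solution(t, k1, x0))
  r <- k_minus1 / k1
  disc <- sqrt(r^2 + 4 * r * x0)
  a <- (-r + disc) / 2          # equilibrium amine concentration
  b <- (-r - disc) / 2          # negative root
  e <- exp(-k1 * (a - b) * t)
  (a * (x0 - b) - b * (x0 - a) * e) / ((x0 - b) - (x0 - a) * e)
}

#' Irreversible second-order equimolar kinetics
#'
#' Closed form x(t) = x0 / (1 + k1 * x0 * t) for the equimolar bimolecular
#' reaction without a reverse pathway. Used both as a model in its own right
#' (for reactions with no detectable hydrolysis over the observation window)
#' and as step one of the constrained fitting pathway.
#'
#' @inheritParams reversible_equimolar_solution
#' @return Amine concentration x(t).
#' @export
irreversible_second_order_solution <- function(t, k1, x0) {
  if (any(t < 0) || k1 < 0 || x0 <= 0)
    stop("`t`, `k1` must be non-negative and `x0` positive")
  x0 / (1 + k1 * x0 * t)
}

#' Equilibrium amine concentration of the reversible equimolar model
#'
#' The positive root of k1 x^2 + k_minus1 x - k_minus1 x0 = 0, i.e. the
#' concentration at which formation and hydrolysis balance. Computed in a
#' numerically stable form. `k1 = 0` returns `x0` (nothing reacts);
#' `k_minus1 = 0` returns 0 (reaction goes to completion).
#'
#' @inheritParams reversible_equimolar_solution
#' @return Equilibrium amine concentration in [0, x0].
#' @export
#' @examples
#' equilibrium_amine(0.058, 5.2e-5, 5e-4)  # ~3.575e-4
equilibrium_amine <- function(k1, k_minus1, x0) {
  if (k1 < 0 || k_minus1 < 0 || x0 <= 0)
    stop("rates must be non-negative and `x0` positive")
  if (k1 == 0) return(x0)
  if (k_minus1 == 0) return(0)
  r <- k_minus1 / k1
  # stable quadratic root: x_eq = 2 r x0 / (r + sqrt(r^2 + 4 r x0))
  2 * r * x0 / (r + sqrt(r^2 + 4 * r * x0))
}
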