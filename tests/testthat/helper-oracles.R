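# Independent numerical oracles used across the suite. These must not call
# the package's own closed-form implementations.

# adaptive ODE integration of dx/dt = -k1 x^2 + k_minus1 (x0 - x)
ode_amine <- function(times, k1, k_minus1, x0, rtol = 1e-12, atol = 1e-16) {
  rhs <- function(t, y, p) list(-p[1] * y^2 + p[2] * (p[3] - y))
  out <- deSolve::ode(y = x0, times = times, func = rhs,
                      parms = c(k1, k_minus1, x0),
                      rtol = rtol, atol = atol)
  unname(out[, 2])
}

# bisection on the aldehyde mass balance of the two-ligand competition:
# g(P) = P + a1 P/(kd1 + P) + a2 P/(kd2 + P) - p0
bisect_free_ald <- function(p0, a1, a2, kd1, kd2, iters = 200) {
  g <- function(p) p + a1 * p / (kd1 + p) + a2 * p / (kd2 + p) - p0
  lo <- 0; hi <- p0
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# quadratic-free root of the one-ligand equilibrium via uniroot on the
# mass-action relation (independent of the closed form)
uniroot_single_im <- function(ald0, am0, Keq) {
  if (Keq == 0 || am0 == 0) return(0)
  f <- function(im) Keq * (ald0 - im) * (am0 - im) - im
  stats::uniroot(f, c(0, min(ald0, am0) * (1 - 1e-15)),
                 tol = 1e-15)$root
}

# a noiseless amine consumption trace on the standard acquisition grid
make_amine_trace <- function(k1, k_minus1, x0, times = seq(0, 7200, 30)) {
  x <- reversible_equimolar_solution(times, k1, k_minus1, x0)
  concentration_trace(times, x, species = "amine", x0 = x0)
}
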