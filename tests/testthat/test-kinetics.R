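test_that("closed-form solution matches an independent ODE integration", {
  tt <- c(0, 30, 300, 3600, 7200)
  grid <- expand.grid(k1 = c(1e-3, 0.058, 1, 10),
                      km = c(0, 1e-5, 1e-3),
                      x0 = c(1e-5, 5e-4, 1e-2))
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    cf <- reversible_equimolar_solution(tt, grid$k1[i], grid$km[i],
                                        grid$x0[i])
    od <- ode_amine(tt, grid$k1[i], grid$km[i], grid$x0[i])
    worst <- max(worst, max(abs(cf - od) / pmax(abs(od), 1e-300)))
  }
  expect_lt(worst, 1e-8)
})

test_that("kinetic limits behave: irreversible, inert, half-life identities", {
  tt <- c(0, 100, 1e4, 1e6)
  # k_minus1 = 0 reduces to the irreversible hyperbola
  expect_equal(reversible_equimolar_solution(tt, 0.5, 0, 1e-3),
               1e-3 / (1 + 0.5 * 1e-3 * tt))
  # k1 = 0: nothing happens
  expect_equal(reversible_equimolar_solution(tt, 0, 1e-4, 1e-3),
               rep(1e-3, 4))
  expect_equal(reversible_equimolar_solution(tt, 0, 0, 1e-3),
               rep(1e-3, 4))
  # irreversible closed form
  expect_equal(irreversible_second_order_solution(0, 0.75, 5e-5), 5e-5)
  # k1 x0 t = 1 -> half of x0
  expect_equal(irreversible_second_order_solution(1 / (0.75 * 5e-5),
                                                  0.75, 5e-5), 5e-5 / 2)
  # published-scale plug-in: k1 = 0.75 L/mol/s, 7200 s
  expect_equal(irreversible_second_order_solution(7200, 0.75, 5e-5),
               5e-5 / 1.27, tolerance = 1e-12)
  expect_error(reversible_equimolar_solution(tt, -1, 0, 1e-3))
  expect_error(irreversible_second_order_solution(-1, 0.5, 1e-3))
})

test_that("trajectory is monotone nonincreasing and bounded by equilibrium", {
  set.seed(11)
  for (i in 1:25) {
    k1 <- 10^runif(1, -3, 1)
    km <- 10^runif(1, -7, -3)
    x0 <- 10^runif(1, -5, -2)
    tt <- seq(0, 7200, 30)
    x <- reversible_equimolar_solution(tt, k1, km, x0)
    xeq <- equilibrium_amine(k1, km, x0)
    expect_true(all(diff(x) <= 1e-15 * x0))
    expect_true(all(x >= xeq - 1e-12 * x0))
    expect_equal(x[1], x0)
  }
})

test_that("equilibrium amine is the positive quadratic root with detailed balance", {
  xeq <- equilibrium_amine(0.058, 5.2e-5, 5e-4)
  expect_equal(xeq, 3.575e-4, tolerance = 1e-3)
  # residual of the defining quadratic
  expect_lt(abs(0.058 * xeq^2 + 5.2e-5 * xeq - 5.2e-5 * 5e-4), 1e-15)
  # detailed balance: Keq equals (x0 - xeq)/xeq^2 exactly
  expect_equal(0.058 / 5.2e-5, (5e-4 - xeq) / xeq^2, tolerance = 1e-12)
  expect_equal(equilibrium_amine(0.5, 0, 1e-3), 0)
  expect_equal(equilibrium_amine(0, 1e-4, 1e-3), 1e-3)
  # strong binding limit
  expect_lt(equilibrium_amine(1e6, 1e-9, 1e-3), 1e-8)
  # long-time closed form converges to the equilibrium value
  expect_equal(reversible_equimolar_solution(1e8, 0.058, 5.2e-5, 5e-4),
               xeq, tolerance = 1e-10)
})

test_that("free reversible fit recovers parameters from noiseless traces", {
  tr <- make_amine_trace(0.1, 1e-4, 1e-4)
  fit <- fit_kinetics(tr, model = "reversible")
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["k1"]] - 0.1) / 0.1, 1e-6)
  expect_lt(abs(coef(fit)[["k_minus1"]] - 1e-4) / 1e-4, 1e-6)
  # Keq from fitted parameters reproduces k1/k_minus1 to machine precision
  expect_equal(fit$Keq, coef(fit)[["k1"]] / coef(fit)[["k_minus1"]])
  # model methods
  expect_length(residuals(fit), nrow(tr))
  expect_equal(predict(fit, list(times = 0)), 1e-4, tolerance = 1e-8)
  expect_output(print(fit), "k1")
  expect_output(print(summary(fit)), "Equilibrium amine")
})

test_that("auto pathway escalates to the constrained fit for near-irreversible traces", {
  # with measurement noise, a vanishing reverse rate is unidentifiable in
  # the free fit (relative SE of k_minus1 far above 100%)
  tt <- seq(0, 7200, 30)
  x <- reversible_equimolar_solution(tt, 0.75, 1e-9, 5e-5)
  set.seed(8)
  y <- pmin(pmax(x + rnorm(length(tt), 0, 0.002 / 14200), 0), 5e-5)
  tr <- concentration_trace(tt, y, species = "amine", x0 = 5e-5)
  fit <- fit_kinetics(tr, model = "auto")
  expect_identical(fit$method, "constrained_fit")
  expect_identical(names(fit$fixed), "k1")
  expect_lt(abs(coef(fit)[["k1"]] - 0.75) / 0.75, 0.05)
})

test_that("constrained pathway fixes k1 from the irreversible fit and flags the bound", {
  # strictly irreversible truth: step 1 exact, step 2 lands on the bound
  tr0 <- make_amine_trace(0.75, 0, 5e-5)
  fit0 <- fit_kinetics(tr0, model = "constrained")
  expect_lt(abs(coef(fit0)[["k1"]] - 0.75) / 0.75, 1e-6)
  expect_true(fit0$possibly_irreversible)

  # small but nonzero reverse rate recovered within 20%
  tr1 <- make_amine_trace(0.75, 1e-6, 5e-5)
  fit1 <- fit_kinetics(tr1, model = "constrained")
  expect_lt(abs(coef(fit1)[["k_minus1"]] - 1e-6) / 1e-6, 0.2)

  short <- concentration_trace(c(0, 30), c(5e-5, 4.9e-5),
                               species = "amine", x0 = 5e-5)
  expect_error(fit_kinetics(short, model = "constrained"), "points")
})

test_that("degenerate and invalid traces are handled explicitly", {
  flat <- concentration_trace(seq(0, 300, 30), rep(1e-4, 11),
                              species = "amine", x0 = 1e-4)
  fit <- fit_kinetics(flat)
  expect_true(fit$degenerate)
  expect_equal(unname(coef(fit)), c(0, 0))

  im <- concentration_trace(seq(0, 300, 30), rep(0, 11), species = "imine")
  expect_error(fit_kinetics(im), "amine")
  no_x0 <- concentration_trace(seq(0, 300, 30), rep(1e-4, 11),
                               species = "amine")
  expect_error(fit_kinetics(no_x0), "x0")
})

test_that("3-SE intervals cover the truth under 1% concentration noise", {
  tt <- seq(0, 7200, 30)
  x_true <- reversible_equimolar_solution(tt, 0.058, 5.2e-5, 5e-4)
  set.seed(101)
  n_sim <- 200
  hit_k1 <- hit_km <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    y <- pmin(pmax(x_true + rnorm(length(tt), 0, 0.01 * 5e-4), 0), 5e-4)
    f <- fit_kinetics(concentration_trace(tt, y, species = "amine",
                                          x0 = 5e-4),
                      model = "reversible")
    hit_k1[i] <- abs(coef(f)[["k1"]] - 0.058) <= 3 * f$se[["k1"]]
    hit_km[i] <- abs(coef(f)[["k_minus1"]] - 5.2e-5) <=
      3 * f$se[["k_minus1"]]
  }
  expect_gte(mean(hit_k1), 0.95)
  expect_gte(mean(hit_km), 0.95)
})

test_that("free-offset fits absorb a common-mode baseline error honestly", {
  tt <- seq(0, 7200, 30)
  x_true <- reversible_equimolar_solution(tt, 0.058, 5.2e-5, 5e-4)
  # noiseless with offset: strict model biased, free-offset model exact
  y <- x_true + 2e-6
  tr <- concentration_trace(tt, y, species = "amine", x0 = 5e-4)
  f_free <- fit_kinetics(tr, model = "reversible", offset = "free")
  expect_lt(abs(coef(f_free)[["k1"]] - 0.058) / 0.058, 1e-5)
  expect_equal(f_free$offset, 2e-6, tolerance = 1e-4)
  f_fix <- fit_kinetics(tr, model = "reversible", offset = "fixed")
  expect_gt(abs(coef(f_fix)[["k1"]] - 0.058) / 0.058,
            abs(coef(f_free)[["k1"]] - 0.058) / 0.058)
})

test_that("replicate aggregation conventions differ exactly as documented", {
  # identical replicates: all modes agree
  fits <- lapply(1:3, function(i) fit_kinetics(
    make_amine_trace(0.1, 1e-4, 1e-4), model = "reversible"))
  a1 <- aggregate_replicates(fits, "per_replicate_mean")
  a2 <- aggregate_replicates(fits, "ratio_of_means")
  a3 <- aggregate_replicates(fits, "global")
  expect_equal(a1$Keq, a2$Keq, tolerance = 1e-8)
  expect_equal(a1$Keq, a3$Keq, tolerance = 1e-6)
  expect_equal(a1$k1, 0.1, tolerance = 1e-6)

  # scattered replicates: mean-of-ratios differs from ratio-of-means
  pars <- list(c(9.2, 4.7e-6), c(9.8, 1.19e-5))
  fits2 <- lapply(pars, function(p) fit_kinetics(
    make_amine_trace(p[1], p[2], 1e-4), model = "reversible"))
  pm <- aggregate_replicates(fits2, "per_replicate_mean")
  rm_ <- aggregate_replicates(fits2, "ratio_of_means")
  expect_equal(pm$Keq, mean(c(9.2 / 4.7e-6, 9.8 / 1.19e-5)),
               tolerance = 1e-4)
  expect_equal(rm_$Keq, mean(c(9.2, 9.8)) / mean(c(4.7e-6, 1.19e-5)),
               tolerance = 1e-4)
  expect_gt(pm$Keq / rm_$Keq, 1.2)  # genuinely different conventions
  expect_identical(pm$aggregation, "per_replicate_mean")

  # single replicate falls back to fit standard errors
  single <- aggregate_replicates(fits2[1], "per_replicate_mean")
  expect_equal(single$n_replicates, 1L)
  expect_true(is.finite(single$k1_uncertainty))

  # mixed x0 under global mode is rejected unless allowed
  fits3 <- c(fits2[1], list(fit_kinetics(make_amine_trace(9.2, 4.7e-6, 2e-4),
                                         model = "reversible")))
  expect_error(aggregate_replicates(fits3, "global"), "x0")
  expect_s3_class(aggregate_replicates(fits3, "global",
                                       allow_mixed_x0 = TRUE),
                  "rate_constants")
})

test_that("simulate() reproduces traces refittable to the same parameters", {
  fit <- fit_kinetics(make_amine_trace(0.058, 5.2e-5, 5e-4),
                      model = "reversible")
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  refit <- fit_kinetics(sims[[1]], model = "reversible")
  expect_lt(abs(coef(refit)[["k1"]] - 0.058) / 0.058, 0.05)
})
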