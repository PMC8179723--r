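test_that("noise-free curves are recovered to better than 0.1%", {
  cases <- list(
    list(model = "fcs3d", par = c(G0 = 0.169, tauD = 4.2e-3, kappa = 3)),
    list(model = "nifs3d", par = c(G0 = 7.4, tauD = 9e-3, tauZ = 3.6e-4)),
    list(model = "nifs2d", par = c(G0 = 3.97, tauD = 3.2e-4, tauC = 1e-3)))
  for (cs in cases) {
    curve <- model_curve(cs$model, cs$par)
    fit <- fcs_fit(curve, cs$model, weights = "uniform")
    expect_true(fit$converged)
    expect_equal(coef(fit)[names(cs$par)], cs$par, tolerance = 1e-3)
    expect_lt(max(abs(residuals(fit, type = "raw"))), 1e-6 * cs$par[["G0"]])
  }
})

test_that("the 2D fit iterates the branch switch to the crossover", {
  par <- c(G0 = 4, tauD = 3.2e-4, tauC = 1e-3)
  curve <- model_curve("nifs2d", par)
  fit <- fcs_fit(curve, "nifs2d", weights = "uniform")
  expect_equal(fit$tau_crit,
               branch_crossover(coef(fit)[["tauD"]], coef(fit)[["tauC"]]),
               tolerance = 0.01)
})

test_that("initial guesses are close enough to converge", {
  # conventional curve: every guessed parameter within a factor of three
  par_c <- c(G0 = 0.17, tauD = 4.2e-3, kappa = 3)
  g <- initial_guess(model_curve("fcs3d", par_c), "fcs3d")
  ratio <- g[names(par_c)] / par_c
  expect_true(all(ratio > 1 / 3 & ratio < 3))
  # near-field curves: the half-decay heuristic reads the fastest
  # timescale, so guesses can be far from tauD; they must still be
  # positive, finite and good enough for the optimiser (covered by the
  # noise-free round-trip test above)
  for (cs in list(list(model = "nifs3d",
                       par = c(G0 = 7.4, tauD = 9e-3, tauZ = 3.6e-4)),
                  list(model = "nifs2d",
                       par = c(G0 = 4, tauD = 3.2e-4, tauC = 1e-3)))) {
    g2 <- initial_guess(model_curve(cs$model, cs$par), cs$model)
    expect_true(all(is.finite(g2)) && all(g2 > 0))
    expect_equal(g2[["G0"]] / cs$par[["G0"]], 1, tolerance = 0.5)
  }
  # guesses scale only in amplitude under rescaling of the curve
  curve <- model_curve("fcs3d", par_c)
  scaled <- curve; scaled$G <- scaled$G * 10
  g1 <- initial_guess(curve, "fcs3d")
  g2 <- initial_guess(scaled, "fcs3d")
  expect_equal(g2[["G0"]], 10 * g1[["G0"]])
  expect_equal(g2[["tauD"]], g1[["tauD"]])
  # a flat curve has no diffusion time
  flat <- nifs:::new_corr_curve(10^seq(-6, -2, length.out = 20),
                                rep(0.2, 20))
  expect_error(initial_guess(flat, "fcs3d"), "decay")
})

test_that("weighted fits recover parameters from noisy multi-run curves", {
  set.seed(53)
  par <- c(G0 = 0.169, tauD = 4.2e-3, kappa = 3)
  curve <- model_curve("fcs3d", par, noise = 0.01)
  fit <- fcs_fit(curve, "fcs3d", weights = "sd", fixed = c(kappa = 3))
  expect_equal(coef(fit)[c("G0", "tauD")], par[c("G0", "tauD")],
               tolerance = 0.05)
  # consistent noise model: reduced chi-square near 1
  expect_gt(fit$chisq_red, 0.5)
  expect_lt(fit$chisq_red, 2)
  # standard errors are finite and small relative to the estimates
  expect_true(all(is.finite(fit$se[fit$free])))
  expect_true(all(fit$se[fit$free] < 0.2 * coef(fit)[fit$free]))

  par2 <- c(G0 = 4, tauD = 3.2e-4, tauC = 1e-3)
  curve2 <- model_curve("nifs2d", par2, noise = 0.01)
  fit2 <- fcs_fit(curve2, "nifs2d", weights = "sd")
  expect_equal(coef(fit2), par2, tolerance = 0.05)
})

test_that("about two thirds of normalised residuals fall within one sd", {
  set.seed(59)
  par <- c(G0 = 7.4, tauD = 9e-3, tauZ = 3.6e-4)
  lags <- 10^seq(-6.5, -1, length.out = 70)
  runs <- replicate(20, {
    cv <- model_curve("nifs3d", par, lags = lags)
    cv$G <- cv$G + rnorm(length(lags), 0, 0.02 * par[["G0"]])
    cv
  }, simplify = FALSE)
  avg <- average_curves(runs)
  fit <- fcs_fit(avg, "nifs3d", weights = "sd")
  frac <- mean(abs(residuals(fit)) <= 1)
  expect_gt(frac, 0.5)
  expect_lt(frac, 0.9)
})

test_that("derived quantities invert the amplitude relations", {
  C_fl <- 1e18     # 1 per fL in m^-3
  par <- c(G0 = 0.169, tauD = 4.2e-3, kappa = 3)
  fit <- fcs_fit(model_curve("fcs3d", par), "fcs3d", weights = "uniform",
                 concentration = C_fl)
  expect_equal(fit$derived$Veff, 1 / (par[["G0"]] * C_fl), tolerance = 1e-4)
  expect_equal(fit$derived$N, fit$derived$Veff * C_fl)

  # near-field 3D carries the extra factor of two in the amplitude
  par3 <- c(G0 = 7.4, tauD = 9e-3, tauZ = 3.6e-4)
  fit3 <- fcs_fit(model_curve("nifs3d", par3), "nifs3d",
                  weights = "uniform", concentration = 5e20)
  expect_equal(fit3$derived$Veff, 1 / (2 * par3[["G0"]] * 5e20),
               tolerance = 1e-4)
  # halving G0 doubles the volume
  d2 <- derive_quantities(
    structure(list(model = "nifs3d", par = c(G0 = par3[["G0"]] / 2)),
              class = "fcs_fit"), 5e20)
  expect_equal(d2$Veff / fit3$derived$Veff, 2, tolerance = 1e-4)

  bad <- structure(list(model = "fcs3d", par = c(G0 = -1)),
                   class = "fcs_fit")
  expect_error(derive_quantities(bad, C_fl), "positive")
})

test_that("fit interface validates inputs and supports methods", {
  par <- c(G0 = 0.17, tauD = 4.2e-3, kappa = 3)
  curve <- model_curve("fcs3d", par)        # no sd column
  expect_error(fcs_fit(curve, "fcs3d", weights = "sd"), "standard deviations")
  fit <- fcs_fit(curve, "fcs3d", weights = "uniform")
  expect_s3_class(fit, "fcs_fit")
  expect_named(coef(fit), c("G0", "tauD", "kappa"))
  expect_equal(predict(fit, 0), coef(fit)[["G0"]], tolerance = 1e-6)
  expect_length(predict(fit), nrow(curve))
  expect_output(print(fit), "FCS model fit")
  expect_output(print(summary(fit)), "Reduced chi-square")
  # fixing a parameter holds it exactly
  fitf <- fcs_fit(curve, "fcs3d", weights = "uniform", fixed = c(kappa = 5))
  expect_identical(coef(fitf)[["kappa"]], 5)
})
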