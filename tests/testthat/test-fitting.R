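test_that("design matrix has the documented columns and levels", {
  ds <- table2_datasets()$xylan
  d <- build_design(ds, "arrhenius")
  expect_equal(dim(d$X), c(16L, 3L))
  expect_equal(colnames(d$X), c("delta_T", "ln_C", "ln_t"))
  expect_setequal(round(unique(d$X[, "ln_t"]), 10),
                  round(log(c(15, 30, 60, 90)), 10))
  expect_equal(d$n, 16L)
})

test_that("unidentifiable designs are rejected with a named culprit", {
  cond1 <- fractionation_conditions(rep(80, 8), rep(c(60, 90), 4),
                                    rep(c(0.5, 1), each = 4))
  expect_error(solubilization_dataset(cond1, "xylan", runif(8, 0.3, 0.7)),
               "temperature_C")
  # two levels per factor but concentration locked to time: collinear
  cond2 <- fractionation_conditions(rep(c(80, 105), each = 4),
                                    rep(c(60, 90), 4),
                                    rep(c(0.25, 1), 4))
  ds2 <- solubilization_dataset(cond2, "xylan", runif(8, 0.3, 0.7))
  expect_error(build_design(ds2, "arrhenius"), "collinear")
})

test_that("noiseless data return the generating parameters exactly", {
  for (family in c("arrhenius", "logistic")) {
    slope <- if (family == "arrhenius") 0.1446 else 0.2640
    intercept <- if (family == "arrhenius") -5.5595 else -9.9289
    omega <- if (family == "arrhenius") 14.54 else 13.91
    m <- if (family == "arrhenius") 12.10 else 12.52
    ds <- noiseless_dataset(omega, m, slope, intercept, family)
    fit <- fit_linearized(ds, family)
    expect_equal(fit$constants$omega, omega, tolerance = 1e-8)
    expect_equal(fit$constants$m, m, tolerance = 1e-8)
    expect_equal(fit$model$slope, slope, tolerance = 1e-8)
    expect_equal(fit$model$intercept, intercept, tolerance = 1e-8)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
    expect_lt(max(abs(fit$residuals)), 1e-10)
  }
})

test_that("parameter extraction follows the coefficient identities", {
  ds <- noiseless_dataset()
  fit <- fit_linearized(ds, "arrhenius")
  b <- fit$coefficients
  expect_equal(fit$constants$omega, unname(b["beta3_ln_t"] / b["beta1_delta_T"]))
  expect_equal(fit$constants$m, unname(b["beta2_ln_C"] / b["beta3_ln_t"]))
  expect_equal(fit$model$slope, unname(b["beta3_ln_t"]))
  expect_equal(fit$model$intercept, unname(b["beta0"]))
})

test_that("refitting data simulated from a fit reproduces the fit", {
  cfg <- simulation_config(seed = 21, noise_sigma = 0.1,
                           truth = default_truth()["xylan"])
  noisy <- simulate_alpha(cfg)
  fit1 <- fit_linearized(noisy, "arrhenius")
  resim <- noiseless_dataset(fit1$constants$omega, fit1$constants$m,
                             fit1$model$slope, fit1$model$intercept,
                             "arrhenius")
  fit2 <- fit_linearized(resim, "arrhenius")
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-8)
})

test_that("shifting the reference temperature only moves the intercept", {
  ds <- noiseless_dataset()
  delta <- 15
  f70 <- fit_linearized(ds, "arrhenius", t_ref = 70)
  f85 <- fit_linearized(ds, "arrhenius", t_ref = 70 + delta)
  expect_equal(f85$constants$omega, f70$constants$omega, tolerance = 1e-8)
  expect_equal(f85$constants$m, f70$constants$m, tolerance = 1e-8)
  expect_equal(f85$model$slope, f70$model$slope, tolerance = 1e-8)
  expect_equal(f85$model$intercept - f70$model$intercept,
               f70$model$slope * delta / f70$constants$omega,
               tolerance = 1e-8)
  expect_equal(f85$r_squared, f70$r_squared, tolerance = 1e-12)
})

test_that("goodness of fit is invariant to affine predictor rescaling", {
  cfg <- simulation_config(seed = 5, noise_sigma = 0.15,
                           truth = default_truth()["xylan"])
  ds <- simulate_alpha(cfg)
  f1 <- fit_linearized(ds, "arrhenius")
  # scaling every density by a common factor shifts ln C by a constant
  scaled <- fa_density_table(c(60, 70, 80, 90),
                             1.05 * c(1.131, 1.153, 1.174, 1.192))
  ds2 <- solubilization_dataset(
    fractionation_conditions(ds$temperature_C, ds$fa_weight_fraction * 100,
                             ds$time_min / 60),
    ds$component, ds$alpha, density_table = scaled)
  f2 <- fit_linearized(ds2, "arrhenius")
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-10)
  expect_equal(f2$model$slope, f1$model$slope, tolerance = 1e-10)
})

test_that("a realistic noisy fit yields strong, significant diagnostics", {
  cfg <- simulation_config(
    time_grid = c(0.25, 0.5, 1, 1.5, 2), seed = 101, noise_sigma = 0.15,
    truth = list(xylan_plus_lignin = solubilization_presets(
      "arrhenius", "xylan_plus_lignin")))
  ds <- simulate_alpha(cfg)
  expect_equal(nrow(ds), 80L)
  fit <- fit_linearized(ds, "arrhenius")
  # population R2 under these settings is 0.83; band from pilot replicates
  expect_gt(fit$r_squared, 0.75)
  expect_lt(fit$r_squared, 0.92)
  expect_lt(fit$p_value, 1e-6)
  # F follows from R2 and the dof by construction
  expect_equal(fit$f_statistic,
               (fit$r_squared / 3) / ((1 - fit$r_squared) / (fit$n - 4)),
               tolerance = 1e-12)
})

test_that("all variants are fitted, ranked, and failures are contained", {
  cfg <- simulation_config(seed = 31, noise_sigma = 0.1)
  sim <- simulate_alpha(cfg)
  split_ds <- lapply(split(seq_len(nrow(sim)), sim$component), function(i) {
    solubilization_dataset(
      fractionation_conditions(sim$temperature_C[i],
                               sim$fa_weight_fraction[i] * 100,
                               sim$time_min[i] / 60),
      sim$component[i], sim$alpha[i])
  })
  cmp <- fit_all_variants(split_ds, "arrhenius")
  expect_s3_class(cmp, "csf_fit_comparison")
  expect_equal(sort(cmp$summary$variant), sort(names(split_ds)))
  expect_true(all(diff(cmp$summary$r_squared) <= 0))
  # distinct per-component generators are recovered per variant
  expect_equal(cmp$fits$xylan$constants$omega, 22.53, tolerance = 0.25)
  expect_equal(cmp$fits$lignin$constants$omega, 11.06, tolerance = 0.25)
  # identical datasets give identical fits
  twin <- fit_all_variants(list(a = split_ds$xylan, b = split_ds$xylan),
                           "arrhenius")
  expect_equal(coef(twin$fits$a), coef(twin$fits$b))
  # a degenerate variant (all alpha at 1) is reported, not fatal
  cond <- generate_design(simulation_config())
  sat <- solubilization_dataset(cond, "lignin", rep(1, nrow(cond)))
  mixed <- suppressWarnings(
    fit_all_variants(list(ok = split_ds$xylan, saturated = sat), "arrhenius"))
  expect_false(is.na(mixed$summary$error[
    mixed$summary$variant == "saturated"]))
  expect_null(mixed$fits$saturated)
  expect_s3_class(mixed$fits$ok, "csf_fit")
})

test_that("nonlinear least squares agrees with the linearized fit", {
  ds <- noiseless_dataset()
  lin <- fit_linearized(ds, "arrhenius")
  # init away from truth: converges to the same optimum
  oracle <- nls_oracle(ds, "arrhenius",
                       init = list(omega = 20, m = 10, slope = 0.1,
                                   intercept = -4))
  expect_equal(coef(oracle), coef(lin), tolerance = 1e-6)
  # init at truth converges immediately
  fast <- nls_oracle(ds, "arrhenius", init = lin)
  expect_lte(fast$convergence$finIter, 3)
  expect_equal(coef(fast), coef(lin), tolerance = 1e-8)
})

test_that("heavy noise leaves both estimators finite and comparable", {
  cfg <- simulation_config(seed = 77, noise_sigma = 1.0,
                           truth = default_truth()["xylan"])
  ds <- simulate_alpha(cfg)
  # sigma = 1 pushes some alphas into the clipped tails by construction
  lin <- suppressWarnings(fit_linearized(ds, "arrhenius"))
  oracle <- suppressWarnings(nls_oracle(ds, "arrhenius", init = lin))
  expect_true(all(is.finite(coef(lin))))
  expect_true(all(is.finite(coef(oracle))))
})
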