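test_that("factorial designs have the right cardinality and ordering", {
  cfg <- simulation_config()
  des <- generate_design(cfg)
  expect_equal(nrow(des), 4L * 4L * 4L)
  expect_equal(des$temperature_C[1:16], rep(80, 16))
  expect_equal(des$fa_weight_fraction[1:4], rep(0.60, 4))
  expect_equal(des$time_min[1:4], c(15, 30, 60, 90))
  expect_error(simulation_config(t_grid = 80), "two distinct levels")
  expect_error(simulation_config(t_grid = numeric(0)), "two distinct levels")
})

test_that("the packaged design is a 16-run fixture with the printed triples", {
  cond <- table2_conditions()
  expect_equal(nrow(cond), 16L)
  expect_setequal(unique(cond$temperature_C), c(80, 90, 99, 105))
  expect_setequal(unique(cond$fa_weight_fraction), c(0.60, 0.70, 0.80, 0.90))
  expect_setequal(unique(cond$time_min), c(15, 30, 60, 90))
  expect_equal(cond$temperature_C[7], 90)
  expect_equal(cond$fa_weight_fraction[7], 0.80)
  expect_equal(cond$time_min[7], 60)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 123, noise_sigma = 0.2)
  d1 <- simulate_alpha(cfg)
  d2 <- simulate_alpha(cfg)
  expect_identical(d1$alpha, d2$alpha)
  # byte-identical artifacts end to end
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_alpha_csv(d1, f1); write_alpha_csv(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  d3 <- simulate_alpha(simulation_config(seed = 124, noise_sigma = 0.2))
  expect_false(identical(d1$alpha, d3$alpha))
})

test_that("noiseless simulation lies exactly on the model curve", {
  ds <- noiseless_dataset()
  truth <- xpl_truth
  cond <- generate_design(simulation_config(noise_sigma = 0))
  x <- csf_ext_fa(cond, severity_constants(truth$omega, truth$m))
  m <- solubilization_model("arrhenius", truth$slope, truth$intercept)
  expect_equal(ds$alpha, predict_alpha(m, x), tolerance = 1e-12)
  fit <- fit_linearized(ds, "arrhenius")
  expect_equal(unname(coef(fit)), unname(unlist(truth)), tolerance = 1e-8)
})

test_that("alpha-scale noise mode stays within [0, 1]", {
  cfg <- simulation_config(seed = 8, noise_sigma = 0.3,
                           noise_scale = "alpha",
                           truth = default_truth()["lignin"])
  ds <- simulate_alpha(cfg)
  expect_true(all(ds$alpha >= 0 & ds$alpha <= 1))
})

test_that("composition tables invert the mass balance exactly", {
  cfg <- simulation_config(seed = 17, noise_sigma = 0.15)
  ds <- simulate_alpha(cfg)
  comp <- simulate_composition_table(ds)
  rt <- derive_solubilization(comp, cfg$feedstock)
  for (c_ in c("glucan", "xylan", "lignin")) {
    truth_alpha <- ds$alpha[ds$component == c_]
    expect_equal(rt[[c_]], truth_alpha, tolerance = 1e-10)
  }
  # degenerate cases: nothing removed; all xylan removed
  cond <- generate_design(cfg)
  zero <- solubilization_dataset(
    cond[rep(seq_len(nrow(cond)), 3), ],
    rep(c("glucan", "xylan", "lignin"), each = nrow(cond)),
    rep(0, 3 * nrow(cond)))
  attr(zero, "config") <- cfg
  comp0 <- simulate_composition_table(zero)
  expect_equal(comp0$solid_yield, rep(1, nrow(cond)))
  expect_equal(comp0$glucan_content, rep(0.434, nrow(cond)))
  onex <- solubilization_dataset(
    cond[rep(seq_len(nrow(cond)), 3), ],
    rep(c("glucan", "xylan", "lignin"), each = nrow(cond)),
    rep(c(0, 1, 0), each = nrow(cond)))
  attr(onex, "config") <- cfg
  comp1 <- simulate_composition_table(onex)
  expect_equal(comp1$solid_yield, rep(1 - 0.244, nrow(cond)))
  expect_equal(comp1$xylan_content, rep(0, nrow(cond)))
})

test_that("recovered-slope dispersion scales with the noise level", {
  slope_sd <- function(sigma) {
    ests <- vapply(1:50, function(i) {
      cfg <- simulation_config(
        seed = 1000 + i, noise_sigma = sigma,
        truth = list(xylan_plus_lignin =
                       solubilization_presets("arrhenius",
                                              "xylan_plus_lignin")))
      fit_linearized(simulate_alpha(cfg), "arrhenius")$model$slope
    }, numeric(1))
    sd(ests)
  }
  s1 <- slope_sd(0.1)
  s2 <- slope_sd(0.2)
  expect_gte(s2, 2 * s1 * 0.8) # doubling sigma doubles spread, 20% slack
})

test_that("a wider severity range widens the simulated alpha span", {
  narrow <- simulation_config(t_grid = c(88, 92), fa_grid = c(70, 80),
                              time_grid = c(0.75, 1.25), noise_sigma = 0,
                              truth = default_truth()["xylan"])
  wide <- simulation_config(noise_sigma = 0,
                            truth = default_truth()["xylan"])
  span <- function(cfg) diff(range(simulate_alpha(cfg)$alpha))
  expect_gt(span(wide), span(narrow))
})

test_that("noise calibration hits a target goodness of fit", {
  cfg <- simulation_config(
    time_grid = c(0.25, 0.5, 1, 1.5, 2), seed = 11,
    truth = list(xylan_plus_lignin = solubilization_presets(
      "arrhenius", "xylan_plus_lignin")))
  cal <- calibrate_noise(cfg, target_r2 = 0.90)
  expect_equal(cal$r_squared, 0.90, tolerance = 1e-6)
  expect_gt(cal$sigma, 0)
  expect_equal(cal$fit$n, 80L)
})
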