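test_that("classical severity factor matches its closed form", {
  expect_equal(severity_factor(
    fractionation_conditions(100, 60, time_h = 1 / 60)), 0)
  expect_equal(severity_factor(
    fractionation_conditions(100, 60, time_h = 10 / 60)), 1)
  expect_equal(severity_factor(
    fractionation_conditions(114.75, 60, time_h = 1 / 60)),
    log10(exp(1)), tolerance = 1e-10)
})

test_that("combined severity factor subtracts pH and requires it", {
  expect_equal(combined_severity_factor(
    fractionation_conditions(100, 60, 1 / 60, ph = 0)), 0)
  expect_equal(combined_severity_factor(
    fractionation_conditions(100, 60, 10 / 60, ph = 2)), -1)
  expect_equal(combined_severity_factor(
    fractionation_conditions(114.75, 60, 10 / 60, ph = 1)),
    log10(exp(1)), tolerance = 1e-10)
  expect_error(combined_severity_factor(
    fractionation_conditions(100, 60, 1)), "pH")
})

test_that("wt% to molarity conversion follows 1000*rho*w/M", {
  expect_equal(wtpct_to_molarity(0.60), 1000 * 1.131 * 0.60 / 46.03)
  expect_equal(wtpct_to_molarity(0.60), 14.743, tolerance = 1e-4)
  expect_equal(wtpct_to_molarity(0.90), 23.307, tolerance = 1e-4)
  expect_error(wtpct_to_molarity(0), "\\(0, 1\\]")
  expect_error(wtpct_to_molarity(0.65), "65")
  expect_error(wtpct_to_molarity(0.65), "60, 70, 80, 90")
})

test_that("condition invariants are enforced at construction", {
  expect_error(fractionation_conditions(300, 60, 1), "temperature")
  expect_error(fractionation_conditions(80, 0, 1), "weight fraction")
  expect_error(fractionation_conditions(80, 60, 0), "time")
  # hours at the boundary are minutes internally
  cond <- fractionation_conditions(80, 60, 0.25)
  expect_equal(cond$time_min, 15)
  expect_equal(cond$fa_weight_fraction, 0.60)
})

test_that("extended severity vanishes at the reference point", {
  # a liquor at exactly 1 mol/L: density 0.9206 g/mL at 5 wt%
  dt <- fa_density_table(5, 0.9206)
  cond <- fractionation_conditions(70, 5, time_h = 1 / 60)
  k <- severity_constants(14.54, 12.10, t_ref = 70)
  expect_equal(csf_ext_fa(cond, k, dt), 0, tolerance = 1e-12)
})

test_that("general CSF_ext reduces to the FA-specific form", {
  cond <- fractionation_conditions(c(80, 105), c(60, 90), c(0.25, 1.5),
                                   catalyst_molarity = 1)
  k0 <- severity_constants(14.54, 12.10, n = 0)
  expect_identical(csf_ext(cond, k0), csf_ext_fa(cond, k0))
  # unit catalyst molarity contributes ln 1 = 0 even with n = 1
  k1 <- severity_constants(14.54, 12.10, n = 1)
  expect_equal(csf_ext(cond, k1), csf_ext_fa(cond, k0))
  # but a catalyzed convention demands the molarity
  cond2 <- fractionation_conditions(80, 60, 1)
  expect_error(csf_ext(cond2, k1), "catalyst_molarity")
})

test_that("severity decomposes additively into its three terms", {
  k <- csf_presets("arrhenius-table1")
  cond <- fractionation_conditions(99, 80, 0.5)
  x <- csf_ext_fa(cond, k)
  expect_equal(x,
               (99 - 70) / k$omega +
                 k$m * log(wtpct_to_molarity(0.80)) + log(30),
               tolerance = 1e-12)
})

test_that("CSF_ext is strictly monotone in each operating factor", {
  k <- csf_presets("arrhenius-table1")
  set.seed(11)
  for (i in 1:25) {
    t0 <- runif(1, 75, 100)
    h0 <- runif(1, 0.25, 1.5)
    base <- csf_ext_fa(fractionation_conditions(t0, 60, h0), k)
    expect_gt(csf_ext_fa(fractionation_conditions(t0 + 5, 60, h0), k), base)
    expect_gt(csf_ext_fa(fractionation_conditions(t0, 60, h0 + 0.1), k), base)
    expect_gt(csf_ext_fa(fractionation_conditions(t0, 70, h0), k), base)
  }
})

test_that("table-consistent presets reproduce the printed design severities", {
  rep <- reproduce_table2()
  expect_s3_class(rep, "table2_reproduction")
  expect_equal(nrow(rep), 16L)
  # logistic column: all 16 within printed rounding
  expect_true(all(rep$match_L))
  # arrhenius column: all but the flagged misprint
  expect_identical(which(rep$outlier_A), 12L)
  expect_true(all(rep$match_A[-12]))
  expect_gt(abs(rep$delta_A[12]), 10)
})

test_that("the closed-form constant presets differ from the table-consistent ones", {
  cond <- table2_conditions()
  t2 <- load_table2()
  a7 <- csf_ext_fa(cond, csf_presets("eq7"))
  l8 <- csf_ext_fa(cond, csf_presets("eq8"))
  # the closed-form constants miss the printed rounding for most runs,
  # unlike the table-consistent presets
  expect_gte(sum(abs(a7 - t2$A_CSF_ext)[-12] > 0.02), 12)
  expect_true(all(abs(l8 - t2$L_CSF_ext) > 0.02))
})

test_that("csf_ext_fa refuses a catalyzed constant set", {
  expect_error(
    csf_ext_fa(fractionation_conditions(80, 60, 1),
               severity_constants(14, 12, n = 1)),
    "n = 0")
})
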