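# Elemental composition arithmetic, ion m/z, and formula prediction.

test_that("formula parsing round-trips and rejects malformed input", {
  expect_equal(parse_formula("C15H12O7"), c(C = 15L, H = 12L, O = 7L))
  expect_equal(parse_formula("C20H19NO13S"),
               c(C = 20L, H = 19L, N = 1L, O = 13L, S = 1L))
  expect_error(parse_formula("C15Xx2"), "unknown element")
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("C15H#2"), "malformed")
  for (f in c("C15H12O7", "CH4", "C6H8O6", "C5H7NO3")) {
    expect_identical(format_formula(parse_formula(f)), f)
  }
  # Hill order is canonical regardless of input order; carbon-free
  # compositions are written alphabetically
  expect_identical(format_formula(parse_formula("O7C15H12")), "C15H12O7")
  expect_identical(format_formula(parse_formula("SO3")), "O3S")
  expect_identical(parse_formula(format_formula(parse_formula("SO3"))),
                   parse_formula("SO3"))
})

test_that("monoisotopic masses reproduce the characteristic mass shifts", {
  expect_equal(round(monoisotopic_mass("H2O"), 4), 18.0106)
  expect_equal(round(monoisotopic_mass("C6H8O6"), 4), 176.0321)
  expect_equal(round(monoisotopic_mass("SO3"), 4), 79.9568)
  expect_equal(round(monoisotopic_mass("C5H7NO3"), 4), 129.0426)
  expect_equal(round(monoisotopic_mass("C2H5NO"), 4), 59.0371)
  expect_equal(round(monoisotopic_mass("CH2"), 2), 14.02)
  expect_identical(monoisotopic_mass(numeric(0)), 0)
})

test_that("mass is additive under composition addition", {
  set.seed(42)
  for (i in 1:50) {
    a <- random_counts()
    b <- random_counts()
    ab <- parse_formula(paste0(format_formula(a), format_formula(b)))
    expect_lt(abs(monoisotopic_mass(ab) -
                    monoisotopic_mass(a) - monoisotopic_mass(b)), 1e-9)
  }
})

test_that("ion m/z includes the electron mass and supports both adducts", {
  expect_equal(round(ion_mz("C15H12O7"), 4), 303.0510)
  expect_equal(round(ion_mz("C21H18O12", "[M+NH2]-"), 4), 478.0991)
  expect_equal(round(ion_mz("C15H12O10S"), 4), 383.0078)
  # unicode minus and the [M+NH3-H]- alias are accepted
  expect_equal(ion_mz("C15H12O7", "[M−H]−"), ion_mz("C15H12O7"))
  expect_equal(ion_mz("C21H18O12", "[M+NH3-H]-"),
               ion_mz("C21H18O12", "[M+NH2]-"))
  expect_error(ion_mz("C15H12O7", "[M+H]+"), "unsupported adduct")
})

test_that("ppm error and DBE match the published conventions", {
  expect_equal(round(ppm_error(303.0521, 303.0510), 2), 3.63)
  expect_equal(round(ppm_error(479.0834, 479.0831), 2), 0.63)
  expect_equal(ppm_error(512.0509, 512.0509), 0)
  expect_error(ppm_error(100, 0), "positive")
  expect_equal(rdbe("C15H12O7"), 10)
  expect_equal(rdbe("C20H19NO13S"), 12)
  expect_equal(rdbe("CH4"), 0)
})

test_that("every fixture row recomputes: predicted m/z, ppm and DBE", {
  t1 <- tax_table1()
  pred <- ion_mz(t1$formula, t1$ion)
  # predicted m/z to the printed 4 dp within transcription tolerance
  expect_gte(mean(abs(pred - t1$pred_mz) <= 2e-4), 0.95)
  # DBE is exact on all rows
  expect_identical(rdbe(t1$formula), as.numeric(t1$dbe))
  # the printed ppm column was computed against the display-rounded
  # prediction; within 0.05 ppm on at least 95% of rows
  ppm <- ppm_error(t1$meas_mz, round(pred, 4))
  expect_gte(mean(abs(ppm - t1$diff_ppm) <= 0.05), 0.95)
})

test_that("formula prediction equals the brute-force oracle on random masses", {
  set.seed(101)
  bounds <- c(C = 12, H = 20, N = 2, O = 8, S = 2)
  masses <- runif(50, 120, 450)
  for (mz in masses) {
    got <- predict_formulas(mz, tol_ppm = 20, bounds = bounds)
    want <- oracle_predict(mz, tol_ppm = 20, bounds = bounds)
    expect_identical(got$formula, want$formula)
    expect_equal(got$predicted_mz, want$predicted_mz, tolerance = 1e-12)
  }
})

test_that("formula prediction spot cases behave per contract", {
  top <- predict_formulas(303.0510)
  expect_identical(top$formula[1], "C15H12O7")
  cand <- predict_formulas(383.0082)
  expect_true("C15H12O10S" %in% cand$formula)
  row <- cand[cand$formula == "C15H12O10S", ]
  expect_equal(round(ppm_error(383.0082, round(row$predicted_mz, 4)), 2), 1.04)
  expect_identical(nrow(predict_formulas(303.0510, tol_ppm = 0.001,
                                         bounds = c(C = 1, H = 1, O = 1))), 0L)
  expect_error(predict_formulas(303.0510, tol_ppm = -1), "tol_ppm")
})
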