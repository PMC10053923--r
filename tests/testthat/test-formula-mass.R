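test_that("monoisotopic masses match reference constants and are additive", {
  expect_equal(monoisotopic_mass("H"), 1.0078250, tolerance = 1e-7)
  expect_equal(monoisotopic_mass("C"), 12)
  # linearity over formula concatenation
  expect_equal(monoisotopic_mass("C2H4O2"), 2 * monoisotopic_mass("CH2O"),
               tolerance = 1e-9)
  withr::with_seed(5, {
    for (i in 1:10) {
      a <- c(C = sample(0:20, 1), H = sample(0:30, 1), N = sample(0:3, 1),
             O = sample(0:10, 1), S = sample(0:2, 1))
      b <- c(C = sample(0:20, 1), H = sample(0:30, 1), N = sample(0:3, 1),
             O = sample(0:10, 1), S = sample(0:2, 1))
      expect_equal(monoisotopic_mass(a + b),
                   monoisotopic_mass(a) + monoisotopic_mass(b),
                   tolerance = 1e-9)
    }
  })
  expect_error(monoisotopic_mass("C2Xe3"), class = "fusemet_data_error")
  expect_error(parse_formula("not a formula!"), class = "fusemet_data_error")
})

test_that("protonated adduct m/z reproduces printed accurate masses to 4 dp", {
  expect_equal(round(adduct_mz("C28H24O14", "[M+H]+"), 4), 585.1239)
  expect_equal(round(adduct_mz("C21H20O10", "[M+H]+"), 4), 433.1129)
  expect_equal(round(adduct_mz("C30H48O5", "[M+H]+"), 4), 489.3575)
  # round trip
  m <- monoisotopic_mass("C30H48O5")
  expect_identical(adduct_mz(m, "[M+H]+") - fusemet:::PROTON_MASS, m)
  expect_error(adduct_mz(100, "[M+Na]+"), class = "fusemet_config_error")
})

test_that("ppm error is signed, antisymmetric to second order, and gates at 3", {
  expect_identical(ppm_error(500, 500), 0)
  th <- adduct_mz("C48H28O30", "[M-H]-")
  err <- ppm_error(1083.0620, th)
  expect_gt(err, 0)
  expect_lt(abs(err), 3)          # inside the instrument's mass-accuracy gate
  expect_equal(err, 2.53, tolerance = 0.01)
  a <- 433.1129; b <- a * (1 + 2e-6)
  expect_equal(ppm_error(a, b), -ppm_error(b, a), tolerance = 1e-4)
})

test_that("formula prediction recovers the true formula and matches brute force", {
  cand <- predict_formula(433.1129, "[M+H]+", tol_ppm = 3,
                          bounds = list(C = 40, H = 60, O = 30))
  expect_true("C21H20O10" %in% cand$formula)
  expect_true(all(abs(cand$ppm_error) <= 3))
  expect_true(all(cand$rdbe >= 0 & cand$rdbe == round(cand$rdbe)))

  # independent full-grid enumeration oracle on a smaller search space
  bounds <- list(C = 25, H = 30, O = 12)
  mz <- adduct_mz("C15H10O7", "[M+H]+")  # a flavonol-type mass
  oracle <- local({
    g <- expand.grid(C = 0:25, H = 0:30, O = 0:12)
    mass <- g$C * 12 + g$H * 1.00782503207 + g$O * 15.9949146196
    theo <- mass + 1.00727646688
    err <- 1e6 * (mz - theo) / theo
    rdbe <- g$C - g$H / 2 + 1
    keep <- abs(err) <= 3 & g$C > 0 & rdbe >= 0 & rdbe == round(rdbe) &
      g$H / g$C >= 0.2 & g$H / g$C <= 3.1 & g$O / g$C <= 1.2
    sort(sprintf("C%dH%dO%d", g$C[keep], g$H[keep], g$O[keep]))
  })
  got <- predict_formula(mz, "[M+H]+", tol_ppm = 3, bounds = bounds)
  normalize <- function(f) sort(sprintf("C%dH%dO%d", f$C, f$H, f$O))
  expect_setequal(normalize(got), oracle)
  expect_equal(got$formula[1], "C15H10O7")  # exact mass ranks first

  # vanishing tolerance empties the list for a noisy mass
  expect_equal(nrow(predict_formula(433.2, "[M+H]+", tol_ppm = 1e-4,
                                    bounds = bounds)), 0L)
  # widening bounds never removes a candidate
  wide <- predict_formula(mz, "[M+H]+", tol_ppm = 3,
                          bounds = list(C = 30, H = 40, N = 2, O = 15, S = 1))
  expect_true(all(got$formula %in% wide$formula))
  expect_error(predict_formula(100, bounds = list(C = 0, H = 0, O = 0)),
               class = "fusemet_config_error")
})

test_that("round-trip: masses generated from in-bounds formulas are recovered", {
  withr::with_seed(11, {
    for (i in 1:15) {
      f <- c(C = sample(5:30, 1), H = sample(6:40, 1), N = sample(0:2, 1),
             O = sample(1:12, 1), S = 0)
      if (f[["H"]] / f[["C"]] < 0.2 || f[["H"]] / f[["C"]] > 3.1) next
      if (f[["O"]] / f[["C"]] > 1.2) next
      r <- f[["C"]] - f[["H"]] / 2 + f[["N"]] / 2 + 1
      if (r < 0 || r != round(r)) next
      adduct <- sample(c("[M+H]+", "[M-H]-"), 1)
      mz <- adduct_mz(monoisotopic_mass(f), adduct)
      got <- predict_formula(mz, adduct, tol_ppm = 1,
                             bounds = list(C = 35, H = 45, N = 3, O = 15, S = 1))
      lab <- fusemet:::format_formula(as.data.frame(as.list(f)))
      expect_true(lab %in% got$formula)
    }
  })
})
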