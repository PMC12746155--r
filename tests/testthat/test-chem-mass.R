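test_that("formula parsing handles counts, repeats, deuterium, and round-trips", {
  expect_equal(parse_formula("C21H40N2O6"),
               c(C = 21, H = 40, N = 2, O = 6))
  expect_equal(parse_formula("H2O"), c(H = 2, O = 1))
  expect_equal(parse_formula("C5D7H3NO2"),
               c(C = 5, H = 3, D = 7, N = 1, O = 2))
  # repeated element mentions accumulate
  expect_equal(parse_formula("CH3COOH"), c(C = 2, H = 4, O = 2))
  # round trip through formatting
  for (s in c("C21H40N2O6", "H2O", "C5D7H3NO2", "C15H21N5O5"))
    expect_equal(parse_formula(format_formula(parse_formula(s))),
                 parse_formula(s))
  expect_equal(parse_formula(""), setNames(numeric(0), character(0)))
})

test_that("formula parsing rejects unknown elements and malformed counts", {
  expect_error(parse_formula("C21X2"), "X")
  expect_error(parse_formula("C0H2"), "C0")
  expect_error(parse_formula("C2.5"), "unparseable")
  expect_error(as_formula(c(C = -1)), "non-negative")
  expect_error(as_formula(c(Qq = 2)), "Qq")
})

test_that("monoisotopic and average masses match hand-summed values", {
  expect_equal(monoisotopic_mass("C5H10N2O4"),
               oracle_mono(c(C = 5, H = 10, N = 2, O = 4)), tolerance = 1e-12)
  expect_equal(monoisotopic_mass("C5H10N2O4"), 162.0641, tolerance = 1e-4)
  expect_equal(monoisotopic_mass("C21H40N2O6"), 416.2886, tolerance = 1e-4)
  expect_identical(monoisotopic_mass(""), 0)
  expect_identical(average_mass(""), 0)
  # standard atomic weights: tetracycline and water
  expect_equal(average_mass("C22H24N2O8"), 444.44, tolerance = 0.01)
  expect_equal(average_mass("H2O"), 18.015, tolerance = 0.001)
})

test_that("monoisotopic mass is additive over random formulas", {
  set.seed(42)
  for (i in 1:50) {
    a <- random_formula(); b <- random_formula()
    ab <- table(c(rep(names(a), a), rep(names(b), b)))
    ab <- setNames(as.numeric(ab), names(ab))
    expect_equal(monoisotopic_mass(a) + monoisotopic_mass(b),
                 monoisotopic_mass(ab), tolerance = 1e-9)
  }
})

test_that("adduct m/z arithmetic follows (M + delta)/|z|", {
  expect_equal(adduct_mz("C5H10N2O4", "[M+H]+"), 163.0713, tolerance = 1e-4)
  expect_equal(adduct_mz("C15H21N5O5", "[M+H]+"), 352.1615, tolerance = 1e-4)
  # [M]+ with zero delta reduces to the neutral mass
  expect_equal(adduct_mz("C6H6", adduct("[M]+", charge = 1, delta = 0)),
               monoisotopic_mass("C6H6"))
  expect_error(adduct("bad", charge = 0, delta = 1), "non-zero")
  expect_error(adduct("nonsense+"), "unknown adduct")
})

test_that("ppm error is signed, zero on self, and errors on bad input", {
  theo <- adduct_mz("C5H10N2O4", "[M+H]+")
  expect_equal(ppm_error(163.0726, theo), 7.8, tolerance = 0.05)
  theo2 <- adduct_mz("C21H40N2O6", "[M+H]+")
  expect_equal(ppm_error(417.2931, theo2), -6.7, tolerance = 0.05)
  expect_identical(ppm_error(417.2931, 417.2931), 0)
  expect_error(ppm_error(100, 0), "positive")
  # antisymmetric to first order
  expect_equal(ppm_error(theo, 163.0726), -7.8, tolerance = 0.05)
})

test_that("RDBE arithmetic counts deuterium as hydrogen", {
  expect_equal(rdbe("C21H40N2O6"), 3)
  expect_equal(rdbe("CH4"), 0)
  expect_equal(rdbe("C6H6"), 4)
  expect_equal(rdbe("C5D7H3NO2"), rdbe("C5H10NO2"))
})

test_that("ppm_error of an adduct m/z against itself is 0 for all adducts", {
  for (a in c("[M+H]+", "[M-H]-", "[M+Na]+"))
    for (f in c("C6H12O6", "C21H40N2O6", "C15H21N5O5"))
      expect_identical(ppm_error(adduct_mz(f, a), adduct_mz(f, a)), 0)
})

test_that("formula enumeration matches the brute-force oracle", {
  cases <- list(
    list(mass = 18.0106, tol = 5, cmax = 0, hmax = 4, nmax = 0, omax = 2),
    list(mass = 352.1611 - proton_mass(), tol = 10, cmax = 30, hmax = 60,
         nmax = 10, omax = 10),
    list(mass = 417.2931 - proton_mass(), tol = 10, cmax = 30, hmax = 60,
         nmax = 10, omax = 10),
    list(mass = 162.0641, tol = 8, cmax = 12, hmax = 24, nmax = 4, omax = 6))
  for (cs in cases) {
    got <- enumerate_formulas(cs$mass, tol_ppm = cs$tol,
                              bounds = c(C = cs$cmax, H = cs$hmax,
                                         N = cs$nmax, O = cs$omax))
    oracle <- oracle_enumerate(cs$mass, cs$tol, cs$cmax, cs$hmax, cs$nmax,
                               cs$omax)
    expect_identical(
      formula_set(as.matrix(got[, c("C", "H", "N", "O")])),
      formula_set(oracle))
  }
})

test_that("enumeration of water-scale mass is the single expected formula", {
  got <- enumerate_formulas(18.0106, tol_ppm = 5, bounds = c(H = 4, O = 2),
                            use_nitrogen_rule = FALSE)
  expect_equal(nrow(got), 1L)
  expect_identical(got$formula, "H2O")
})

test_that("the doreamide neutral mass admits several candidates incl. the assigned formula", {
  got <- enumerate_formulas(417.2931 - proton_mass(), tol_ppm = 10,
                            bounds = c(C = 30, H = 60, N = 10, O = 10))
  expect_gte(nrow(got), 2L)
  expect_true("C21H40N2O6" %in% got$formula)
})

test_that("every enumerated candidate satisfies its stated constraints", {
  got <- enumerate_formulas(352.1611 - proton_mass(), tol_ppm = 10,
                            bounds = c(C = 30, H = 60, N = 10, O = 10))
  expect_gt(nrow(got), 0)
  for (i in seq_len(nrow(got))) {
    f <- parse_formula(got$formula[i])
    expect_lte(abs(got$ppm[i]), 10)
    expect_gte(rdbe(f), 0)
    expect_equal(rdbe(f), round(rdbe(f)))
    expect_true(nitrogen_rule(f))
    expect_true(all(f <= c(C = 30, H = 60, N = 10, O = 10)[names(f)]))
  }
  # ranked by |ppm| ascending
  expect_true(!is.unsorted(abs(got$ppm)))
})

test_that("enumeration returns an empty frame when nothing fits", {
  got <- enumerate_formulas(500.0001, tol_ppm = 0.001,
                            bounds = c(C = 5, H = 5, N = 1, O = 1))
  expect_s3_class(got, "formula_candidates")
  expect_equal(nrow(got), 0L)
})
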