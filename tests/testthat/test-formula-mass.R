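test_that("formula parsing handles both dialects, accumulation and errors", {
  f <- parse_formula("C12H14ON", "protonated_ion")
  expect_equal(unclass(f$counts)[c("C", "H", "O", "N")],
               c(C = 12L, H = 14L, O = 1L, N = 1L))
  expect_identical(f$charge_state, "protonated_ion")
  # canonical output is Hill order
  expect_identical(format(f), "C12H14NO")
  expect_true(parse_formula(format(f), "protonated_ion") == f)

  expect_equal(unclass(parse_formula("H")$counts), c(H = 1L))
  expect_equal(unclass(parse_formula("C2C3")$counts), c(C = 5L))
  # Table 1 underscore dialect
  expect_identical(format(parse_formula("C_12_H_14_ON")), "C12H14NO")

  expect_error(parse_formula(""), "empty")
  expect_error(parse_formula("C12X4"), "X")
  expect_error(formula_counts(c(C = -1)), "non-negative")
})

test_that("proton mass equals H minus electron up to the atomic binding energy", {
  mc <- mass_constants()
  # H(1s) binding energy (13.6 eV ~ 1.5e-8 u) separates the two CODATA routes
  expect_equal(mc$proton, mc$elements[["H"]] - mc$electron, tolerance = 2e-8)
})

test_that("ion m/z reproduces the printed pseudane [M+H]+ masses", {
  printed <- unique(table1_printed()[, c("mz", "ion_formula")])
  for (i in seq_len(nrow(printed))) {
    theo <- ion_mz(parse_formula(printed$ion_formula[i], "protonated_ion"))
    # all printed rows agree within 1 ppm (observed values, 4th-decimal noise)
    expect_lt(abs(ppm_error(printed$mz[i], theo)), 1)
  }
  # the three exactly-reproducible anchors, at 4 decimals
  expect_equal(round_half_away(ion_mz(parse_formula("C12H14ON", "protonated_ion"))), 188.1070)
  expect_equal(round_half_away(ion_mz(parse_formula("C20H30ON", "protonated_ion"))), 300.2322)
  expect_equal(round_half_away(ion_mz(parse_formula("C15H20ON", "protonated_ion"))), 230.1539)
})

test_that("neutral and protonated conventions agree", {
  for (fstr in c("C12H13NO", "C16H21NO", "CH4", "C6H12O6")) {
    neutral <- parse_formula(fstr, "neutral")
    cc <- neutral$counts
    cc["H"] <- cc["H"] + 1L
    ionised <- formula_counts(cc, "protonated_ion")
    expect_equal(ion_mz(neutral), ion_mz(ionised), tolerance = 1e-9)
  }
})

test_that("monoisotopic mass is additive over compositions", {
  set.seed(41)
  el <- names(mass_constants()$elements)
  for (i in 1:25) {
    a <- setNames(sample(0:8, 5, replace = TRUE), el)
    b <- setNames(sample(0:8, 5, replace = TRUE), el)
    a["C"] <- a["C"] + 1L; b["H"] <- b["H"] + 1L  # keep nonempty
    fa <- formula_counts(a); fb <- formula_counts(b); fab <- formula_counts(a + b)
    expect_equal(monoisotopic_mass(fa) + monoisotopic_mass(fb),
                 monoisotopic_mass(fab), tolerance = 1e-9)
  }
})

test_that("ppm error is signed, scaled and strictly monotone in observed m/z", {
  expect_equal(ppm_error(188.1070, 188.1070), 0)
  expect_equal(ppm_error(200.0002, 200.0000), 1.0, tolerance = 1e-6)
  expect_error(ppm_error(100, 0), "positive")
  # the C14H18ON assignment of the 216.1382 unknown has a sub-ppm negative error
  d <- ppm_error(216.1382, ion_mz(parse_formula("C14H18ON", "protonated_ion")))
  expect_gt(d, -1); expect_lt(d, 0)
  set.seed(42)
  theo <- runif(1, 100, 500)
  obs <- sort(runif(20, theo - 0.01, theo + 0.01))
  expect_true(all(diff(ppm_error(obs, theo)) > 0))
})

test_that("RDBE follows the CHNOS closed form with the ion H-removal convention", {
  expect_equal(rdbe(parse_formula("C12H13NO", "neutral")), 7)
  expect_equal(rdbe(parse_formula("CH4", "neutral")), 0)
  expect_equal(rdbe(parse_formula("C12H14ON", "protonated_ion")), 7)
  # every pseudane ion parent has the 7 unsaturations of the quinolone scaffold
  for (fstr in unique(table1_printed()$ion_formula))
    expect_equal(rdbe(parse_formula(fstr, "protonated_ion")), 7)
})

test_that("formula enumeration recovers the unknown-peak assignments", {
  cand <- enumerate_formulas(216.1382, 5)
  expect_identical(cand$formula[1], "C14H18NO")
  expect_true(all(abs(cand$ppm_error) <= 5))
  expect_true(all(cand$rdbe >= 0 & cand$rdbe <= 20))
  cand2 <- enumerate_formulas(230.1539, 5)
  expect_identical(cand2$formula[1], "C15H20NO")
  # pathologically tight tolerance finds nothing
  expect_identical(nrow(enumerate_formulas(188.1070, 1e-6)), 0L)
})

test_that("enumeration matches the brute-force oracle on fuzzed masses", {
  bounds <- c(C = 15L, H = 30L, N = 2L, O = 4L, S = 1L)
  set.seed(7)
  masses <- runif(60, 80, 350)
  for (mzq in masses) {
    got <- enumerate_formulas(mzq, 5, bounds = bounds)
    want <- oracle_enumerate(mzq, 5, bounds)
    expect_identical(got$formula, want$formula)
    if (nrow(want))
      expect_equal(got$theoretical_mz, want$theoretical_mz, tolerance = 1e-9)
  }
})

test_that("consecutive pseudane ions differ by exactly one CH2 unit", {
  theo <- vapply(unique(table1_printed()$ion_formula),
                 function(s) ion_mz(parse_formula(s, "protonated_ion")), 0)
  expect_equal(unname(diff(theo)), rep(mass_constants()$ch2, 8), tolerance = 1e-6)
})

test_that("display rounding is half away from zero", {
  expect_equal(round_half_away(2.00005, 4), 2.0001)
  expect_equal(round_half_away(-2.00005, 4), -2.0001)
  expect_equal(round_half_away(1.23444, 4), 1.2344)
})
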