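test_that("formula parsing handles both dialects and rejects garbage", {
  expect_equal(unclass(parse_formula("C19H18O11")),
               c(C = 19L, H = 18L, O = 11L), ignore_attr = TRUE)
  expect_equal(unclass(parse_formula("H2O")), c(H = 2L, O = 1L),
               ignore_attr = TRUE)
  expect_equal(unclass(parse_formula("C_35_H_42_O_20_")),
               c(C = 35L, H = 42L, O = 20L), ignore_attr = TRUE)
  # the mangled markup variant that appears in the packaged table
  expect_equal(unclass(parse_formula("C_26_H30O_15_")),
               c(C = 26L, H = 30L, O = 15L), ignore_attr = TRUE)
  expect_error(parse_formula("C19Xx2"), "unknown element")
  expect_error(parse_formula(""), "empty")
  expect_error(parse_formula("19C"), "malformed")
})

test_that("adduct m/z values reproduce the printed 2-dp table values", {
  expect_equal(round(monoisotopic_mz("C19H18O11", "M_minus_H"), 2), 421.08)
  expect_equal(round(monoisotopic_mz("C16H20O9", "M_plus_formate"), 2),
               401.11)
  expect_equal(round(monoisotopic_mz("C35H42O20", "[M-H]"), 2), 781.22)
  expect_equal(round(monoisotopic_mz("C29H32O15", "[M-H]"), 2), 619.17)
  expect_equal(round(monoisotopic_mz("C41H52O25", "[M-H]"), 2), 943.27)
  expect_equal(round(monoisotopic_mz("C40H44O20", "[M-H]"), 2), 843.24)
  # both adduct spellings resolve identically
  expect_equal(monoisotopic_mz("C16H20O9", "[M-H+HCOOH]"),
               monoisotopic_mz("C16H20O9", "M_plus_formate"))
  expect_error(monoisotopic_mz("C6H12O6", "[M+Na]"), "unknown adduct")
})

test_that("monoisotopic mass is additive over composition", {
  for (pair in list(c("C6H12O6", "H2O"), c("C19H18O11", "C2H2O"))) {
    a <- parse_formula(pair[1])
    b <- parse_formula(pair[2])
    combined <- tapply(c(a, b), c(names(a), names(b)), sum)
    expect_equal(monoisotopic_mass(a) + monoisotopic_mass(b),
                 sum(ELEMENT_MASSES[names(combined)] * combined),
                 tolerance = 1e-9)
  }
})

test_that("neutral-loss explanation matches the glycoside fragment ladder", {
  # trifloroside [M-H]- 781.22: 619.17 is the de-glucosylated ion
  # (anhydroglucose, 162.05) and 739.20 the deacetylated one (ketene, 42.01)
  out <- explain_losses(781.22, c(619.17, 739.20, 300.00))
  expect_equal(out$losses[1], "anhydroglucose")
  expect_lte(abs(out$mass_error[1]), 0.01)
  expect_equal(out$losses[2], "C2H2O")
  expect_equal(out$delta[2], 42.02, tolerance = 1e-9)
  expect_equal(out$losses[3], "unexplained")
  # two-step chains are found when no single loss fits
  out2 <- explain_losses(500.00, 500.00 - 18.0106 - 136.0160)
  expect_match(out2$losses, "H2O/anhydro_dihydroxybenzoyl")
  expect_error(explain_losses(400, c(399, 401)), "smaller than the precursor")
})

test_that("the m/z audit confirms consistent rows and flags the known outliers", {
  t2 <- load_compound_fixture("table2")
  audit2 <- audit_fixture_mz(t2)
  # scabraside and the other seco-iridoid markers are arithmetic-consistent
  expect_false(audit2$flagged[audit2$name == "Scabraside"])
  expect_equal(audit2$computed_mz[audit2$name == "Scabraside"], 843.2353,
               tolerance = 1e-4)
  # syringaresinol's printed 491.14 is ~0.05 off the computed formate m/z
  expect_true(audit2$flagged[grepl("Syringaresinol", audit2$name)])
  expect_equal(sum(audit2$flagged), 1)

  t1 <- load_compound_fixture("table1")
  audit1 <- audit_fixture_mz(t1)
  dg <- audit1[audit1$name == "Deglu-trifloroside", ]
  expect_false(dg$flagged)
  expect_equal(round(dg$computed_mz, 2), 619.17)
  # the audit flags, never overwrites: printed values are untouched
  expect_equal(audit1$printed_mz[audit1$name == "Loganin"], 435.22)
  expect_true(audit1$flagged[audit1$name == "Loganin"])

  # the marker-table audit matches the committed expectation file
  expected <- read.csv(system.file("extdata", "table2_mz_audit_expected.csv",
                                   package = "chemomarker"))
  expect_equal(audit2$flagged, expected$flagged)
  expect_equal(round(audit2$computed_mz, 2), expected$computed_mz_2dp)
})
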