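test_that("percent yield is the recovered fraction of the charge", {
  expect_equal(percent_yield(500, 1000), 50)
  expect_equal(percent_yield(930.35, 930.35), 100)
  # inverse arithmetic round trip at the reference polymeric batch size:
  # charge 300 + 600 + 30.35 mg, 78.56% recovered
  actual <- 930.35 * 78.56 / 100
  expect_equal(percent_yield(actual, 930.35), 78.56, tolerance = 1e-12)
  expect_warning(percent_yield(1100, 1000), "exceeds 100")
  expect_error(percent_yield(0, 100), "positive")
  # scale invariance
  expect_equal(percent_yield(730.9 * 3.7, 930.35 * 3.7),
               percent_yield(730.9, 930.35))
})

test_that("drug content percent follows the external-standard formula", {
  expect_equal(drug_content_percent(100, 100, 1, 1), 100)
  expect_equal(drug_content_percent(200, 100, 1, 1), 200)
  expect_equal(drug_content_percent(0.9799, 1, 1, 1) * 100 / 100, 97.99)
  # linear in sample peak area
  base <- drug_content_percent(123, 150, 0.5, 0.52)
  expect_equal(drug_content_percent(2 * 123, 150, 0.5, 0.52), 2 * base)
  expect_error(drug_content_percent(1, 0, 1, 1), "positive")
})

test_that("equimolar masses reproduce the reference batch sheet", {
  mm_cef <- molar_mass("C14H13N5O5S2")
  mm_naoh <- 22.990 + 15.999 + 1.008
  expect_equal(round(equimolar_mass(300, mm_cef, mm_naoh), 2), 30.35)
  # identity and transitivity
  expect_equal(equimolar_mass(300, mm_cef, mm_cef), 300)
  mm_arg <- molar_mass("C6H14N4O2")
  ab <- equimolar_mass(300, mm_cef, mm_naoh)
  abc <- equimolar_mass(ab, mm_naoh, mm_arg)
  expect_equal(abc, equimolar_mass(300, mm_cef, mm_arg), tolerance = 1e-9)
  # 1.00 mmol of L-arginine weighs 174.20 mg
  expect_equal(round(1.00 * mm_arg, 2), 174.20)
  expect_error(equimolar_mass(-1, 10, 10), "positive")
})

test_that("drug loading is the w/w fraction of the total", {
  expect_equal(drug_loading_percent(0, 500), 0)
  expect_equal(drug_loading_percent(500, 0), 100)
  expect_equal(drug_loading_percent(300, 507.2), 100 * 300 / 807.2)
  expect_equal(round(drug_loading_percent(300, 507.2), 2), 37.17)
  expect_equal(drug_loading_percent(300 * 2.5, 507.2 * 2.5),
               drug_loading_percent(300, 507.2))
  expect_error(drug_loading_percent(0, 0), "both")
  expect_error(drug_loading_percent(-1, 10), "non-negative")
})

test_that("bundled compositions load and validate", {
  comps <- load_compositions()
  expect_identical(sort(names(comps$formulations)), c("F1", "F2", "F3"))
  expect_identical(comps$drug, "Cefdinir")
  f1 <- unlist(comps$formulations$F1$components)
  expect_equal(sum(f1), 930.35)
  expect_true(all(unlist(lapply(comps$formulations,
                                function(f) unlist(f$components))) > 0))
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("drug: X", "formulations:", "  F1:", "    components:",
               "      Y: 10"), bad)
  expect_error(load_compositions(bad), "drug component")
})

test_that("the co-amorphous composition implies a 0.759:1:1 molar ratio", {
  comps <- load_compositions()
  f3 <- unlist(comps$formulations$F3$components)
  mm <- c("Cefdinir" = molar_mass("C14H13N5O5S2"),
          "L-arginine" = molar_mass("C6H14N4O2"),
          "L-phenylalanine" = molar_mass("C9H11NO2"))
  chk <- stoichiometry_check(f3, mm)
  expect_equal(round(chk$ratio, 3), c(0.759, 1.000, 1.000))
  expect_error(stoichiometry_check(f3, mm[1:2]), "no molar mass")
})
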