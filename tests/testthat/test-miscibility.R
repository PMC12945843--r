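test_that("chi follows the lattice formula and the inorganic convention", {
  drug <- ref_substance("Cefdinir")
  ctx <- chi_context(drug_molar_volume = 230)
  # identical total parameters give chi = 0
  clone <- substance("clone", "polymer", drug$hsp)
  expect_equal(flory_huggins_chi(drug, clone, ctx), 0)
  # cefdinir vs HPMC 606 at Vm = 230 cm^3/mol: frozen hand arithmetic
  # 230 * (sqrt(491.6241) - sqrt(525.61))^2 / (8.314 * 298) ~= 0.0527
  hpmc <- ref_substance("HPMC 606")
  expect_equal(flory_huggins_chi(drug, hpmc, ctx), 0.0527, tolerance = 2e-3)
  # inorganic carriers sit outside the lattice model
  sba <- ref_substance("SBA-15")
  expect_identical(flory_huggins_chi(drug, sba, ctx), NA_real_)
  expect_error(chi_context(drug_molar_volume = -5), "positive")
})

test_that("chi classification uses a strict bound and handles NA", {
  expect_identical(classify_by_chi(0.076), "miscible")
  expect_identical(classify_by_chi(0.6), "not_miscible")
  expect_identical(classify_by_chi(0.5), "not_miscible")
  expect_identical(classify_by_chi(NA_real_), "not_applicable")
  expect_error(classify_by_chi(-0.1), "non-negative")
})

test_that("chi is non-negative, zero iff equal delta_t, monotone, linear in Vm", {
  drug <- ref_substance("Cefdinir")
  dt_drug <- total_parameter(drug)
  excipients <- generate_synthetic_excipients(300, seed = 11)
  ctx <- chi_context(drug_molar_volume = 200)
  for (e in excipients) {
    e$inorganic <- FALSE
    chi <- flory_huggins_chi(drug, e, ctx)
    expect_gte(chi, 0)
    expect_identical(chi == 0, total_parameter(e) == dt_drug)
    # scaling in Vm, exact up to floating rounding
    expect_equal(flory_huggins_chi(drug, e, chi_context(2000)), chi * 10,
                 tolerance = 1e-12)
    expect_equal(chi, naive_chi(200, dt_drug, total_parameter(e)),
                 tolerance = 1e-12)
  }
  # strictly increasing in |delta_t difference|, all else fixed
  gaps <- seq(0.1, 5, by = 0.1)
  chis <- vapply(gaps, function(g) {
    e <- substance("e", "polymer", hsp(dt_drug + g, 0, 0))
    flory_huggins_chi(drug, e, ctx)
  }, numeric(1))
  expect_true(all(diff(chis) > 0))
})

test_that("pair assessment populates classifications from its constituents", {
  drug <- ref_substance("Cefdinir")
  ctx <- chi_context(fedors_molar_volume(cefdinir_fragments()))
  clone <- substance("clone", "polymer", drug$hsp)
  a <- assess_pair(drug, clone, ctx)
  expect_equal(a$ra, 0)
  expect_equal(a$chi, 0)
  expect_identical(a$ra_class, "miscible")
  expect_identical(a$chi_class, "miscible")
  pvp <- assess_pair(drug, ref_substance("PVP K30"), ctx)
  expect_identical(pvp$ra_class, "miscible")
  expect_equal(pvp$ra, sqrt(6.5364), tolerance = 1e-9)
  sba <- assess_pair(drug, ref_substance("SBA-15"), ctx)
  expect_identical(sba$chi_class, "not_applicable")
  # literature Ra disagrees with recomputation -> discrepancy note
  expect_match(pvp$notes, "differs")
  expect_error(assess_pair(ref_substance("PVP K30"), drug, ctx),
               "role 'drug'")
})

test_that("screen orders by Ra, picks best per role, and validates input", {
  fix <- ref_fixture()
  drug <- fix$substances[[1]]
  excipients <- fix$substances[-1]
  ctx <- chi_context(fedors_molar_volume(cefdinir_fragments()))
  rep <- screen(drug, excipients, ctx)
  expect_s3_class(rep, "screening_report")
  expect_identical(nrow(rep$assessments), length(excipients))
  expect_true(!is.unsorted(rep$assessments$ra))
  # among the three polymers HPMC 606 has the lowest chi
  pol <- rep$assessments[rep$assessments$role == "polymer", ]
  expect_identical(pol$excipient[which.min(pol$chi)], "HPMC 606")
  expect_identical(rep$best_per_role$polymer, "HPMC 606")
  expect_identical(rep$best_per_role$mesoporous_carrier, "SBA-15")
  # a clone of the drug ranks first overall
  clone <- substance("drug-clone", "coformer", drug$hsp)
  rep2 <- screen(drug, c(excipients, list(clone)), ctx)
  expect_identical(rep2$assessments$excipient[[1]], "drug-clone")
  # single excipient: report of length one, best of its role
  rep1 <- screen(drug, list(excipients[[1]]), ctx)
  expect_identical(nrow(rep1$assessments), 1L)
  expect_identical(rep1$best_per_role[[excipients[[1]]$role]],
                   excipients[[1]]$name)
  expect_error(screen(drug, list(), ctx), "non-empty")
  expect_error(screen(drug, c(excipients, excipients[1]), ctx), "duplicate")
})

test_that("report regeneration is byte-identical", {
  fix <- ref_fixture()
  ctx <- chi_context(fedors_molar_volume(cefdinir_fragments()))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_report_csv(screen(fix$substances[[1]], fix$substances[-1], ctx), f1)
  write_report_csv(screen(fix$substances[[1]], fix$substances[-1], ctx), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  md <- report_markdown(screen(fix$substances[[1]], fix$substances[-1], ctx))
  expect_true(any(grepl("^\\| excipient", md)))
})
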