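tab <- group_contribution_table()

test_that("Fedors volume is the increment sum", {
  # linearity on a single group
  dv_ch2 <- tab$delta_v[tab$label == "CH2"]
  expect_equal(fedors_molar_volume(c(CH2 = 3), tab), 3 * dv_ch2)
  # ethanol: brute-force sum over the bundled increments
  eth <- c(CH3 = 1, CH2 = 1, OH = 1)
  expected <- sum(vapply(names(eth), function(g)
    eth[[g]] * tab$delta_v[tab$label == g], numeric(1)))
  expect_equal(fedors_molar_volume(eth, tab), expected)
  expect_equal(expected, 59.6) # 33.5 + 16.1 + 10.0, frozen
})

test_that("fragment validation catches empty and unknown inputs", {
  expect_error(fedors_molar_volume(numeric(0), tab), "empty")
  expect_error(fedors_molar_volume(c(CH3 = 0), tab), "empty")
  expect_error(fedors_molar_volume(c(XX9 = 1), tab), "XX9")
  expect_error(fedors_molar_volume(c(CH3 = 1.5), tab), "integers")
})

test_that("Hoftyzer-Van Krevelen components follow their defining sums", {
  v <- 100
  fd_ch3 <- tab$Fd[tab$label == "CH3"]
  one <- hvk_hsp(c(CH3 = 1), tab, v)
  expect_equal(one[["delta_d"]], fd_ch3 / v)
  expect_equal(one[["delta_p"]], 0)
  expect_equal(one[["delta_h"]], 0)
  # two identical polar groups: delta_p = sqrt(2) * Fp / V
  fp_oh <- tab$Fp[tab$label == "OH"]
  two <- hvk_hsp(c(OH = 2), tab, v)
  expect_equal(two[["delta_p"]], sqrt(2) * fp_oh / v, tolerance = 1e-12)
  # ethanol with its Fedors volume, frozen hand arithmetic:
  # Fd = 420+270+210 = 900; Fp^2 = 500^2; Eh = 20000; V = 59.6
  eth <- hvk_hsp(c(CH3 = 1, CH2 = 1, OH = 1), tab, 59.6)
  expect_equal(eth[["delta_d"]], 900 / 59.6, tolerance = 1e-12)
  expect_equal(eth[["delta_p"]], 500 / 59.6, tolerance = 1e-12)
  expect_equal(eth[["delta_h"]], sqrt(20000 / 59.6), tolerance = 1e-12)
  expect_error(hvk_hsp(c(CH3 = 1), tab, 0), "positive")
})

test_that("volume additivity and count-scaling hold on synthetic fragment sets", {
  for (seed in 1:50) {
    a <- generate_synthetic_fragments(seed, tab)
    b <- generate_synthetic_fragments(seed + 1000, tab)
    ab <- tapply(c(a, b), names(c(a, b)), sum)
    ab <- stats::setNames(as.numeric(ab), names(ab))
    va <- fedors_molar_volume(a, tab)
    vb <- fedors_molar_volume(b, tab)
    expect_equal(fedors_molar_volume(ab, tab), va + vb, tolerance = 1e-9)
    # doubling every count doubles V and leaves delta_d unchanged
    expect_equal(fedors_molar_volume(a * 2, tab), 2 * va, tolerance = 1e-9)
    h1 <- hvk_hsp(a, tab, va)
    h2 <- hvk_hsp(a * 2, tab, 2 * va)
    expect_equal(h2[["delta_d"]], h1[["delta_d"]], tolerance = 1e-9)
    expect_equal(h2[["delta_h"]], h1[["delta_h"]], tolerance = 1e-9)
    # output always satisfies the component invariants
    expect_true(all(h1 >= 0))
  }
})

test_that("molar mass sums bundled atomic weights over a parsed formula", {
  # frozen sums over the bundled IUPAC weights
  expect_equal(molar_mass("H2O"), 2 * 1.008 + 15.999)
  expect_equal(molar_mass("C6H14N4O2"), 174.204, tolerance = 1e-9)
  expect_equal(molar_mass("C14H13N5O5S2"), 395.408, tolerance = 1e-9)
  expect_equal(round(molar_mass("C6H14N4O2"), 2), 174.20)
  expect_equal(round(molar_mass("C14H13N5O5S2"), 2), 395.41)
  expect_error(molar_mass("C2Xx5"), "Xx")
  expect_error(molar_mass(""), "empty")
  expect_equal(parse_formula("CH3CH3"), c(C = 2L, H = 6L))
})

test_that("the cefdinir multiset gives a plausible Fedors molar volume", {
  fr <- cefdinir_fragments()
  vm <- fedors_molar_volume(fr, tab)
  expect_gt(vm, 150)
  expect_lt(vm, 400)
  # multiset is formula-consistent: 26 heavy atoms (C14 N5 O5 S2)
  heavy <- sum(fr * stats::setNames(tab$heavy_atoms, tab$label)[names(fr)])
  expect_identical(as.numeric(heavy), 26)
})

test_that("unknown schemes and malformed tables are rejected", {
  expect_error(group_contribution_table("nonsense"), "unknown")
  bad <- tempfile(fileext = ".csv")
  writeLines("label,Fd\nCH3,420", bad)
  expect_error(group_contribution_table(path = bad), "lacks columns")
})
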