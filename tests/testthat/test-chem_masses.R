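# Monoisotopic mass bookkeeping: formulas, peptides, fragments, diagnostics.

test_that("modification deltas reproduce the printed search values", {
  # expected values frozen from an independent atom-count summation
  expect_equal(formula_mass("C3H4O2"),
               oracle_formula_mass(list(C = 3, H = 4, O = 2)), tolerance = 1e-6)
  expect_identical(round(formula_mass("C3H4O2"), 2), 72.02)   # lactyl
  expect_identical(round(formula_mass("C2H3NO"), 2), 57.02)   # carbamidomethyl
  expect_identical(round(formula_mass("O"), 2), 15.99)        # oxidation
  # acetyl (C2H2O) is 42.0106 Da; the correct 2-decimal value is 42.01
  expect_identical(round(formula_mass("C2H2O"), 2), 42.01)
  expect_equal(formula_mass("C2H2O"),
               oracle_formula_mass(list(C = 2, H = 2, O = 1)),
               tolerance = 1e-6)
  expect_identical(formula_mass(""), 0)
  expect_error(formula_mass("C3Xx2"), "unknown element")
})

test_that("peptide masses match the elemental-composition oracle", {
  expect_equal(peptide_mass(peptide_form("PEPTIDE")), 799.3600,
               tolerance = 1e-4)
  lac <- default_modifications()$lactyl
  expect_equal(peptide_mass(peptide_form("K", list("1" = lac))), 218.1267,
               tolerance = 1e-4)
  # a zero-delta modification leaves the mass unchanged
  zero <- modification("nothing", "", "G")
  expect_identical(peptide_mass(peptide_form("G", list("1" = zero))),
                   peptide_mass(peptide_form("G")))
})

test_that("mass additivity: concatenation adds masses minus one water", {
  set.seed(42)
  water <- formula_mass("H2O")
  for (i in 1:20) {
    a <- random_protein(sample(2:15, 1))
    b <- random_protein(sample(2:15, 1))
    expect_equal(peptide_mass(peptide_form(paste0(a, b))),
                 peptide_mass(peptide_form(a)) + peptide_mass(peptide_form(b)) -
                   water,
                 tolerance = 1e-9)
  }
})

test_that("peptide_form validates modification placement", {
  lac <- default_modifications()$lactyl
  expect_error(peptide_form("AG", list("3" = lac)), "out of range")
  expect_error(peptide_form("AG", list("1" = lac)), "not permitted")
  ac <- default_modifications()$acetyl_nterm
  expect_error(peptide_form("AGK", list("1" = ac)), "not permitted")
  expect_silent(peptide_form("AGK", list("1" = ac), is_protein_nterm = TRUE))
  expect_error(peptide_form("AB1"), "unknown residue")
})

test_that("fragment ions: b1 anchor value and b/y complementarity", {
  fr <- fragment_ions(peptide_form("AG"), 1L)
  expect_equal(fr$mz[fr$label == "b1^1"], 72.0444, tolerance = 1e-4)

  set.seed(7)
  for (i in 1:25) {
    seqstr <- random_protein(sample(2:30, 1))
    p <- peptide_form(seqstr)
    fr <- fragment_ions(p, 1L)
    n <- nchar(seqstr)
    m <- peptide_mass(p)
    b <- fr$mz[fr$series == "b"][order(fr$index[fr$series == "b"])]
    y <- fr$mz[fr$series == "y"][order(fr$index[fr$series == "y"])]
    # b_i + y_(n-i) = neutral mass + 2 protons
    expect_equal(b + rev(y), rep(m + 2 * oracle_proton, n - 1L),
                 tolerance = 1e-6)
  }
  expect_error(fragment_ions(peptide_form("AGK"), 0L), "positive")
})

test_that("positional isomers share precursor mass, differ at site-determining ions", {
  lac <- default_modifications()$lactyl
  p2 <- peptide_form("AKAKA", list("2" = lac))
  p4 <- peptide_form("AKAKA", list("4" = lac))
  expect_equal(peptide_mass(p2), peptide_mass(p4), tolerance = 1e-9)
  f2 <- fragment_ions(p2, 1L)
  f4 <- fragment_ions(p4, 1L)
  differ <- abs(f2$mz - f4$mz) > 1e-6
  expect_setequal(f2$label[differ], c("b2^1", "b3^1", "y2^1", "y3^1"))
})

test_that("diagnostic ion geometry: cyclic and open immonium forms", {
  ci <- cycim_ion()
  oi <- open_immonium_ion()
  expect_equal(ci$mz, 156.1019, tolerance = 1e-4)
  expect_equal(oi$mz, 173.1285, tolerance = 1e-4)
  # defining identity: cyclic = open - NH3
  expect_equal(ci$mz, oi$mz - formula_mass("NH3"), tolerance = 1e-4)
})

test_that("modification definitions load from JSON", {
  cfg <- tempfile(fileext = ".json")
  writeLines('[{"name":"lactyl","formula":"C3H4O2","targets":["K"]},
               {"name":"cam","formula":"C2H3NO","targets":["C"],"variable":false}]',
             cfg)
  mods <- read_modifications(cfg)
  expect_named(mods, c("lactyl", "cam"))
  expect_equal(mods$lactyl$delta, 72.0211, tolerance = 1e-4)
  expect_false(mods$cam$variable)
})
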