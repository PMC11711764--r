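# AScore localization, CycIm detection, and the composite validation gate.

lac_delta <- "+72.021129"

test_that("symmetric evidence gives AScore exactly 0", {
  # spectrum containing only ions shared by both placements of AKAKA
  lac <- default_modifications()$lactyl
  f2 <- fragment_ions(peptide_form("AKAKA", list("2" = lac)), 1L)
  f4 <- fragment_ions(peptide_form("AKAKA", list("4" = lac)), 1L)
  shared <- f2$mz[vapply(f2$mz, function(v) any(abs(f4$mz - v) < 1e-6),
                         logical(1))]
  s <- spectrum("sc1", "S1", 300, 2L, 1e6, shared, rep(1000, length(shared)))
  loc <- ascore("AKAKA", paste0("K2", lac_delta), s)
  expect_identical(loc$ascore, 0)
})

test_that("one-sided site-determining evidence reproduces the binomial tail score", {
  # all ions of the K2 placement present, so its 4 site-determining ions are
  # 4/4 matched and the K4 placement's are 0/4
  lac <- default_modifications()$lactyl
  f2 <- fragment_ions(peptide_form("AKAKA", list("2" = lac)), 1L)
  s <- spectrum("sc1", "S1", 300, 2L, 1e6, f2$mz, rep(1000, length(f2$mz)))
  loc <- ascore("AKAKA", paste0("K2", lac_delta), s, fragment_tol = 0.02)
  expect_identical(loc$best_site, 2L)
  # three of the four site-determining ions share one 100 Da window, so all
  # four are first retained at depth 3; deeper levels only dilute p. Hence the
  # most discriminating depth is 3 and the score is the k = n = 4 tail there.
  p3 <- 3 * 2 * 0.02 / 100
  expect_identical(loc$depth_used, 3L)
  expect_equal(loc$ascore, -10 * log10(p3^4), tolerance = 1e-9)
  # and the reported depth is self-consistent with the score formula
  pd <- loc$depth_used * 2 * 0.02 / 100
  expect_equal(loc$ascore, -10 * log10(pd^4), tolerance = 1e-9)
})

test_that("single-candidate peptides are force-localized with the sentinel score", {
  lac <- default_modifications()$lactyl
  p <- peptide_form("AAEKVLSGR", list("4" = lac), charge = 2L)
  s <- simulate_spectrum(p, noiseless_params(), seed = 5)
  loc <- ascore("AAEKVLSGR", paste0("K4", lac_delta), s)
  expect_identical(loc$best_site, 4L)
  expect_identical(loc$ascore, 1000)
  expect_error(ascore("AAEVLSGR", "", s), "exactly one lactyl")
})

test_that("simulated two-lysine peptides localize to the true site", {
  lac <- default_modifications()$lactyl
  for (seed in 1:20) {
    p <- peptide_form("TLHEKGSVAYK", list("5" = lac), charge = 2L)
    s <- simulate_spectrum(p, noiseless_params(), seed = seed)
    loc <- ascore("TLHEKGSVAYK", paste0("K5", lac_delta), s)
    expect_identical(loc$best_site, 5L)
    expect_gt(loc$ascore, 20)
  }
})

test_that("AScore is non-decreasing in matched site-determining ions", {
  lac <- default_modifications()$lactyl
  f2 <- fragment_ions(peptide_form("AKAKA", list("2" = lac)), 1L)
  f4 <- fragment_ions(peptide_form("AKAKA", list("4" = lac)), 1L)
  shared <- f2$mz[vapply(f2$mz, function(v) any(abs(f4$mz - v) < 1e-6),
                         logical(1))]
  sd2 <- setdiff(round(f2$mz, 6), round(shared, 6))
  prev <- -Inf
  for (k in 0:4) {
    mzs <- c(shared, sd2[seq_len(k)])
    s <- spectrum("sc", "S1", 300, 2L, 1e6, mzs, rep(1000, length(mzs)))
    loc <- ascore("AKAKA", paste0("K2", lac_delta), s)
    expect_gte(loc$ascore, prev)
    prev <- loc$ascore
  }
})

test_that("CycIm detection distinguishes present, absent and undetectable", {
  mk <- function(mzs, first_mass = 110) {
    spectrum("s", "S1", 500, 2L, 1e6, mzs, rep(1000, length(mzs)),
             first_mass = first_mass)
  }
  hit <- detect_cycim(mk(c(156.1020, 300)), tol = 0.02)
  expect_identical(hit$status, "present")
  expect_equal(hit$abs_error, 156.1020 - cycim_ion()$mz, tolerance = 1e-9)
  expect_lt(hit$abs_error, 0.02)
  expect_identical(detect_cycim(mk(c(156.20, 300)), tol = 0.02)$status,
                   "absent")
  expect_identical(detect_cycim(mk(c(300, 400), first_mass = 200))$status,
                   "undetectable")
  # intensity floor: a sub-threshold peak does not count
  s <- spectrum("s", "S1", 500, 2L, 1e6, c(156.1019, 300), c(1, 1e6))
  expect_identical(detect_cycim(s, min_rel_intensity = 0.01)$status, "absent")
  expect_identical(detect_cycim(s, min_rel_intensity = 0)$status, "present")
})

test_that("the gate chain filters in order and maps positions to the protein", {
  cohort <- simulate_cohort(example_cohort_spec(
    seed = 44, fragment_sigma = 0, fragment_detection_prob = 1,
    n_noise_peaks = 0L, cycim_emission_prob = 1))
  index <- build_candidate_index(cohort$proteins)
  psms <- estimate_fdr(search_spectra(cohort$spectra, index))
  v <- validate_sites(psms, cohort$spectra)
  # on a noiseless cohort every retained site maps to a planted position
  truth_sites <- unique(cohort$truth[cohort$truth$modified,
                                     c("accession", "position")])
  got <- unique(v[c("accession", "protein_position")])
  expect_identical(
    nrow(merge(got, truth_sites,
               by.x = c("accession", "protein_position"),
               by.y = c("accession", "position"))),
    nrow(got))
  # all planted sites recovered
  expect_identical(nrow(got), nrow(truth_sites))
  # threshold gate: q above the cut rejects everything
  v0 <- validate_sites(psms, cohort$spectra, fdr_q = 0)
  expect_identical(nrow(v0), 0L)
  # gate-chain counts are monotone non-increasing
  rep_counts <- attr(v, "report")
  expect_true(rep_counts["n_lactyl"] >= rep_counts["n_fdr_pass"])
  expect_true(rep_counts["n_fdr_pass"] >= rep_counts["n_ascore_pass"])
  expect_true(rep_counts["n_ascore_pass"] >= rep_counts["n_flank_pass"])
  expect_true(rep_counts["n_flank_pass"] >= rep_counts["n_validated"])
})

test_that("disabling the CycIm gate never shrinks the retained set", {
  cohort <- simulate_cohort(example_cohort_spec(seed = 55, hostile = TRUE,
                                                n_noise_peaks = 40L))
  index <- build_candidate_index(cohort$proteins)
  psms <- estimate_fdr(search_spectra(cohort$spectra, index))
  v_on <- validate_sites(psms, cohort$spectra, cycim_gate = TRUE)
  v_off <- validate_sites(psms, cohort$spectra, cycim_gate = FALSE)
  expect_gte(nrow(v_off), nrow(v_on))
  if (nrow(v_on)) {
    expect_true(all(v_on$scan_id %in% v_off$scan_id))
  }
})
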