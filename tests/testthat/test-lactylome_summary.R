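# Cohort summaries: detection frequency, intensity ranking, occupancy.

fake_validated <- function(sites, samples_per_site, intensity = 1e6) {
  do.call(rbind, lapply(seq_along(sites), function(i) {
    data.frame(accession = sub(":.*", "", sites[i]),
               protein_position = as.integer(sub(".*:", "", sites[i])),
               sample_id = samples_per_site[[i]],
               precursor_intensity = intensity[min(i, length(intensity))],
               stringsAsFactors = FALSE)
  }))
}

test_that("detection frequency counts samples, not PSMs", {
  roster <- sprintf("S%02d", 1:12)
  v <- fake_validated(c("P1:10", "P2:20"),
                      list(roster, roster[1:6]))
  # duplicated PSMs in one sample must not inflate the count
  v <- rbind(v, v[1, ])
  f <- detection_frequency(v, roster)
  expect_equal(f$frequency[f$accession == "P1"], 100)
  expect_equal(f$frequency[f$accession == "P2"], 50)
  expect_identical(nrow(detection_frequency(v[0, ], roster)), 0L)
})

test_that("occupancy follows the intensity-ratio definition", {
  q <- data.frame(
    sample_id = "S1", accession = "P1", site_position = 10L,
    modified_flag = c(TRUE, FALSE), peptide = "AAEKVLSGR",
    precursor_intensity = c(2e6, 2e6))
  expect_equal(site_occupancy(q, "P1", 10L, "S1"), 0.5)
  q$precursor_intensity <- c(3e6, 0)
  expect_equal(site_occupancy(q, "P1", 10L, "S1"), 1.0)
  expect_true(is.na(site_occupancy(q, "P1", 99L, "S1")))
  q$precursor_intensity <- c(-1, 1)
  expect_error(site_occupancy(q, "P1", 10L, "S1"), "negative")
})

test_that("planted occupancies are recovered exactly under the deterministic split", {
  proteins <- data.frame(accession = "SYN1",
                         sequence = "MSDFLTRAAEKVLSGRTQLVDDLSK")
  plan <- data.frame(accession = "SYN1", position = 11L, occupancy = 0.37,
                     present_in = NA_integer_, base_intensity = 1e6)
  cohort <- simulate_cohort(cohort_spec(proteins, plan, n_samples = 4L,
                                        sim = sim_params(seed = 3)))
  for (sid in cohort$samples) {
    expect_identical(site_occupancy(cohort$quant, "SYN1", 11L, sid), 0.37)
  }
})

test_that("binomial-split occupancies land within 0.05 at 50 copies", {
  proteins <- data.frame(accession = "SYN1",
                         sequence = "MSDFLTRAAEKVLSGRTQLVDDLSK")
  plan <- data.frame(accession = "SYN1", position = 11L, occupancy = 0.37,
                     present_in = NA_integer_, base_intensity = 1e6)
  res <- lapply(1:10, function(seed) {
    cohort <- simulate_cohort(cohort_spec(proteins, plan, n_samples = 4L,
                                          split = "binomial", n_copies = 50L,
                                          sim = sim_params(seed = seed)))
    vapply(cohort$samples, function(sid) {
      c(est = site_occupancy(cohort$quant, "SYN1", 11L, sid),
        real = cohort$site_truth$occupancy[cohort$site_truth$sample_id == sid])
    }, numeric(2))
  })
  est <- unlist(lapply(res, function(m) m["est", ]))
  real <- unlist(lapply(res, function(m) m["real", ]))
  # the estimator recovers the realized split exactly ...
  expect_equal(max(abs(est - real)), 0, tolerance = 1e-12)
  # ... and the cohort-average estimate sits within the binomial band of the
  # planned occupancy at 50 copies per precursor
  expect_lt(abs(mean(est) - 0.37), 0.05)
})

test_that("intensity ranking uses a strict detection-count cut and fixed ties", {
  roster <- sprintf("S%02d", 1:12)
  v <- fake_validated(c("P1:10", "P2:20", "P3:30"),
                      list(roster, roster[1:11], roster[1:10]),
                      intensity = c(1e6, 5e6, 9e6))
  s <- site_summaries(v, data.frame(sample_id = character(0),
                                    accession = character(0),
                                    site_position = integer(0),
                                    modified_flag = logical(0),
                                    precursor_intensity = numeric(0)),
                      roster)
  r <- rank_by_intensity(s, min_detections = 10L)
  # P3 detected exactly 10 times -> excluded ("more than 10")
  expect_false("P3" %in% r$accession)
  expect_identical(r$accession[r$intensity_rank == 1L], "P2")
  expect_identical(r$accession[r$intensity_rank == 2L], "P1")
  # permuting input rows leaves ranks unchanged
  set.seed(1)
  v2 <- v[sample(nrow(v)), ]
  r2 <- rank_by_intensity(site_summaries(v2, data.frame(
    sample_id = character(0), accession = character(0),
    site_position = integer(0), modified_flag = logical(0),
    precursor_intensity = numeric(0)), roster), min_detections = 10L)
  expect_identical(r[c("accession", "protein_position", "intensity_rank")],
                   r2[c("accession", "protein_position", "intensity_rank")])
})
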