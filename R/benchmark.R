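# Benchmarks with known ground truth: end-to-end mining performance on the
# default cohort, and FDR calibration on null spectra.

#' End-to-end mining benchmark over multiple seeds
#'
#' Runs the full pipeline on the default 12-sample, six-site cohort for each
#' seed and scores the validated sites against the planted truth: per-seed
#' site-level sensitivity, the pooled false-site fraction, and the detection
#' frequency and intensity rank of the ubiquitous high-intensity site.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param ... Passed to [pipeline_config()].
#' @return List with `per_seed` (data.frame) and pooled `sensitivity`,
#'   `false_site_fraction`, `top_site_frequency`, `top_site_rank`.
#' @export
mining_benchmark <- function(seeds = 1:20, ...) {
  rows <- lapply(seeds, function(sd) {
    run <- run_lactylome_pipeline(pipeline_config(seed = sd, ...))
    plan <- run$config$cohort$site_plan
    planted <- paste(plan$accession, plan$position)
    got <- unique(run$validated[c("accession", "protein_position")])
    got_key <- paste(got$accession, got$protein_position)
    top <- run$summaries[run$summaries$accession == plan$accession[1] &
                           run$summaries$protein_position == plan$position[1], ]
    top_rank <- run$ranking$intensity_rank[
      run$ranking$accession == plan$accession[1] &
        run$ranking$protein_position == plan$position[1]]
    data.frame(
      seed = sd,
      n_planted = length(planted),
      n_true = sum(got_key %in% planted),
      n_false = sum(!got_key %in% planted),
      top_site_frequency = if (nrow(top)) top$frequency else 0,
      top_site_rank = if (length(top_rank)) top_rank else NA_integer_
    )
  })
  per_seed <- do.call(rbind, rows)
  list(
    per_seed = per_seed,
    sensitivity = sum(per_seed$n_true) / sum(per_seed$n_planted),
    false_site_fraction = sum(per_seed$n_false) /
      max(1L, sum(per_seed$n_true) + sum(per_seed$n_false)),
    top_site_frequency = mean(per_seed$top_site_frequency),
    top_site_rank = mean(per_seed$top_site_rank)
  )
}

#' FDR calibration on null spectra
#'
#' Simulates spectra whose fragment content comes from held-out reversed
#' ("decoy-side") sequences occurring in neither the target nor the decoy
#' database, with precursor masses drawn from the database's own candidate
#' mass distribution so every spectrum is scored. No match can be true, and
#' target and decoy candidates are exchangeable, so the fraction of target
#' PSMs accepted at the q-value threshold is bounded by the nominal FDR level
#' up to binomial sampling error.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param q_threshold Acceptance threshold (default 0.01).
#' @param n_null_spectra Null spectra simulated per seed.
#' @return List with per-seed counts, the pooled `accepted_fraction`, the
#'   pooled target-PSM count `n_target_psms`, and the implied binomial
#'   standard error `binom_se` at the nominal level.
#' @export
fdr_null_calibration <- function(seeds = 1:20, q_threshold = 0.01,
                                 n_null_spectra = 300L) {
  index <- build_candidate_index(example_cohort_spec(seed = 1)$proteins)
  proton <- 1.007276466621
  rows <- lapply(seeds, function(sd) {
    set.seed(sd)
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    held_out <- vapply(1:4, function(i) {
      paste(sample(aa, 60, replace = TRUE), collapse = "")
    }, character(1))
    rev_seq <- vapply(held_out, function(s) {
      paste(rev(strsplit(s, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
    peps <- digest_proteins(
      data.frame(accession = paste0("NULL", seq_along(rev_seq)),
                 sequence = rev_seq),
      digest_spec(max_missed = 2L, specificity = "semi",
                  min_length = 7L, max_length = 30L))
    pick_pep <- sample(nrow(peps), n_null_spectra, replace = TRUE)
    pick_mass <- sample(nrow(index$forms), n_null_spectra, replace = TRUE)
    spectra <- lapply(seq_len(n_null_spectra), function(i) {
      s <- simulate_spectrum(
        peptide_form(peps$sequence[pick_pep[i]], charge = 2L),
        sim_params(), scan_id = sprintf("n%04d", i))
      # precursor from the database mass distribution, jittered within ppm
      m <- index$forms$mass[pick_mass[i]] *
        (1 + stats::runif(1, -3e-6, 3e-6))
      s$precursor_mz <- (m + 2 * proton) / 2
      s
    })
    psms <- search_spectra(spectra, index)
    if (is.null(psms) || !nrow(psms)) {
      return(data.frame(seed = sd, n_target = 0L, n_accepted = 0L))
    }
    psms <- suppressWarnings(estimate_fdr(psms))
    data.frame(seed = sd, n_target = nrow(psms),
               n_accepted = sum(psms$q_value <= q_threshold))
  })
  per_seed <- do.call(rbind, rows)
  n <- sum(per_seed$n_target)
  list(per_seed = per_seed,
       n_target_psms = n,
       accepted_fraction = if (n) sum(per_seed$n_accepted) / n else NA_real_,
       binom_se = if (n) sqrt(q_threshold * (1 - q_threshold) / n) else NA_real_)
}
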