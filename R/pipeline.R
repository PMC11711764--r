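# End-to-end orchestration: simulate -> digest -> search -> validate ->
# summarize -> conserve, with persisted intermediates and a run report.

#' Tolerance presets
#'
#' The four search tolerance regimes used across dataset types:
#' `meltome_5ppm_0.02` (5 ppm / 0.02 Da), `tissues_10ppm_0.05`
#' (10 ppm / 0.05 Da), `species_7ppm_0.02` (7 ppm / 0.02 Da) and
#' `inhouse_10ppm_0.02` (10 ppm / 0.02 Da, the default).
#'
#' @return Named list of `list(precursor_ppm, fragment_tol)`.
#' @export
tolerance_presets <- function() {
  list(
    meltome_5ppm_0.02 = list(precursor_ppm = 5, fragment_tol = 0.02),
    tissues_10ppm_0.05 = list(precursor_ppm = 10, fragment_tol = 0.05),
    species_7ppm_0.02 = list(precursor_ppm = 7, fragment_tol = 0.02),
    inhouse_10ppm_0.02 = list(precursor_ppm = 10, fragment_tol = 0.02)
  )
}

#' Pipeline configuration
#'
#' @param cohort A [cohort_spec()]; default [example_cohort_spec()] with the
#'   given seed.
#' @param preset Tolerance preset name (see [tolerance_presets()]).
#' @param fdr_q PSM q-value threshold (default 0.01).
#' @param ascore_min AScore threshold; sites must exceed it (default 20).
#' @param cycim_tol Diagnostic-ion m/z tolerance in Da (default 0.02).
#' @param min_detections Strict detection-count floor for the intensity
#'   ranking (default 10).
#' @param digest A [digest_spec()] used for the search database.
#' @param homologs Optional homolog data.frame for the conservation stage
#'   (`accession`, `sequence`), reference first.
#' @param homolog_site Reference site for conservation mapping.
#' @param n_boot Bootstrap replicates for the conservation stage.
#' @param output_dir Directory for persisted intermediates, or `NULL` to keep
#'   everything in memory.
#' @param seed Master seed; also seeds the cohort simulation when `cohort` is
#'   not supplied.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, preset = "inhouse_10ppm_0.02",
                            fdr_q = 0.01, ascore_min = 20, cycim_tol = 0.02,
                            min_detections = 10L,
                            digest = digest_spec(),
                            homologs = NULL, homolog_site = NULL,
                            n_boot = 200L, output_dir = NULL, seed = 1L) {
  presets <- tolerance_presets()
  if (!preset %in% names(presets)) {
    stop("unknown preset: ", preset, " (expected one of ",
         paste(names(presets), collapse = ", "), ")")
  }
  stopifnot(fdr_q >= 0, ascore_min >= 0, cycim_tol > 0)
  if (is.null(cohort)) cohort <- example_cohort_spec(seed = seed)
  structure(list(cohort = cohort, preset = preset,
                 precursor_ppm = presets[[preset]]$precursor_ppm,
                 fragment_tol = presets[[preset]]$fragment_tol,
                 fdr_q = fdr_q, ascore_min = ascore_min,
                 cycim_tol = cycim_tol,
                 min_detections = as.integer(min_detections),
                 digest = digest, homologs = homologs,
                 homolog_site = homolog_site, n_boot = as.integer(n_boot),
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full lactylation-mining pipeline
#'
#' Simulates (or accepts) a cohort, builds the target-decoy index, searches
#' all spectra, controls FDR, applies the AScore and CycIm validation gates,
#' summarizes sites across the cohort, and (optionally) assesses cross-species
#' conservation. Fully reproducible from the configuration, seed included.
#'
#' @param config A [pipeline_config()].
#' @return List with `cohort`, `psms`, `validated`, `summaries`, `ranking`,
#'   `conservation` (or `NULL`), and `report` (gate-chain counts, monotone
#'   non-increasing along the chain).
#' @export
run_lactylome_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- simulate_cohort(config$cohort)

  index <- build_candidate_index(
    cohort$proteins, spec = config$digest,
    precursor_ppm = config$precursor_ppm,
    fragment_tol = config$fragment_tol
  )
  psms <- search_spectra(cohort$spectra, index)
  psms <- estimate_fdr(psms)
  validated <- validate_sites(
    psms, cohort$spectra, fdr_q = config$fdr_q,
    ascore_min = config$ascore_min, cycim_tol = config$cycim_tol,
    fragment_tol = config$fragment_tol
  )
  gate <- attr(validated, "report")
  summaries <- site_summaries(validated, cohort$quant, cohort$samples)
  ranking <- rank_by_intensity(summaries, config$min_detections)

  conservation <- NULL
  if (!is.null(config$homologs)) {
    conservation <- conservation_report(
      config$homologs, reference_site = config$homolog_site,
      n_boot = config$n_boot, seed = config$seed
    )
  }

  report <- list(
    seed = config$seed, preset = config$preset,
    n_spectra = length(cohort$spectra),
    n_psms = unname(gate["n_psms"]),
    n_lactyl_psms = unname(gate["n_lactyl"]),
    n_fdr_pass = unname(gate["n_fdr_pass"]),
    n_ascore_pass = unname(gate["n_ascore_pass"]),
    n_flank_pass = unname(gate["n_flank_pass"]),
    n_cycim_present = unname(gate["n_cycim_present"]),
    n_cycim_absent = unname(gate["n_cycim_absent"]),
    n_cycim_undetectable = unname(gate["n_cycim_undetectable"]),
    n_validated_psms = unname(gate["n_validated"]),
    n_sites = if (nrow(summaries)) nrow(summaries) else 0L
  )

  out <- list(cohort = cohort, psms = psms, validated = validated,
              summaries = summaries, ranking = ranking,
              conservation = conservation, report = report,
              config = config)
  class(out) <- "lactylome_run"

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(config$output_dir, "cohort"))
    utils::write.table(psms, file.path(config$output_dir, "psms.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(validated)) {
      utils::write.table(validated,
                         file.path(config$output_dir, "validated_sites.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (nrow(summaries)) {
      flat <- summaries[setdiff(names(summaries), "occupancy_by_sample")]
      utils::write.table(flat,
                         file.path(config$output_dir, "site_summaries.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(conservation)) {
      ape::write.tree(conservation$tree,
                      file.path(config$output_dir, "conservation.nwk"))
      utils::write.table(conservation$mapped_sites,
                         file.path(config$output_dir, "mapped_sites.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.lactylome_run <- function(x, ...) {
  r <- x$report
  cat("<lactylome_run>\n")
  cat(sprintf("  spectra %d -> PSMs %d -> lactyl %d -> q<=%.3g %d -> AScore %d -> flank %d -> CycIm %d\n",
              r$n_spectra, r$n_psms, r$n_lactyl_psms, x$config$fdr_q,
              r$n_fdr_pass, r$n_ascore_pass, r$n_flank_pass,
              r$n_validated_psms))
  cat(sprintf("  validated sites: %d\n", r$n_sites))
  invisible(x)
}
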