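# Synthetic-data generation: centroided HCD spectra of (lactylated) tryptic
# peptides and multi-sample cohorts with known per-site occupancy, intensity
# and localization ground truth. Every downstream stage is testable against
# the truth these functions emit.

#' Simulation parameters for synthetic spectra
#'
#' @param fragment_sigma Gaussian m/z jitter applied to fragment peaks (Da).
#'   Default 0.003 Da, consistent with high-resolution Orbitrap MS2.
#' @param fragment_detection_prob Probability that each theoretical b/y ion
#'   yields an observed peak.
#' @param intensity_lognormal_mu,intensity_lognormal_sigma Log-scale location
#'   and spread of fragment peak intensities.
#' @param n_noise_peaks Number of uniform random noise peaks per spectrum.
#' @param noise_mz_range Length-2 numeric, m/z interval for noise peaks.
#' @param cycim_emission_prob Probability that a lactylated precursor emits
#'   the CycIm diagnostic peak.
#' @param first_mass Acquisition low-mass cutoff (Da). Default 110 so the
#'   CycIm region (m/z 156.10) is observable.
#' @param hostile Logical. By default noise peaks are kept at least 0.05 Da
#'   away from true fragment and diagnostic m/z so oracle tests are
#'   unambiguous; `hostile = TRUE` lifts this guard.
#' @param seed Integer seed controlling cohort generation.
#' @return A `sim_params` list.
#' @export
sim_params <- function(fragment_sigma = 0.003,
                       fragment_detection_prob = 0.9,
                       intensity_lognormal_mu = 9,
                       intensity_lognormal_sigma = 0.6,
                       n_noise_peaks = 20L,
                       noise_mz_range = c(110, 1400),
                       cycim_emission_prob = 0.95,
                       first_mass = 110,
                       hostile = FALSE,
                       seed = 1L) {
  stopifnot(fragment_sigma >= 0,
            fragment_detection_prob >= 0, fragment_detection_prob <= 1,
            cycim_emission_prob >= 0, cycim_emission_prob <= 1,
            length(noise_mz_range) == 2L,
            noise_mz_range[2] > noise_mz_range[1])
  structure(as.list(environment()), class = "sim_params")
}

# Does a peptide form carry a lactyl (+72.0211) on a lysine?
.has_lactyl <- function(p) {
  if (!length(p$mods)) return(FALSE)
  pos <- as.integer(names(p$mods))
  deltas <- vapply(p$mods, `[[`, numeric(1), "delta")
  res <- strsplit(p$sequence, "")[[1]][pos]
  any(res == "K" & abs(deltas - formula_mass("C3H4O2")) < 1e-3)
}

#' Simulate one centroided MS/MS spectrum
#'
#' Emits singly-charged b/y peaks (each retained with
#' `fragment_detection_prob`, m/z jittered, lognormal intensities), the CycIm
#' diagnostic peak with `cycim_emission_prob` iff the form carries a lactyl
#' modification, and uniform noise peaks. Peaks below `first_mass` are
#' removed. Draws from the current RNG stream; fix the seed outside (or via
#' `seed`) for reproducibility.
#'
#' @param p A [peptide_form()] with charge set.
#' @param params A [sim_params()].
#' @param scan_id,sample_id Identifiers stamped on the spectrum.
#' @param precursor_intensity Precursor intensity recorded on the spectrum.
#' @param seed Optional integer; if given, a local seed is set first.
#' @return A [spectrum()].
#' @export
simulate_spectrum <- function(p, params = sim_params(), scan_id = "scan1",
                              sample_id = "S1", precursor_intensity = 1e6,
                              seed = NULL) {
  stopifnot(inherits(p, "peptide_form"), nchar(p$sequence) >= 2L,
            !is.na(p$charge))
  if (!is.null(seed)) set.seed(seed)
  theo <- fragment_ions(p, 1L)$mz
  keep <- stats::runif(length(theo)) < params$fragment_detection_prob
  mz <- theo[keep] + stats::rnorm(sum(keep), 0, params$fragment_sigma)
  inten <- stats::rlnorm(sum(keep), params$intensity_lognormal_mu,
                         params$intensity_lognormal_sigma)

  protected <- theo
  if (.has_lactyl(p) &&
      stats::runif(1) < params$cycim_emission_prob) {
    ci <- cycim_ion()
    mz <- c(mz, ci$mz + stats::rnorm(1, 0, params$fragment_sigma))
    inten <- c(inten, stats::rlnorm(1, params$intensity_lognormal_mu,
                                    params$intensity_lognormal_sigma))
  }
  protected <- c(protected, cycim_ion()$mz)

  if (params$n_noise_peaks > 0L) {
    noise <- stats::runif(params$n_noise_peaks, params$noise_mz_range[1],
                          params$noise_mz_range[2])
    if (!params$hostile) {
      # keep noise clear of true signal so tests have an unambiguous oracle
      for (it in 1:50) {
        bad <- vapply(noise, function(x) any(abs(protected - x) < 0.05),
                      logical(1))
        if (!any(bad)) break
        noise[bad] <- stats::runif(sum(bad), params$noise_mz_range[1],
                                   params$noise_mz_range[2])
      }
    }
    mz <- c(mz, noise)
    inten <- c(inten, stats::rlnorm(params$n_noise_peaks,
                                    params$intensity_lognormal_mu - 1.5,
                                    params$intensity_lognormal_sigma))
  }

  prec_mz <- (peptide_mass(p) + p$charge * 1.007276466621) / p$charge
  spectrum(scan_id, sample_id, prec_mz, p$charge, precursor_intensity,
           mz, inten, first_mass = params$first_mass)
}

#' Cohort specification for the synthetic lactylproteome
#'
#' Describes a multi-sample cohort with planted lactylation sites. Defaults
#' emulate a 12-cell-line panel with per-site occupancies and lognormal
#' precursor intensities.
#'
#' @param proteins data.frame with `accession`, `sequence`.
#' @param site_plan data.frame with columns `accession`, `position` (1-based
#'   protein coordinate of a lysine), `occupancy` in \[0,1\], `present_in`
#'   (number of samples carrying the site; `NA` = all) and `base_intensity`.
#' @param n_samples Number of cohort samples (default 12).
#' @param spectra_per_peptide MS/MS spectra emitted per peptide form per
#'   sample.
#' @param split `"deterministic"` (expected-value intensity split between
#'   modified and unmodified forms; occupancy recovery is then exact) or
#'   `"binomial"` (sampled over `n_copies` precursor copies).
#' @param n_copies Precursor copies for the binomial split mode.
#' @param sim A [sim_params()].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(proteins, site_plan, n_samples = 12L,
                        spectra_per_peptide = 2L,
                        split = c("deterministic", "binomial"),
                        n_copies = 50L, sim = sim_params()) {
  split <- match.arg(split)
  stopifnot(n_samples >= 1L, spectra_per_peptide >= 1L)
  if (any(site_plan$occupancy < 0 | site_plan$occupancy > 1)) {
    stop("site occupancy outside [0,1]")
  }
  for (i in seq_len(nrow(site_plan))) {
    seqstr <- proteins$sequence[proteins$accession == site_plan$accession[i]]
    if (!length(seqstr)) stop("site accession not in protein set")
    if (substring(seqstr, site_plan$position[i], site_plan$position[i]) != "K") {
      stop("planned site is not a lysine: ", site_plan$accession[i], ":",
           site_plan$position[i])
    }
  }
  if (is.null(site_plan$present_in)) site_plan$present_in <- NA_integer_
  if (is.null(site_plan$base_intensity)) site_plan$base_intensity <- 1e6
  structure(list(proteins = proteins, site_plan = site_plan,
                 n_samples = as.integer(n_samples),
                 spectra_per_peptide = as.integer(spectra_per_peptide),
                 split = split, n_copies = as.integer(n_copies), sim = sim),
            class = "cohort_spec")
}

# Host peptide for a planted site: the shortest tryptic peptide (<=2 missed
# cleavages) holding the lysine at an internal position, i.e. the
# missed-cleavage peptide a lactyl-blocked K produces.
.host_peptide <- function(protein, position) {
  dg <- digest(protein, digest_spec(max_missed = 2L, specificity = "full"))
  cand <- dg[dg$start <= position & dg$end > position, , drop = FALSE]
  if (!nrow(cand)) stop("no host peptide covers site ", position)
  cand <- cand[order(cand$missed, cand$end - cand$start, cand$start), ]
  cand[1L, ]
}

#' Simulate a multi-sample cohort with planted lactylation sites
#'
#' For each planted site and carrying sample, the precursor intensity is split
#' between the lactylated and unmodified peptide forms according to the
#' planned occupancy, MS/MS spectra are simulated for each form, and the
#' complete ground truth (per-spectrum peptide form, per-site-and-sample
#' occupancy and intensity split) is recorded. Generation is a pure function
#' of the spec, including its seed.
#'
#' @param spec A [cohort_spec()].
#' @return A `lactyl_cohort` list with elements `spectra` (list of
#'   [spectrum()]), `quant` (precursor quantitation data.frame), `truth`
#'   (per-spectrum truth), `site_truth` (per site and sample), `samples`,
#'   `proteins`, `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$sim$seed)
  samples <- sprintf("S%02d", seq_len(spec$n_samples))
  spectra <- list(); truth <- list(); quant <- list(); site_truth <- list()
  scan_counter <- 0L
  lac <- default_modifications()$lactyl

  for (i in seq_len(nrow(spec$site_plan))) {
    plan <- spec$site_plan[i, ]
    prot <- spec$proteins[spec$proteins$accession == plan$accession, ,
                          drop = FALSE]
    host <- .host_peptide(prot, plan$position)
    pep_site <- plan$position - host$start + 1L
    n_present <- if (is.na(plan$present_in)) spec$n_samples else plan$present_in
    for (s in seq_len(n_present)) {
      sid <- samples[s]
      total <- plan$base_intensity * stats::rlnorm(1, 0, 0.3)
      occ <- plan$occupancy
      if (spec$split == "binomial") {
        k <- stats::rbinom(1, spec$n_copies, occ)
        occ_real <- k / spec$n_copies
      } else {
        occ_real <- occ
      }
      int_mod <- occ_real * total
      int_unmod <- (1 - occ_real) * total
      site_truth[[length(site_truth) + 1L]] <- data.frame(
        accession = plan$accession, position = plan$position,
        sample_id = sid, occupancy = occ_real, planned_occupancy = occ,
        intensity_mod = int_mod, intensity_unmod = int_unmod,
        stringsAsFactors = FALSE
      )
      forms <- list()
      if (int_mod > 0) {
        mods <- stats::setNames(list(lac), pep_site)
        forms$modified <- list(
          form = peptide_form(host$sequence, mods, charge = 2L,
                              is_protein_nterm = host$start == 1L),
          intensity = int_mod, modified = TRUE)
      }
      if (int_unmod > 0) {
        forms$unmodified <- list(
          form = peptide_form(host$sequence, charge = 2L,
                              is_protein_nterm = host$start == 1L),
          intensity = int_unmod, modified = FALSE)
      }
      for (f in forms) {
        quant[[length(quant) + 1L]] <- data.frame(
          sample_id = sid, accession = plan$accession,
          site_position = plan$position, modified_flag = f$modified,
          peptide = host$sequence, precursor_intensity = f$intensity,
          stringsAsFactors = FALSE
        )
        for (r in seq_len(spec$spectra_per_peptide)) {
          scan_counter <- scan_counter + 1L
          scan_id <- sprintf("scan%05d", scan_counter)
          sp <- simulate_spectrum(f$form, spec$sim, scan_id = scan_id,
                                  sample_id = sid,
                                  precursor_intensity = f$intensity)
          spectra[[scan_id]] <- sp
          truth[[length(truth) + 1L]] <- data.frame(
            scan_id = scan_id, sample_id = sid, accession = plan$accession,
            position = plan$position, peptide = host$sequence,
            peptide_site = if (f$modified) pep_site else NA_integer_,
            modified = f$modified, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  structure(list(
    spectra = spectra,
    quant = do.call(rbind, quant),
    truth = do.call(rbind, truth),
    site_truth = do.call(rbind, site_truth),
    samples = samples, proteins = spec$proteins, spec = spec
  ), class = "lactyl_cohort")
}

#' Persist a simulated cohort to disk
#'
#' Writes one MGF per sample, the precursor quantitation TSV, the protein
#' FASTA and the ground truth as JSON.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in cohort$samples) {
    sub <- Filter(function(s) s$sample_id == sid, cohort$spectra)
    if (length(sub)) write_mgf(sub, file.path(dir, paste0(sid, ".mgf")))
  }
  utils::write.table(cohort$quant, file.path(dir, "quant.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fasta(cohort$proteins, file.path(dir, "proteins.fasta"))
  jsonlite::write_json(
    list(truth = cohort$truth, site_truth = cohort$site_truth),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE
  )
  invisible(dir)
}

#' The default benchmark cohort specification
#'
#' A 12-sample cohort with six planted lactyl sites across four synthetic
#' proteins. Site `SYN1:11` is ubiquitous (all 12 samples), high intensity and
#' at occupancy 0.50 — the pattern of a dominant, fully penetrant site; the
#' remaining sites vary in prevalence, occupancy and abundance. Protein
#' sequences are fixed, hand-designed concatenations of tryptic segments so
#' each planted lysine sits inside a well-formed missed-cleavage host peptide
#' (one of them with a second, decoy lysine to exercise site localization).
#'
#' @param seed Integer seed for the simulation.
#' @param ... Passed on to [sim_params()].
#' @param split,spectra_per_peptide Passed to [cohort_spec()].
#' @return A [cohort_spec()].
#' @export
example_cohort_spec <- function(seed = 1L, ...,
                                split = "deterministic",
                                spectra_per_peptide = 2L) {
  proteins <- data.frame(
    accession = c("SYN1", "SYN2", "SYN3", "SYN4"),
    sequence = c(
      paste0("MSDFLTR", "AAEKVLSGR", "TQLVDDLSK", "GFLNPEAVR"),
      paste0("MQTPLNK", "GVTKAEILDHR", "SSYNLVTK", "EAGLKDVFR"),
      paste0("MADVLQR", "TLHEKGSVAYK", "NPDQFVLR"),
      paste0("MEGVPSR", "LDKAGFTNR", "VVSPELAGK", "HQTLDNKVEGR")
    ),
    stringsAsFactors = FALSE
  )
  site_plan <- data.frame(
    accession = c("SYN1", "SYN2", "SYN2", "SYN3", "SYN4", "SYN4"),
    position = c(11L, 11L, 31L, 12L, 10L, 32L),
    occupancy = c(0.50, 0.30, 0.40, 0.70, 0.20, 0.90),
    present_in = c(NA, 9L, 6L, 12L, 6L, 3L),
    base_intensity = c(5e6, 1e6, 6e5, 8e5, 9e5, 4e5)
  )
  cohort_spec(proteins, site_plan, n_samples = 12L,
              spectra_per_peptide = spectra_per_peptide, split = split,
              sim = sim_params(seed = seed, ...))
}

#' Simulate a homolog family with a conserved lysine (synthetic stand-in)
#'
#' Generates a reference protein and homologs at increasing evolutionary
#' distance by random point substitution; the planted lysine column is never
#' touched, emulating a site conserved from mammals to insects. No indels are
#' introduced. The sequences are synthetic: they stand in for curated homolog
#' sets, they are not real orthologs.
#'
#' @param seed Integer seed.
#' @param length Protein length (default 180).
#' @param site Position of the conserved lysine.
#' @param rates Named per-homolog substitution probabilities per position;
#'   names become accessions. The reference is emitted at rate 0.
#' @return data.frame with `accession`, `sequence` (reference first).
#' @export
simulate_homolog_family <- function(seed = 1L, length = 180L, site = 97L,
                                    rates = c(homolog_A = 0.04,
                                              homolog_B = 0.07,
                                              homolog_C = 0.30,
                                              homolog_D = 0.35)) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHILMNPQRSTVWY", "")[[1]]  # K only where planted
  ref <- sample(aa, length, replace = TRUE)
  ref[site] <- "K"
  seqs <- c(reference = paste(ref, collapse = ""))
  for (nm in names(rates)) {
    hom <- ref
    mut <- which(stats::runif(length) < rates[[nm]] & seq_len(length) != site)
    for (j in mut) hom[j] <- sample(setdiff(aa, hom[j]), 1L)
    seqs[nm] <- paste(hom, collapse = "")
  }
  data.frame(accession = names(seqs), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}
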