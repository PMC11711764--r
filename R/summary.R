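# Cohort-level site summaries: detection frequency across samples, intensity
# ranking, and modification occupancy from precursor quantitation.

#' Per-site detection frequency across a cohort
#'
#' frequency = 100 * (#samples with at least one validated PSM for the site)
#' / (#samples in the roster).
#'
#' @param validated Validated-site data.frame ([validate_sites()] output).
#' @param samples Character vector: the full cohort sample roster.
#' @return data.frame with `accession`, `protein_position`, `n_detected`,
#'   `n_samples`, `frequency` (percent).
#' @export
detection_frequency <- function(validated, samples) {
  stopifnot(length(samples) >= 1L)
  if (!nrow(validated)) {
    return(data.frame(accession = character(0), protein_position = integer(0),
                      n_detected = integer(0), n_samples = integer(0),
                      frequency = numeric(0)))
  }
  key <- unique(validated[c("accession", "protein_position")])
  key <- key[order(key$accession, key$protein_position), , drop = FALSE]
  key$n_detected <- vapply(seq_len(nrow(key)), function(i) {
    hits <- validated$accession == key$accession[i] &
      validated$protein_position == key$protein_position[i]
    length(intersect(unique(validated$sample_id[hits]), samples))
  }, integer(1))
  key$n_samples <- length(samples)
  key$frequency <- 100 * key$n_detected / key$n_samples
  rownames(key) <- NULL
  key
}

#' Occupancy of a site in one sample (or pooled)
#'
#' occupancy = sum of lactylated-peptide intensity at the site divided by the
#' sum of lactylated plus unmodified intensity at the site; `NA` when the
#' denominator is zero. Peptides with missed cleavages covering the site are
#' pooled by their modified flag.
#'
#' @param quant Quantitation data.frame with columns `sample_id`, `accession`,
#'   `site_position`, `modified_flag`, `precursor_intensity`.
#' @param accession,position The site.
#' @param sample Sample id, or `NULL` to pool all samples.
#' @return Occupancy in \[0,1\] or `NA`.
#' @export
site_occupancy <- function(quant, accession, position, sample = NULL) {
  if (any(quant$precursor_intensity < 0)) stop("negative intensity")
  sel <- quant$accession == accession & quant$site_position == position
  if (!is.null(sample)) sel <- sel & quant$sample_id == sample
  mod <- sum(quant$precursor_intensity[sel & quant$modified_flag])
  unmod <- sum(quant$precursor_intensity[sel & !quant$modified_flag])
  if (mod + unmod == 0) return(NA_real_)
  mod / (mod + unmod)
}

#' Build per-site cohort summaries
#'
#' Combines detection frequency, summed validated precursor intensity, and
#' per-sample plus median occupancy into one table.
#'
#' @param validated Validated-site data.frame.
#' @param quant Quantitation data.frame (see [site_occupancy()]).
#' @param samples Cohort sample roster.
#' @return data.frame, one row per site, with an `occupancy_by_sample` list
#'   column and `median_occupancy`.
#' @export
site_summaries <- function(validated, quant, samples) {
  freq <- detection_frequency(validated, samples)
  if (!nrow(freq)) return(freq)
  freq$summed_intensity <- vapply(seq_len(nrow(freq)), function(i) {
    hits <- validated$accession == freq$accession[i] &
      validated$protein_position == freq$protein_position[i]
    sum(validated$precursor_intensity[hits])
  }, numeric(1))
  occ <- lapply(seq_len(nrow(freq)), function(i) {
    vapply(samples, function(sid) {
      site_occupancy(quant, freq$accession[i], freq$protein_position[i], sid)
    }, numeric(1))
  })
  freq$occupancy_by_sample <- occ
  freq$median_occupancy <- vapply(occ, function(v) {
    stats::median(v, na.rm = TRUE)
  }, numeric(1))
  freq
}

#' Rank sites by summed intensity
#'
#' Sites detected more than `min_detections` times are ranked by summed
#' precursor intensity, descending (the "detection frequency of more than 10
#' times" reporting convention — strictly more). Ties break by accession then
#' position, so the ranking is invariant to input order.
#'
#' @param summaries [site_summaries()] output.
#' @param min_detections Strict lower bound on `n_detected` (default 10).
#' @return The filtered summaries with an `intensity_rank` column, rank 1
#'   first.
#' @export
rank_by_intensity <- function(summaries, min_detections = 10L) {
  keep <- summaries[summaries$n_detected > min_detections, , drop = FALSE]
  if (!nrow(keep)) {
    keep$intensity_rank <- integer(0)
    return(keep)
  }
  ord <- order(-keep$summed_intensity, keep$accession, keep$protein_position)
  keep <- keep[ord, , drop = FALSE]
  keep$intensity_rank <- seq_len(nrow(keep))
  rownames(keep) <- NULL
  keep
}
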