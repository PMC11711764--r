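# The validation gate: AScore localization of the lactyl site, CycIm
# diagnostic-ion confirmation, and the composite FDR -> AScore -> CycIm
# filter producing validated sites.

.lactyl_delta <- function() formula_mass("C3H4O2")

# Rows of a parsed mod string that are lactyl-on-lysine.
.lactyl_rows <- function(sequence, md) {
  res <- strsplit(sequence, "")[[1]]
  which(res[md$pos] == "K" & abs(md$delta - .lactyl_delta()) < 1e-3)
}

#' AScore site localization of a lactyl modification
#'
#' For peak depths 1..10 (top-d most intense peaks per 100 Da window), the two
#' best-scoring placements of the lactyl group over the peptide's lysines are
#' compared on their site-determining ions: AScore is the difference of
#' -10*log10 binomial survival probabilities of the matched site-determining
#' ion counts, taken at the most discriminating depth (per-trial probability
#' `d * 2 * fragment_tol / 100`). Peptides with a single candidate lysine are
#' force-localized and reported with the sentinel score 1000.
#'
#' @param sequence Peptide sequence.
#' @param mods Modification string (as in PSM output, e.g. `"K5+72.021129"`);
#'   must contain exactly one lactyl; other modifications are held fixed.
#' @param s The matched [spectrum()].
#' @param fragment_tol Fragment tolerance in Da (default 0.02).
#' @param max_depth Largest peak depth considered (default 10).
#' @return List with `best_site`, `runner_up_site`, `ascore`, `depth_used`.
#' @export
ascore <- function(sequence, mods, s, fragment_tol = 0.02, max_depth = 10L) {
  md <- .parse_mod_string(mods)
  li <- .lactyl_rows(sequence, md)
  if (length(li) != 1L) {
    stop("AScore requires exactly one lactyl modification on the peptide")
  }
  res <- strsplit(sequence, "")[[1]]
  cands <- which(res == "K")
  if (!length(cands)) stop("no candidate lysine for localization")
  others <- md[-li, , drop = FALSE]
  cands <- setdiff(cands, others$pos)

  placement_string <- function(site) {
    pos <- c(others$pos, site)
    delta <- c(others$delta, .lactyl_delta())
    ord <- order(pos)
    paste(sprintf("%s%d%+0.6f", res[pos[ord]], pos[ord], delta[ord]),
          collapse = ";")
  }

  if (length(cands) == 1L) {
    return(list(best_site = cands, runner_up_site = NA_integer_,
                ascore = 1000, depth_used = NA_integer_))
  }

  ladders <- lapply(cands, function(k) .ladder_mz(sequence, placement_string(k)))
  depths <- seq_len(max_depth)
  peaks_by_depth <- lapply(depths, function(d) {
    sort(s$mz[.filter_peak_depth(s$mz, s$intensity, d)])
  })

  # whole-ladder score per placement per depth; ranking sums over depths
  totals <- numeric(length(cands))
  for (j in seq_along(cands)) {
    n <- length(ladders[[j]])
    for (d in depths) {
      k <- sum(.count_matches(ladders[[j]], peaks_by_depth[[d]], fragment_tol))
      totals[j] <- totals[j] + binomial_match_score(k, n, d * 2 * fragment_tol / 100)
    }
  }
  ord <- order(-totals, cands)
  a <- ord[1L]; b <- ord[2L]

  sd_a <- setdiff_tol(ladders[[a]], ladders[[b]])
  sd_b <- setdiff_tol(ladders[[b]], ladders[[a]])
  n_sd <- length(sd_a)
  diffs <- vapply(depths, function(d) {
    p <- d * 2 * fragment_tol / 100
    ka <- sum(.count_matches(sd_a, peaks_by_depth[[d]], fragment_tol))
    kb <- sum(.count_matches(sd_b, peaks_by_depth[[d]], fragment_tol))
    binomial_match_score(ka, n_sd, p) - binomial_match_score(kb, length(sd_b), p)
  }, numeric(1))

  if (max(diffs) >= -min(diffs)) {
    list(best_site = cands[a], runner_up_site = cands[b],
         ascore = max(diffs), depth_used = which.max(diffs))
  } else {
    list(best_site = cands[b], runner_up_site = cands[a],
         ascore = -min(diffs), depth_used = which.min(diffs))
  }
}

# m/z values of x with no counterpart in y (within 1e-6 Da) — the
# site-determining ions between two placements.
setdiff_tol <- function(x, y, tol = 1e-6) {
  x[vapply(x, function(v) all(abs(y - v) > tol), logical(1))]
}

#' Detect the CycIm diagnostic ion in a spectrum
#'
#' Present iff a peak lies within `tol` of the diagnostic m/z and reaches the
#' relative-intensity floor; undetectable (rather than absent) when the
#' acquisition first mass is above the diagnostic ion, so the spectrum could
#' never have recorded it.
#'
#' @param s A [spectrum()].
#' @param diagnostic A diagnostic ion, default [cycim_ion()].
#' @param tol Absolute m/z tolerance in Da (default 0.02).
#' @param min_rel_intensity Floor as a fraction of the base peak (default
#'   0.01; set 0 to accept any intensity).
#' @return List with `status` (`"present"`, `"absent"`, `"undetectable"`),
#'   `observed_mz`, `abs_error`, `intensity`, `rel_intensity`.
#' @export
detect_cycim <- function(s, diagnostic = cycim_ion(), tol = 0.02,
                         min_rel_intensity = 0.01) {
  stopifnot(tol > 0)
  if (s$first_mass > diagnostic$mz + tol) {
    return(list(status = "undetectable", observed_mz = NA_real_,
                abs_error = NA_real_, intensity = NA_real_,
                rel_intensity = NA_real_))
  }
  base <- if (length(s$intensity)) max(s$intensity) else NA_real_
  hit <- which(abs(s$mz - diagnostic$mz) <= tol &
                 s$intensity >= min_rel_intensity * base)
  if (!length(hit)) {
    return(list(status = "absent", observed_mz = NA_real_,
                abs_error = NA_real_, intensity = NA_real_,
                rel_intensity = NA_real_))
  }
  best <- hit[which.max(s$intensity[hit])]
  list(status = "present", observed_mz = s$mz[best],
       abs_error = abs(s$mz[best] - diagnostic$mz),
       intensity = s$intensity[best],
       rel_intensity = s$intensity[best] / base)
}

# Matched sequence ions whose backbone break falls within +/-2 residues of
# the site — the testable stand-in for manual MS/MS confirmation.
.flank_ion_count <- function(sequence, mods, site, s, fragment_tol, depth) {
  lad <- fragment_ions(peptide_form_from_string(sequence, mods), 1L)
  L <- nchar(sequence)
  flank <- (lad$series == "b" & lad$index >= site - 2L & lad$index <= site + 1L) |
    (lad$series == "y" & lad$index >= L - site - 1L & lad$index <= L - site + 2L)
  pk <- sort(s$mz[.filter_peak_depth(s$mz, s$intensity, depth)])
  sum(.count_matches(lad$mz[flank], pk, fragment_tol))
}

# Rebuild a peptide_form carrying plain numeric deltas from a mod string.
peptide_form_from_string <- function(sequence, mods) {
  md <- .parse_mod_string(mods)
  res <- strsplit(sequence, "")[[1]]
  ml <- list()
  if (nrow(md)) {
    ml <- lapply(seq_len(nrow(md)), function(i) {
      modification(sprintf("delta%+0.4f", md$delta[i]), "", res[md$pos[i]])
    })
    # carry the numeric delta directly; formula is unknown at this point
    for (i in seq_along(ml)) ml[[i]]$delta <- md$delta[i]
    names(ml) <- md$pos
  }
  peptide_form(sequence, ml, charge = 2L)
}

#' Validate lactyl PSMs into site calls
#'
#' Applies the composite gate chain in order: PSM q-value <= `fdr_q`, AScore >
#' `ascore_min`, at least `min_flank_ions` matched sequence ions flanking the
#' localized site, and the CycIm diagnostic ion present. Peptide-level site
#' positions are mapped to protein coordinates
#' (`protein_position = peptide start + site - 1`). Spectra in which the
#' diagnostic ion is undetectable (first mass above its m/z) are excluded but
#' counted separately.
#'
#' @param psms Target PSMs with q-values ([estimate_fdr()] output).
#' @param spectra Named list of [spectrum()] objects (names = scan ids), or an
#'   unnamed list (scan ids are read from the spectra).
#' @param fdr_q,ascore_min,cycim_tol,min_flank_ions Gate thresholds; defaults
#'   q <= 0.01, AScore > 20, 0.02 Da, 3 ions. A threshold of `fdr_q = 0`
#'   accepts nothing: a zero-tolerance error budget admits no estimated set,
#'   even when every q-value is exactly 0.
#' @param cycim_gate Logical; `FALSE` disables the diagnostic-ion requirement
#'   (for measuring its specificity benefit).
#' @param min_rel_intensity Relative-intensity floor for the CycIm peak.
#' @param fragment_tol,depth Matching parameters, as in the search.
#' @return data.frame of validated sites with a `report` attribute carrying
#'   the gate-chain counts.
#' @export
validate_sites <- function(psms, spectra, fdr_q = 0.01, ascore_min = 20,
                           cycim_tol = 0.02, min_flank_ions = 3L,
                           cycim_gate = TRUE, min_rel_intensity = 0.01,
                           fragment_tol = 0.02, depth = 10L) {
  if (is.null(names(spectra)) || !all(nzchar(names(spectra)))) {
    names(spectra) <- vapply(spectra, `[[`, character(1), "scan_id")
  }
  report <- c(n_psms = 0L, n_lactyl = 0L, n_fdr_pass = 0L, n_ascore_pass = 0L,
              n_flank_pass = 0L, n_cycim_present = 0L, n_cycim_absent = 0L,
              n_cycim_undetectable = 0L, n_validated = 0L)
  out <- list()
  if (is.null(psms) || !nrow(psms)) {
    return(structure(data.frame(), report = report))
  }
  psms <- psms[!psms$is_decoy, , drop = FALSE]
  report["n_psms"] <- nrow(psms)
  diag <- cycim_ion()

  for (i in seq_len(nrow(psms))) {
    row <- psms[i, ]
    md <- .parse_mod_string(row$mods)
    if (length(.lactyl_rows(row$sequence, md)) != 1L) next
    report["n_lactyl"] <- report["n_lactyl"] + 1L
    if (is.na(row$q_value) || row$q_value > fdr_q || fdr_q <= 0) next
    report["n_fdr_pass"] <- report["n_fdr_pass"] + 1L
    s <- spectra[[row$scan_id]]
    if (is.null(s)) stop("spectrum not found for scan ", row$scan_id)

    loc <- ascore(row$sequence, row$mods, s, fragment_tol = fragment_tol)
    if (!(loc$ascore > ascore_min)) next
    report["n_ascore_pass"] <- report["n_ascore_pass"] + 1L

    # re-anchor the lactyl at the localized site for the flank check
    li <- .lactyl_rows(row$sequence, md)
    md2 <- md; md2$pos[li] <- loc$best_site
    res <- strsplit(row$sequence, "")[[1]]
    ord <- order(md2$pos)
    mods2 <- paste(sprintf("%s%d%+0.6f", res[md2$pos[ord]], md2$pos[ord],
                           md2$delta[ord]), collapse = ";")
    if (.flank_ion_count(row$sequence, mods2, loc$best_site, s,
                         fragment_tol, depth) < min_flank_ions) next
    report["n_flank_pass"] <- report["n_flank_pass"] + 1L

    cy <- detect_cycim(s, diag, tol = cycim_tol,
                       min_rel_intensity = min_rel_intensity)
    report[paste0("n_cycim_", cy$status)] <-
      report[paste0("n_cycim_", cy$status)] + 1L
    if (cycim_gate && cy$status != "present") next

    report["n_validated"] <- report["n_validated"] + 1L
    out[[length(out) + 1L]] <- data.frame(
      accession = row$accession,
      protein_position = row$start + loc$best_site - 1L,
      residue = "K", peptide = row$sequence, peptide_site = loc$best_site,
      sample_id = row$sample_id, scan_id = row$scan_id,
      q_value = row$q_value, ascore = loc$ascore,
      cycim_status = cy$status, cycim_error_da = cy$abs_error,
      precursor_intensity = row$precursor_intensity,
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame()
  structure(res, report = report)
}
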