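# Spectrum-to-peptide matching with a windowed binomial scorer and
# target-decoy FDR control.

#' Binomial peak-match score
#'
#' The survival probability of matching at least `k` of `n` theoretical ions
#' when each trial succeeds with probability `p`, expressed as
#' -10*log10 P\[X >= k\]. Used both for PSM scoring and as the AScore
#' building block.
#'
#' @param k Matched ion count(s).
#' @param n Theoretical ion count(s).
#' @param p Per-trial match probability.
#' @return Score(s), >= 0; 0 when `k` = 0.
#' @export
binomial_match_score <- function(k, n, p) {
  logp <- stats::pbinom(k - 1L, n, p, lower.tail = FALSE, log.p = TRUE)
  s <- -10 * logp / log(10)
  s[k <= 0L] <- 0
  pmax(s, 0)
}

# Retain the top-`depth` most intense peaks per 100 Da window.
.filter_peak_depth <- function(mz, intensity, depth) {
  win <- floor(mz / 100)
  keep <- unlist(lapply(split(seq_along(mz), win), function(idx) {
    idx[order(intensity[idx], decreasing = TRUE)][seq_len(min(depth, length(idx)))]
  }), use.names = FALSE)
  sort(keep)
}

# Count theoretical m/z values with an observed peak within tol.
# `peaks_mz` must be sorted ascending.
.count_matches <- function(theo, peaks_mz, tol) {
  if (!length(peaks_mz)) return(rep(FALSE, length(theo)))
  idx <- findInterval(theo, peaks_mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(peaks_mz))
  (abs(peaks_mz[lo] - theo) <= tol) | (abs(peaks_mz[hi] - theo) <= tol)
}

# Theoretical singly-charged b/y ladder for a (sequence, mod-string) pair.
.ladder_mz <- function(sequence, mods_string) {
  md <- .parse_mod_string(mods_string)
  rm <- residue_masses()
  res <- rm[strsplit(sequence, "")[[1]]]
  if (nrow(md)) res[md$pos] <- res[md$pos] + md$delta
  n <- length(res)
  water <- formula_mass("H2O")
  proton <- 1.007276466621
  c(cumsum(res)[-n] + proton, cumsum(rev(res))[-n] + water + proton)
}

# Expand digest peptides into modified forms: fixed mods applied everywhere,
# variable mod combinations capped at `max_var` per peptide.
.expand_forms <- function(peptides, mods, max_var = 3L) {
  fixed <- Filter(function(m) !m$variable, mods)
  variable <- Filter(function(m) m$variable, mods)
  rm <- residue_masses()
  water <- formula_mass("H2O")
  out <- vector("list", nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    seqstr <- peptides$sequence[i]
    res <- strsplit(seqstr, "")[[1]]
    base_mass <- sum(rm[res]) + water
    fixed_pos <- integer(0); fixed_delta <- numeric(0); fixed_lab <- character(0)
    for (m in fixed) {
      pos <- which(res %in% m$targets)
      fixed_pos <- c(fixed_pos, pos)
      fixed_delta <- c(fixed_delta, rep(m$delta, length(pos)))
    }
    opts <- list()
    for (m in variable) {
      if (m$position_rule == "protein-N-term") {
        if (peptides$start[i] == 1L) {
          opts[[length(opts) + 1L]] <- list(pos = 1L, delta = m$delta)
        }
      } else {
        for (pos in setdiff(which(res %in% m$targets), fixed_pos)) {
          opts[[length(opts) + 1L]] <- list(pos = pos, delta = m$delta)
        }
      }
    }
    combos <- list(integer(0))
    if (length(opts)) {
      for (k in seq_len(min(max_var, length(opts)))) {
        cc <- utils::combn(length(opts), k, simplify = FALSE)
        ok <- vapply(cc, function(ix) {
          !anyDuplicated(vapply(opts[ix], `[[`, integer(1), "pos"))
        }, logical(1))
        combos <- c(combos, cc[ok])
      }
    }
    rows <- lapply(combos, function(ix) {
      pos <- c(fixed_pos, vapply(opts[ix], `[[`, integer(1), "pos"))
      delta <- c(fixed_delta, vapply(opts[ix], `[[`, numeric(1), "delta"))
      ord <- order(pos)
      pos <- pos[ord]; delta <- delta[ord]
      ms <- if (length(pos)) {
        paste(sprintf("%s%d%+0.6f", res[pos], pos, delta), collapse = ";")
      } else ""
      data.frame(sequence = seqstr, mods = ms,
                 mass = base_mass + sum(delta), stringsAsFactors = FALSE)
    })
    blk <- do.call(rbind, rows)
    blk$accession <- peptides$accession[i]
    blk$start <- peptides$start[i]
    blk$end <- peptides$end[i]
    out[[i]] <- blk
  }
  res <- do.call(rbind, out)
  res[!duplicated(res[c("sequence", "mods", "accession", "start")]), ,
      drop = FALSE]
}

#' Build a target-decoy candidate index
#'
#' Digests target and reversed-decoy proteins, expands modified peptide
#' forms, and indexes them by neutral mass for precursor-tolerance lookup.
#'
#' @param proteins Target protein data.frame (`accession`, `sequence`).
#' @param spec A [digest_spec()].
#' @param mods Named list of [modification()] objects
#'   (default [default_modifications()]).
#' @param max_var_mods Cap on variable modifications per peptide (default 3).
#' @param precursor_ppm Precursor tolerance in ppm (default 10).
#' @param fragment_tol Fragment tolerance in Da (default 0.02).
#' @param depth Peak depth per 100 Da window used by the scorer (default 10).
#' @param decoys Optional pre-built decoy data.frame; reversed targets by
#'   default.
#' @return A `candidate_index` object.
#' @export
build_candidate_index <- function(proteins, spec = digest_spec(),
                                  mods = default_modifications(),
                                  max_var_mods = 3L, precursor_ppm = 10,
                                  fragment_tol = 0.02, depth = 10L,
                                  decoys = build_decoys(proteins)) {
  tpep <- digest_proteins(proteins, spec)
  dpep <- digest_proteins(decoys, spec)
  tf <- .expand_forms(tpep, mods, max_var_mods)
  df <- .expand_forms(dpep, mods, max_var_mods)
  tf$is_decoy <- FALSE
  df$is_decoy <- TRUE
  forms <- rbind(tf, df)
  forms <- forms[order(forms$mass), , drop = FALSE]
  rownames(forms) <- NULL
  structure(list(forms = forms, precursor_ppm = precursor_ppm,
                 fragment_tol = fragment_tol, depth = as.integer(depth),
                 cache = new.env(parent = emptyenv())),
            class = "candidate_index")
}

#' @export
print.candidate_index <- function(x, ...) {
  cat(sprintf("<candidate_index> %d forms (%d decoy), %g ppm / %g Da, depth %d\n",
              nrow(x$forms), sum(x$forms$is_decoy), x$precursor_ppm,
              x$fragment_tol, x$depth))
  invisible(x)
}

.cached_ladder <- function(index, sequence, mods) {
  key <- paste0(sequence, "|", mods)
  lad <- index$cache[[key]]
  if (is.null(lad)) {
    lad <- .ladder_mz(sequence, mods)
    assign(key, lad, envir = index$cache)
  }
  lad
}

#' Match one spectrum against the candidate index
#'
#' Candidates whose neutral mass lies within the precursor ppm tolerance are
#' scored by counting fragment matches (within the fragment tolerance) among
#' the top-`depth` most intense peaks per 100 Da window; the score is
#' -10*log10 of the binomial survival probability of that many matches at
#' per-trial probability `depth * 2 * fragment_tol / 100`. Ties are broken
#' lexicographically by peptide sequence then modification string.
#'
#' @param s A [spectrum()].
#' @param index A [build_candidate_index()].
#' @return data.frame of scored candidates, best first, or `NULL` when no
#'   candidate lies within the precursor tolerance.
#' @export
match_spectrum <- function(s, index) {
  proton <- 1.007276466621
  z <- s$precursor_charge
  obs <- s$precursor_mz * z - z * proton
  tol <- obs * index$precursor_ppm * 1e-6
  masses <- index$forms$mass
  lo <- findInterval(obs - tol, masses) + 1L
  hi <- findInterval(obs + tol, masses)
  if (hi < lo) return(NULL)
  cand <- index$forms[lo:hi, , drop = FALSE]

  keep <- .filter_peak_depth(s$mz, s$intensity, index$depth)
  pk <- s$mz[keep]
  p_match <- index$depth * 2 * index$fragment_tol / 100

  k <- integer(nrow(cand)); n <- integer(nrow(cand))
  for (j in seq_len(nrow(cand))) {
    lad <- .cached_ladder(index, cand$sequence[j], cand$mods[j])
    n[j] <- length(lad)
    k[j] <- sum(.count_matches(lad, pk, index$fragment_tol))
  }
  cand$n_matched <- k
  cand$n_theoretical <- n
  cand$score <- binomial_match_score(k, n, p_match)
  ord <- order(-cand$score, cand$sequence, cand$mods)
  cand <- cand[ord, , drop = FALSE]
  cand$scan_id <- s$scan_id
  cand$sample_id <- s$sample_id
  cand$precursor_mz <- s$precursor_mz
  cand$precursor_charge <- z
  cand$precursor_intensity <- s$precursor_intensity
  rownames(cand) <- NULL
  cand
}

#' Search a set of spectra
#'
#' Applies [match_spectrum()] to each spectrum and keeps the best hit per
#' spectrum. Spectra with no candidate in tolerance are counted in the
#' `n_unmatched` attribute.
#'
#' @param spectra List of [spectrum()] objects.
#' @param index A [build_candidate_index()].
#' @return data.frame of best PSMs (one row per matched spectrum) with a
#'   `q_value` column initialised to `NA` (see [estimate_fdr()]).
#' @export
search_spectra <- function(spectra, index) {
  hits <- vector("list", length(spectra))
  unmatched <- 0L
  for (i in seq_along(spectra)) {
    m <- match_spectrum(spectra[[i]], index)
    if (is.null(m)) unmatched <- unmatched + 1L else hits[[i]] <- m[1L, ]
  }
  psms <- do.call(rbind, hits)
  if (!is.null(psms)) psms$q_value <- NA_real_
  attr(psms, "n_unmatched") <- unmatched
  psms
}

#' Target-decoy FDR estimation and q-values
#'
#' At each score threshold `t`, FDR(t) = #decoys >= t / max(1, #targets >= t)
#' (separate-count target-decoy); the q-value is the running minimum of FDR
#' over decreasing thresholds. Decoy PSMs are removed from the returned set.
#'
#' @param psms PSM data.frame from [search_spectra()] (must carry `is_decoy`
#'   and `score`).
#' @param keep_decoys Logical; retain decoy rows (with q-values) for
#'   diagnostics.
#' @return The target PSMs with `q_value` filled in, sorted by decreasing
#'   score.
#' @export
estimate_fdr <- function(psms, keep_decoys = FALSE) {
  if (is.null(psms) || !nrow(psms)) return(psms)
  if (!any(!psms$is_decoy)) {
    warning("no target PSMs; returning empty set")
    return(psms[0, , drop = FALSE])
  }
  ord <- order(-psms$score)
  psms <- psms[ord, , drop = FALSE]
  cum_t <- cumsum(!psms$is_decoy)
  cum_d <- cumsum(psms$is_decoy)
  fdr <- cum_d / pmax(1L, cum_t)
  psms$q_value <- rev(cummin(rev(fdr)))
  if (!keep_decoys) psms <- psms[!psms$is_decoy, , drop = FALSE]
  rownames(psms) <- NULL
  psms
}
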