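# In-silico tryptic proteolysis: full or semi-specific, bounded missed
# cleavages, 1-based coordinates on the deposited protein sequence (the
# N-terminal methionine is never clipped).

#' Read protein sequences from FASTA
#'
#' UniProt-style `sp|ACC|NAME` headers are recognised and the accession taken
#' as the second pipe field; otherwise the first whitespace-delimited token is
#' used. Sequences containing letters outside the 20 canonical amino acids
#' (e.g. `X`) are kept but flagged.
#'
#' @param path Path to a (possibly gapped) amino-acid FASTA file.
#' @return data.frame with columns `accession`, `description`, `sequence`,
#'   `canonical` (logical).
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  first_tok <- sub("\\s.*$", "", headers)
  has_pipes <- grepl("^[a-z]{2}\\|[^|]+\\|", first_tok)
  acc <- first_tok
  acc[has_pipes] <- vapply(strsplit(first_tok[has_pipes], "|", fixed = TRUE),
                           `[[`, character(1), 2L)
  seqs <- as.character(aa)
  data.frame(
    accession = unname(acc),
    description = unname(headers),
    sequence = unname(seqs),
    canonical = !grepl("[^ACDEFGHIKLMNPQRSTVWY-]", seqs),
    stringsAsFactors = FALSE
  )
}

#' Write protein sequences to FASTA
#' @param proteins data.frame with `accession` and `sequence` columns.
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  lines <- as.vector(rbind(paste0(">", proteins$accession),
                           proteins$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Tryptic cleavage sites of a protein
#'
#' Positions `i` such that trypsin cuts after residue `i`: residue `i` is K or
#' R and residue `i+1` is not proline (the classical K/R-not-before-P rule).
#' A terminal K/R is a site coinciding with the protein C-terminus.
#'
#' @param sequence Protein sequence string.
#' @return Increasing integer vector of cut positions (cut is after each).
#' @export
cleavage_sites <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  idx <- which(res %in% c("K", "R"))
  idx[idx == n | res[pmin(idx + 1L, n)] != "P"]
}

#' Digestion settings
#'
#' @param enzyme Only `"trypsin"` is supported.
#' @param max_missed Maximum internal missed cleavage sites (default 2).
#' @param specificity `"semi"` (default; at least one enzymatic terminus) or
#'   `"full"` (both termini enzymatic).
#' @param min_length,max_length Peptide length bounds (default 6..45, the
#'   typical detectable tryptic range).
#' @return A `digest_spec` list.
#' @export
digest_spec <- function(enzyme = "trypsin", max_missed = 2L,
                        specificity = c("semi", "full"),
                        min_length = 6L, max_length = 45L) {
  specificity <- match.arg(specificity)
  stopifnot(identical(enzyme, "trypsin"), max_missed >= 0L,
            min_length >= 1L, max_length >= min_length)
  structure(list(enzyme = enzyme, max_missed = as.integer(max_missed),
                 specificity = specificity,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length)),
            class = "digest_spec")
}

#' Digest a protein in silico
#'
#' Full mode returns every fragment between enzymatic boundaries with at most
#' `max_missed` internal cut sites; semi mode additionally returns every
#' prefix/suffix of such a fragment that retains one enzymatic terminus.
#' Output is deduplicated by coordinates and length-filtered.
#'
#' @param protein Either a sequence string or a one-row data.frame with
#'   `accession` and `sequence`.
#' @param spec A [digest_spec()].
#' @return data.frame with columns `accession`, `sequence`, `start`, `end`
#'   (1-based inclusive protein coordinates), `missed`, `n_term_enzymatic`,
#'   `c_term_enzymatic`.
#' @export
digest <- function(protein, spec = digest_spec()) {
  stopifnot(inherits(spec, "digest_spec"))
  if (is.data.frame(protein)) {
    acc <- protein$accession[1L]
    seqstr <- protein$sequence[1L]
  } else {
    acc <- NA_character_
    seqstr <- protein
  }
  n <- nchar(seqstr)
  sites <- cleavage_sites(seqstr)
  bounds <- sort(unique(c(0L, sites, n)))  # cut after these positions
  nb <- length(bounds)

  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + spec$max_missed)
    for (j in (i + 1L):jmax) {
      starts <- c(starts, bounds[i] + 1L)
      ends <- c(ends, bounds[j])
    }
  }
  full <- data.frame(start = starts, end = ends,
                     n_term_enzymatic = TRUE, c_term_enzymatic = TRUE)

  if (spec$specificity == "semi") {
    semi_list <- vector("list", nrow(full))
    for (k in seq_len(nrow(full))) {
      s <- full$start[k]; e <- full$end[k]
      # prefixes keep the enzymatic N-terminus; suffixes the C-terminus
      pre_e <- if (e - 1L >= s) seq(s, e - 1L) else integer(0)
      suf_s <- if (s + 1L <= e) seq(s + 1L, e) else integer(0)
      semi_list[[k]] <- rbind(
        if (length(pre_e)) data.frame(start = s, end = pre_e,
                                      n_term_enzymatic = TRUE,
                                      c_term_enzymatic = pre_e %in% bounds),
        if (length(suf_s)) data.frame(start = suf_s, end = e,
                                      n_term_enzymatic = (suf_s - 1L) %in% bounds,
                                      c_term_enzymatic = TRUE)
      )
    }
    full <- rbind(full, do.call(rbind, semi_list))
  }

  full <- full[!duplicated(full[c("start", "end")]), , drop = FALSE]
  len <- full$end - full$start + 1L
  keep <- len >= spec$min_length & len <= spec$max_length
  full <- full[keep, , drop = FALSE]
  if (!nrow(full)) {
    return(data.frame(accession = character(0), sequence = character(0),
                      start = integer(0), end = integer(0), missed = integer(0),
                      n_term_enzymatic = logical(0),
                      c_term_enzymatic = logical(0)))
  }
  full$missed <- vapply(seq_len(nrow(full)), function(k) {
    sum(sites >= full$start[k] & sites <= full$end[k] - 1L)
  }, integer(1))
  full <- full[full$missed <= spec$max_missed, , drop = FALSE]
  full$sequence <- substring(seqstr, full$start, full$end)
  full$accession <- acc
  ord <- order(full$start, full$end)
  rownames(full) <- NULL
  full[ord, c("accession", "sequence", "start", "end", "missed",
              "n_term_enzymatic", "c_term_enzymatic")]
}

#' Digest a set of proteins
#' @param proteins data.frame with `accession` and `sequence` columns.
#' @param spec A [digest_spec()].
#' @return Row-bound [digest()] output across proteins.
#' @export
digest_proteins <- function(proteins, spec = digest_spec()) {
  out <- lapply(seq_len(nrow(proteins)),
                function(i) digest(proteins[i, , drop = FALSE], spec))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build reversed decoy proteins
#'
#' One decoy per target by full sequence reversal, accession prefixed
#' `DECOY_` — the standard target-decoy construction for FDR estimation.
#'
#' @param proteins data.frame with `accession` and `sequence` columns.
#' @return data.frame of the same shape with reversed sequences.
#' @export
build_decoys <- function(proteins) {
  rev_one <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  data.frame(
    accession = paste0("DECOY_", proteins$accession),
    description = paste0("DECOY_", proteins$accession),
    sequence = vapply(proteins$sequence, rev_one, character(1),
                      USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}
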