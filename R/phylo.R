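# Cross-species conservation of a modified site: pairwise global alignment,
# homologous-position mapping, Poisson-corrected distances, Neighbor-Joining
# tree and bootstrap supports.

.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Global pairwise alignment of a homolog against the reference
#'
#' Needleman-Wunsch with a substitution matrix and affine gaps
#' (default BLOSUM62, gap open 11, gap extend 1; a gap of length L costs
#' open + L * extend).
#'
#' @param ref,homolog Protein sequence strings.
#' @param substitution_matrix Matrix name or matrix (default BLOSUM62).
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @return List with `aligned_ref`, `aligned_homolog` (equal-length gapped
#'   strings) and `score`.
#' @export
align_pair <- function(ref, homolog, substitution_matrix = NULL,
                       gap_open = 11, gap_extend = 1) {
  stopifnot(nzchar(ref), nzchar(homolog))
  if (is.null(substitution_matrix)) substitution_matrix <- .blosum62()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref), Biostrings::AAString(homolog),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  out <- list(
    aligned_ref = as.character(Biostrings::alignedPattern(aln)),
    aligned_homolog = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln)
  )
  class(out) <- "pairwise_alignment"
  out
}

#' Map a reference site through an alignment
#'
#' Walks alignment columns to the `reference_site`-th reference residue and
#' reports the homolog residue and 1-based position in that column; a homolog
#' gap leaves the site unmapped.
#'
#' @param alignment An [align_pair()] result.
#' @param reference_site 1-based ungapped position in the reference.
#' @return List with `mapped_position` (or `NA`), `residue`, `conserved`
#'   (identical residue to the reference).
#' @export
map_site <- function(alignment, reference_site) {
  r <- strsplit(alignment$aligned_ref, "")[[1]]
  h <- strsplit(alignment$aligned_homolog, "")[[1]]
  ref_count <- cumsum(r != "-")
  col <- match(reference_site, ref_count)
  if (is.na(col)) stop("reference_site beyond reference sequence")
  ref_res <- r[col]
  if (h[col] == "-") {
    return(list(mapped_position = NA_integer_, residue = NA_character_,
                conserved = FALSE))
  }
  list(mapped_position = sum(h[seq_len(col)] != "-"),
       residue = h[col], conserved = h[col] == ref_res)
}

#' Reference-pivoted multiple alignment
#'
#' Aligns every homolog pairwise to the reference and stacks the results on
#' the reference coordinate system: one column per reference residue, homolog
#' insertions relative to the reference are dropped. Pre-aligned input (equal
#' lengths, `-` gaps) is used as-is, reference gap columns included.
#'
#' @param sequences data.frame with `accession`, `sequence`; the reference
#'   must be among them.
#' @param reference Reference accession (default: first row).
#' @param prealigned Logical; treat input as an existing alignment.
#' @param ... Passed to [align_pair()].
#' @return Character matrix, one row per sequence (reference first), of
#'   single-residue columns with `-` for gaps.
#' @export
reference_msa <- function(sequences, reference = sequences$accession[1L],
                          prealigned = FALSE, ...) {
  stopifnot(reference %in% sequences$accession)
  refseq <- sequences$sequence[sequences$accession == reference][1L]
  others <- sequences[sequences$accession != reference, , drop = FALSE]
  if (prealigned) {
    stopifnot(length(unique(nchar(sequences$sequence))) == 1L)
    m <- do.call(rbind, strsplit(
      c(refseq, others$sequence), ""))
    rownames(m) <- c(reference, others$accession)
    return(m)
  }
  n_ref <- nchar(refseq)
  rows <- matrix("-", nrow = nrow(others) + 1L, ncol = n_ref,
                 dimnames = list(c(reference, others$accession), NULL))
  rows[1L, ] <- strsplit(refseq, "")[[1]]
  for (i in seq_len(nrow(others))) {
    aln <- align_pair(refseq, others$sequence[i], ...)
    r <- strsplit(aln$aligned_ref, "")[[1]]
    h <- strsplit(aln$aligned_homolog, "")[[1]]
    rows[i + 1L, ] <- h[r != "-"]
  }
  rows
}

#' Poisson-corrected evolutionary distance between two aligned sequences
#'
#' With `p` the proportion of differing residues over shared ungapped columns
#' (pairwise deletion), the corrected distance is `d = -ln(1 - p)`
#' substitutions per site.
#'
#' @param a,b Equal-length gapped sequences (strings or character vectors).
#' @return Distance in substitutions/site.
#' @export
poisson_distance <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(a, "")[[1]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(b, "")[[1]]
  stopifnot(length(a) == length(b))
  shared <- a != "-" & b != "-"
  if (!any(shared)) stop("no ungapped shared columns")
  p <- mean(a[shared] != b[shared])
  if (p >= 1) stop("saturated pair (p = 1): Poisson distance undefined")
  -log(1 - p)
}

# Saturation-safe variant for bootstrap replicates: caps p just below 1.
.poisson_distance_safe <- function(a, b) {
  shared <- a != "-" & b != "-"
  m <- sum(shared)
  if (m == 0L) return(NA_real_)
  p <- min(mean(a[shared] != b[shared]), (m - 0.5) / m)
  -log(1 - p)
}

#' Pairwise Poisson distance matrix from an alignment
#' @param msa Character matrix from [reference_msa()].
#' @return Symmetric numeric matrix (zero diagonal), labels from row names.
#' @export
poisson_dist_matrix <- function(msa) {
  n <- nrow(msa)
  D <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- poisson_distance(msa[i, ], msa[j, ])
    }
  }
  D
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Classical NJ agglomeration over a symmetric distance matrix; negative
#' branch lengths are clamped to zero (the clamped deficit is reported via a
#' message). The returned tree is unrooted with branch lengths in the units
#' of the input distances (substitutions/site for Poisson distances).
#'
#' @param D Symmetric numeric matrix with zero diagonal, >= 3 taxa.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  tr <- ape::nj(stats::as.dist(D))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sprintf("clamped %d negative branch length(s), total deficit %.3g",
                    sum(neg), -sum(tr$edge.length[neg])))
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Bootstrap supports for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds the
#' Poisson-NJ tree per replicate, and reports for each internal edge of the
#' original tree the percentage of replicates containing its split. Supports
#' are stored as node labels.
#'
#' @param msa Character matrix from [reference_msa()] (>= 3 sequences).
#' @param n_reps Number of replicates (default 1000).
#' @param seed Optional integer seed; same seed gives identical supports.
#' @return The original-data NJ tree with `node.label` set to percent
#'   supports.
#' @export
bootstrap_support <- function(msa, n_reps = 1000L, seed = NULL) {
  if (n_reps <= 0L) stop("n_reps must be positive")
  stopifnot(nrow(msa) >= 3L)
  if (!is.null(seed)) set.seed(seed)
  base <- nj_tree(poisson_dist_matrix(msa))
  n <- nrow(msa); nc <- ncol(msa)
  safe_matrix <- function(m) {
    D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        D[i, j] <- D[j, i] <- .poisson_distance_safe(m[i, ], m[j, ])
      }
    }
    D
  }
  trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    suppressMessages(trees[[r]] <- nj_tree(safe_matrix(msa[, cols, drop = FALSE])))
  }
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(base, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  base$node.label <- format(100 * counts / n_reps, trim = TRUE)
  attr(base, "support_percent") <- 100 * counts / n_reps
  base
}

#' Assess cross-species conservation of a modified site
#'
#' Aligns each homolog to the reference, maps the reference site into every
#' homolog, and builds the Poisson-corrected Neighbor-Joining tree with
#' bootstrap supports over the homolog family.
#'
#' @param sequences data.frame with `accession`, `sequence` (plain or
#'   pre-aligned with `-` gaps).
#' @param reference Reference accession.
#' @param reference_site 1-based site position in the (ungapped) reference.
#' @param n_boot Bootstrap replicates (default 1000; 0 skips bootstrapping).
#' @param seed Seed for the bootstrap.
#' @param prealigned Logical; input already aligned.
#' @param ... Passed to [align_pair()].
#' @return List with `mapped_sites` (data.frame), `msa`, `distances`, `tree`
#'   (with supports as node labels when bootstrapped).
#' @export
conservation_report <- function(sequences,
                                reference = sequences$accession[1L],
                                reference_site, n_boot = 1000L, seed = NULL,
                                prealigned = FALSE, ...) {
  msa <- reference_msa(sequences, reference, prealigned = prealigned, ...)
  refseq_g <- msa[1L, ]
  ref_res <- refseq_g[which(refseq_g != "-")[reference_site]]
  mapped <- lapply(rownames(msa), function(acc) {
    aln <- list(aligned_ref = paste(msa[1L, ], collapse = ""),
                aligned_homolog = paste(msa[acc, ], collapse = ""))
    map_site(aln, reference_site)
  })
  mapped_df <- data.frame(
    accession = rownames(msa),
    mapped_position = vapply(mapped, `[[`, integer(1), "mapped_position"),
    residue = vapply(mapped, function(x) {
      if (is.na(x$mapped_position)) NA_character_ else x$residue
    }, character(1)),
    conserved = vapply(mapped, `[[`, logical(1), "conserved"),
    stringsAsFactors = FALSE
  )
  D <- poisson_dist_matrix(msa)
  tree <- if (n_boot > 0L) {
    bootstrap_support(msa, n_reps = n_boot, seed = seed)
  } else {
    nj_tree(D)
  }
  list(mapped_sites = mapped_df, msa = msa, distances = D, tree = tree,
       reference = reference, reference_site = reference_site,
       reference_residue = ref_res)
}
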