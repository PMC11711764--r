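# Independent oracles used across tests. These deliberately re-derive results
# by brute force or closed form, never by calling the code paths they check.

# Monoisotopic atom masses, written down independently of the package table.
oracle_atoms <- c(H = 1.00782503, C = 12.0, N = 14.00307401, O = 15.99491462,
                  S = 31.97207069)
oracle_proton <- 1.00727646662

oracle_formula_mass <- function(counts) {
  sum(oracle_atoms[names(counts)] * unlist(counts))
}

# Brute-force digestion oracle: enumerate every substring and test the
# enzymatic / missed-cleavage predicate directly.
oracle_digest <- function(seqstr, max_missed, specificity, min_len, max_len) {
  res <- strsplit(seqstr, "")[[1]]
  n <- length(res)
  cut_after <- vapply(seq_len(n), function(i) {
    res[i] %in% c("K", "R") && (i == n || res[i + 1L] != "P")
  }, logical(1))
  is_boundary <- function(pos) pos == 0L || pos == n || cut_after[pos]
  rows <- list()
  for (s in seq_len(n)) {
    for (e in s:n) {
      len <- e - s + 1L
      if (len < min_len || len > max_len) next
      nt <- is_boundary(s - 1L)
      ct <- is_boundary(e)
      enz_ok <- if (specificity == "full") nt && ct else nt || ct
      if (!enz_ok) next
      internal <- if (e - 1L >= s) sum(cut_after[s:(e - 1L)]) else 0L
      if (internal > max_missed) next
      rows[[length(rows) + 1L]] <- c(s, e)
    }
  }
  if (!length(rows)) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, rows)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

# Gotoh affine-gap global alignment oracle (gap of length L costs
# open + L * extend), returning the optimal score only.
oracle_align_score <- function(a, b, mat, open, ext) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in y (consume x)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in x (consume y)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- mat[x[i], y[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + sub
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Least-squares branch-length fit of a quartet topology; returns the summed
# squared residual and total tree length. Grouping is c(x, y) vs the rest.
quartet_fit <- function(D, pair) {
  taxa <- rownames(D)
  x <- pair[1]; y <- pair[2]; rest <- setdiff(taxa, pair)
  z <- rest[1]; w <- rest[2]
  # edges: ex, ey, ez, ew, em
  pairs <- rbind(c(x, y), c(x, z), c(x, w), c(y, z), c(y, w), c(z, w))
  A <- matrix(0, 6, 5, dimnames = list(NULL, c(x, y, z, w, "m")))
  for (r in 1:6) {
    A[r, pairs[r, 1]] <- 1
    A[r, pairs[r, 2]] <- 1
    if (!setequal(pairs[r, ], c(x, y)) && !setequal(pairs[r, ], c(z, w))) {
      A[r, "m"] <- 1
    }
  }
  d <- apply(pairs, 1, function(pq) D[pq[1], pq[2]])
  fit <- qr.solve(A, d)
  resid <- sum((A %*% fit - d)^2)
  list(resid = resid, total = sum(fit), lengths = fit)
}

# Additive distance matrix from a random tree with positive branch lengths.
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.1, 1))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# A crafted alignment in which two sister taxa share `n_excl` exclusive
# substitutions against the other two, plus light private noise.
sister_alignment <- function(n_excl = 50L, len = 300L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  anc <- sample(aa, len, replace = TRUE)
  seqs <- rbind(A = anc, B = anc, C = anc, D = anc)
  shared <- sample(len, n_excl)
  for (j in shared) {
    repl <- sample(setdiff(aa, anc[j]), 1)
    seqs["C", j] <- repl
    seqs["D", j] <- repl
  }
  for (tax in rownames(seqs)) {
    priv <- sample(setdiff(seq_len(len), shared), 5)
    for (j in priv) seqs[tax, j] <- sample(setdiff(aa, seqs[tax, j]), 1)
  }
  seqs
}

# Quiet parameters for unambiguous spectra.
noiseless_params <- function(seed = 1L, ...) {
  sim_params(fragment_sigma = 0, fragment_detection_prob = 1,
             n_noise_peaks = 0L, cycim_emission_prob = 1, seed = seed, ...)
}
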