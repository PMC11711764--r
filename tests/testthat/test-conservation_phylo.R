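# Alignment, site mapping, Poisson distances, NJ trees, bootstrap supports.

test_that("identical sequences align gap-free; a single insertion shifts the map", {
  a <- align_pair("ACDKGH", "ACDKGH")
  expect_identical(a$aligned_ref, "ACDKGH")
  expect_identical(a$aligned_homolog, "ACDKGH")
  b <- align_pair("ACDK", "ACDEK")
  expect_identical(nchar(b$aligned_ref), nchar(b$aligned_homolog))
  m <- map_site(b, 4L)
  expect_identical(m$mapped_position, 5L)
  expect_true(m$conserved)
})

test_that("alignment scores equal the exhaustive affine-gap DP optimum", {
  mat <- lactylmine:::.blosum62()
  set.seed(12)
  for (i in 1:15) {
    a <- random_protein(sample(3:8, 1))
    b <- random_protein(sample(3:8, 1))
    expect_equal(align_pair(a, b)$score,
                 oracle_align_score(a, b, mat, 11, 1),
                 tolerance = 1e-9)
  }
})

test_that("site mapping handles insertions and deletions around the site", {
  # 3-residue insertion in the homolog before the site
  aln <- list(aligned_ref = "AC---DKGH", aligned_homolog = "ACWYVDKGH")
  m <- map_site(aln, 4L)  # K is reference position 4
  expect_identical(m$mapped_position, 7L)
  expect_true(m$conserved)
  # deletion spanning the site
  aln2 <- list(aligned_ref = "ACDKGH", aligned_homolog = "AC--GH")
  m2 <- map_site(aln2, 4L)
  expect_true(is.na(m2$mapped_position))
  expect_false(m2$conserved)
  expect_error(map_site(aln2, 10L), "beyond")
})

test_that("Poisson correction matches its closed form and dominates p", {
  a <- strsplit("AAAAAAAAAA", "")[[1]]
  expect_identical(poisson_distance(a, a), 0)
  b <- a; b[10] <- "C"
  expect_equal(poisson_distance(a, b), -log(1 - 0.1), tolerance = 1e-15)
  # gapped columns excluded (pairwise deletion)
  bg <- b; bg[1] <- "-"
  expect_equal(poisson_distance(a, bg), -log(1 - 1 / 9), tolerance = 1e-15)
  # d >= p for all p
  for (p in seq(0.05, 0.95, by = 0.1)) {
    expect_gte(-log(1 - p), p)
  }
  all_diff <- rep("C", 10)
  expect_error(poisson_distance(a, all_diff), "saturated")
  expect_error(poisson_distance(rep("-", 3), c("A", "A", "A")), "shared")
})

test_that("three taxa give the closed-form star branch lengths", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len["a"]), (5 + 9 - 10) / 2, tolerance = 1e-12)
  expect_equal(unname(len["b"]), (5 + 10 - 9) / 2, tolerance = 1e-12)
  expect_equal(unname(len["c"]), (9 + 10 - 5) / 2, tolerance = 1e-12)
})

test_that("NJ recovers topology and branch lengths from additive matrices", {
  set.seed(77)
  for (n_taxa in c(4L, 5L)) {
    for (rep in 1:10) {
      gen <- random_additive_matrix(n_taxa)
      tr <- nj_tree(gen$D)
      # a tree metric has a unique tree: path distances must reproduce D
      got <- ape::cophenetic.phylo(tr)
      expect_equal(got[rownames(gen$D), colnames(gen$D)], gen$D,
                   tolerance = 1e-9)
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen$tree), tr)), 0)
    }
  }
})

test_that("NJ agrees with brute-force least-squares over quartet topologies", {
  set.seed(31)
  for (rep in 1:10) {
    gen <- random_additive_matrix(4L)
    D <- gen$D
    taxa <- rownames(D)
    pairs <- list(taxa[c(1, 2)], taxa[c(1, 3)], taxa[c(1, 4)])
    fits <- lapply(pairs, function(p) quartet_fit(D, p))
    best <- which.min(vapply(fits, `[[`, numeric(1), "resid"))
    tr <- nj_tree(D)
    # the NJ tree has the winning quartet's split
    sisters <- pairs[[best]]
    rest <- setdiff(taxa, sisters)
    ref <- ape::unroot(ape::read.tree(
      text = sprintf("((%s,%s),(%s,%s));", sisters[1], sisters[2],
                     rest[1], rest[2])))
    expect_equal(as.numeric(ape::dist.topo(tr, ref)), 0)
    expect_lt(fits[[best]]$resid, 1e-12)  # additive: perfect fit exists
  }
})

test_that("taxon order does not change the inferred splits", {
  set.seed(13)
  gen <- random_additive_matrix(5L)
  perm <- sample(5)
  D2 <- gen$D[perm, perm]
  t1 <- nj_tree(gen$D)
  t2 <- nj_tree(D2)
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  bad <- gen$D; bad[1, 2] <- bad[1, 2] + 1
  expect_error(nj_tree(bad), "symmetric")
})

test_that("bootstrap supports: determinism, single-replicate dichotomy, strong sisters", {
  set.seed(19)
  msa <- sister_alignment(n_excl = 50L, len = 300L)
  t1 <- bootstrap_support(msa, n_reps = 100L, seed = 5)
  t2 <- bootstrap_support(msa, n_reps = 100L, seed = 5)
  expect_identical(t1$node.label, t2$node.label)
  sup1 <- attr(bootstrap_support(msa, n_reps = 1L, seed = 2),
               "support_percent")
  expect_true(all(sup1 %in% c(0, 100)))
  # 50 exclusive shared substitutions make the C/D split near-certain
  sup <- attr(t1, "support_percent")
  mrca <- ape::getMRCA(t1, c("C", "D"))
  cd_support <- sup[mrca - ape::Ntip(t1)]
  expect_gte(cd_support, 99)
})

test_that("a planted homolog family conserves the lysine in every member", {
  fam <- simulate_homolog_family(seed = 23)
  cr <- conservation_report(fam, reference = "reference",
                            reference_site = 97L, n_boot = 50L, seed = 1)
  expect_true(all(cr$mapped_sites$conserved))
  expect_true(all(cr$mapped_sites$residue == "K"))
  expect_identical(cr$reference_residue, "K")
  # distances are symmetric with zero diagonal, and Newick output round-trips
  expect_equal(cr$distances, t(cr$distances), tolerance = 1e-12)
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(cr$tree, f)
  back <- ape::read.tree(f)
  expect_equal(as.numeric(ape::dist.topo(back, cr$tree)), 0)
})
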