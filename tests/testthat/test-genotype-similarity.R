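test_that("folding recodes to the minor allele and reports the observed MAF", {
  f <- fold_and_maf(c(0, 0, 1, 2))
  expect_false(f$monomorphic)
  expect_false(f$folded)
  expect_equal(f$maf, 3 / 8)
  expect_identical(f$genotype, c(0L, 0L, 1L, 2L))

  f2 <- fold_and_maf(c(2, 2, 2, 1))   # allele freq 7/8 > 0.5
  expect_true(f2$folded)
  expect_identical(f2$genotype, c(0L, 0L, 0L, 1L))
  expect_equal(f2$maf, 1 / 8)

  f3 <- fold_and_maf(c(0, 0, 0, 0))
  expect_true(f3$monomorphic)
  f4 <- fold_and_maf(c(1, 1, 1, 1))   # constant het column is monomorphic too
  expect_true(f4$monomorphic)
})

test_that("dosages round half-up onto called genotypes", {
  f <- fold_and_maf(c(0.4, 0.5, 1.49, 1.5))
  expect_identical(f$genotype, c(0L, 1L, 1L, 2L))
})

test_that("pair scores match hand-derived values and are symmetric", {
  expect_equal(snp_similarity(0, 2, 0.25), -1 / (0.25 * 0.75))
  expect_equal(snp_similarity(1, 1, 0.1),
               0.5 * (100 + 1 / 0.81) - 1 / 0.09)
  for (p in c(0.05, 0.2, 0.5)) {
    for (gi in 0:2) for (gj in 0:2) {
      expect_identical(snp_similarity(gi, gj, p), snp_similarity(gj, gi, p))
    }
  }
})

test_that("pair scores equal the case-by-case symbolic oracle exactly", {
  ps <- seq(0.01, 0.49, by = 0.01)
  worst <- 0
  for (p in ps) for (gi in 0:2) for (gj in 0:2) {
    worst <- max(worst, abs(snp_similarity(gi, gj, p) -
                              oracle_snp_similarity(gi, gj, p)))
  }
  expect_identical(worst, 0)
})

test_that("rare-allele sharing dominates: (1,1) unbounded, (0,0) vanishing, {0,2} negative", {
  ps <- seq(0.001, 0.499, length.out = 200)
  s11 <- snp_similarity(rep(1, 200), rep(1, 200), ps)
  s00 <- snp_similarity(rep(0, 200), rep(0, 200), ps)
  s02 <- snp_similarity(rep(0, 200), rep(2, 200), ps)
  expect_gt(s11[1], 1e5)
  expect_lt(s00[1], 1e-4)
  expect_true(all(s02 < 0))
})

test_that("invalid inputs to the pair score are rejected", {
  expect_error(snp_similarity(0, 1, 0), "0, 0.5")
  expect_error(snp_similarity(0, 1, 0.6), "0, 0.5")
  expect_error(snp_similarity(0.5, 1, 0.2), "integer")
})

test_that("gene similarity sums per-SNP scores and is additive over SNP sets", {
  panel <- random_panel(n = 25, genes = 3, spg = 4, seed = 3)
  g1 <- unique(panel$gene_of)[1]
  S <- gene_similarity(panel, g1)
  expect_equal(S$n_snps_used, sum(panel$gene_of == g1))
  # scalar evaluation oracle on a handful of pairs
  idx <- which(panel$gene_of == g1)
  for (pair in list(c(1, 2), c(3, 10), c(7, 7))) {
    expect_equal(S$values[pair[1], pair[2]],
                 sum(vapply(idx, function(k)
                   oracle_snp_similarity(panel$dosage[pair[1], k],
                                         panel$dosage[pair[2], k],
                                         panel$maf[k]), 0)))
  }
  # additivity: relabel the gene's SNPs into two half-genes
  panel2 <- panel
  panel2$gene_of[idx] <- rep(c("half1", "half2"), length.out = length(idx))
  expect_equal(gene_similarity(panel2, "half1")$values +
                 gene_similarity(panel2, "half2")$values,
               S$values)
})

test_that("permuting subject order permutes the similarity matrix rows and columns", {
  panel <- random_panel(n = 15, genes = 1, spg = 5, seed = 8)
  perm <- sample(15)
  p2 <- panel
  p2$dosage <- panel$dosage[perm, , drop = FALSE]
  p2$subject_id <- panel$subject_id[perm]
  g <- unique(panel$gene_of)[1]
  expect_equal(unname(gene_similarity(p2, g)$values),
               unname(gene_similarity(panel, g)$values[perm, perm]))
})

test_that("an empty gene raises an explicit error", {
  panel <- random_panel(n = 10, genes = 1, spg = 2, seed = 2)
  expect_error(gene_similarity(panel, "nosuchgene"), "no retained SNPs")
})

test_that("the distance transform anchors the most similar pair at zero", {
  S <- matrix(0, 3, 3)
  S[1, 2] <- S[2, 1] <- 3; S[1, 3] <- S[3, 1] <- 1; S[2, 3] <- S[3, 2] <- -2
  D <- similarity_to_distance(S)
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3], 2)
  expect_equal(D[2, 3], 5)
  expect_equal(diag(D), rep(0, 3))
  # translation invariance
  D2 <- similarity_to_distance(S + 7)
  expect_equal(unclass(D2), unclass(D), ignore_attr = TRUE)
  # constant similarity: all off-diagonal distances zero
  Dc <- similarity_to_distance(matrix(5, 4, 4))
  expect_true(all(Dc == 0))
})

test_that("distance matrices from random panels satisfy their invariants", {
  for (seed in 1:10) {
    panel <- random_panel(n = 12, genes = 1, spg = 6, seed = seed)
    D <- similarity_to_distance(gene_similarity(panel,
                                                unique(panel$gene_of)[1]))
    expect_equal(unclass(D), unclass(t(D)), ignore_attr = TRUE)
    expect_true(all(D >= 0))
    expect_equal(unname(diag(D)), rep(0, 12))
    off <- D[row(D) != col(D)]
    expect_equal(min(off), 0)
  }
})

test_that("the MAF window filter keeps closed-interval endpoints", {
  panel <- random_panel(n = 40, genes = 1, spg = 5, seed = 4)
  panel$maf <- c(0.005, 0.01, 0.03, 0.05, 0.2)
  f <- filter_snps_by_maf(panel, 0.01, 0.05)
  expect_length(f$snp_id, 3)
  expect_identical(f$snp_id, panel$snp_id[2:4])
  # identity window
  f2 <- filter_snps_by_maf(panel, 0, 0.5)
  expect_identical(f2$snp_id, panel$snp_id)
  # empty result permitted
  f3 <- filter_snps_by_maf(panel, 0.4, 0.5)
  expect_length(f3$snp_id, 0)
})
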