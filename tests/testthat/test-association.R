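test_that("the I statistic reproduces the hand-worked four-subject value", {
  Y <- c(1, 1, 0, 0)
  part <- partition(c(1L, 1L, 2L, 2L))
  expect_equal(pr_i(Y, part), 8)
  # equal group means give I = 0
  expect_equal(pr_i(c(1, 0, 1, 0), part), 0)
})

test_that("I is invariant under affine transforms of Y", {
  set.seed(10)
  for (trial in 1:20) {
    Y <- rnorm(30)
    labels <- sample(1:4, 30, TRUE)
    labels <- canonical <- match(labels, unique(labels))
    i0 <- pr_i(Y, labels)
    expect_equal(pr_i(3.2 * Y - 17, labels), i0)
    expect_equal(pr_i(-0.5 * Y + 2, labels), i0)
  }
})

test_that("the per-n scale variant divides the literal I by n", {
  Y <- c(1, 1, 0, 0)
  part <- partition(c(1L, 1L, 2L, 2L))
  expect_equal(pr_i(Y, part, scale = "per_n"), 2)
})

test_that("constant Y is rejected", {
  expect_error(pr_i(rep(1, 6), partition(rep(1:2, 3))), "constant")
})

test_that("one-way ANOVA reproduces the hand-worked six-subject value", {
  Y <- c(1, 1, 0, 0, 0, 1)
  part <- partition(c(1L, 1L, 1L, 2L, 2L, 2L))
  an <- anova_oneway(Y, part)
  expect_equal(an$f_stat, 0.5)
  expect_equal(an$df1, 1)
  expect_equal(an$df2, 4)
})

test_that("I and F agree with brute-force group-sum oracles on random instances", {
  set.seed(77)
  for (trial in 1:200) {
    n <- sample(10:60, 1)
    k <- sample(2:6, 1)
    labels <- c(1:k, sample(1:k, n - k, TRUE))  # every group nonempty
    Y <- rnorm(n)
    expect_equal(pr_i(Y, labels), oracle_pr_i(Y, labels), tolerance = 1e-10)
    expect_equal(anova_oneway(Y, labels)$f_stat, oracle_anova_f(Y, labels),
                 tolerance = 1e-10)
  }
})

test_that("ANOVA agrees with stats::aov and with the squared pooled t at k = 2", {
  set.seed(21)
  Y <- rnorm(40)
  labels <- rep(1:2, each = 20)
  an <- anova_oneway(Y, labels)
  av <- summary(aov(Y ~ factor(labels)))[[1]]
  expect_equal(an$f_stat, av[["F value"]][1])
  expect_equal(an$p, av[["Pr(>F)"]][1])
  tt <- t.test(Y[1:20], Y[21:40], var.equal = TRUE)
  expect_equal(an$f_stat, unname(tt$statistic)^2)
  # four-group case against aov as well
  labels4 <- rep(1:4, each = 10)
  expect_equal(anova_oneway(Y, labels4)$f_stat,
               summary(aov(Y ~ factor(labels4)))[[1]][["F value"]][1])
})

test_that("perfect separation reports the floored degenerate p", {
  Y <- c(0, 0, 0, 1, 1, 1, 1)
  an <- anova_oneway(Y, c(1L, 1L, 1L, 2L, 2L, 2L, 2L))
  expect_true(an$degenerate)
  expect_equal(an$p, 1 / (1e4 + 1))
})

test_that("ANOVA p-values are uniform when the partition is independent of Y", {
  set.seed(31)
  labels <- rep(1:4, each = 25)
  pv <- replicate(2000, anova_oneway(rnorm(100), labels)$p)
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation p-values hit the floor, are seeded, and track the asymptotic p", {
  set.seed(4)
  n <- 60
  labels <- rep(1:3, each = 20)
  Y <- c(rnorm(20, 5), rnorm(40))   # group 1 far away: observed stat extreme
  p <- permutation_p(Y, labels, stat = "pr", B = 500, seed = 9)
  expect_equal(as.numeric(p), 1 / 501)
  expect_identical(as.numeric(permutation_p(Y, labels, stat = "pr",
                                            B = 500, seed = 9)),
                   as.numeric(p))
  expect_false(identical(
    as.numeric(permutation_p(rnorm(n), labels, stat = "pr", B = 500, seed = 1)),
    as.numeric(permutation_p(rnorm(n), labels, stat = "pr", B = 500, seed = 2))))
  # permutation ANOVA p approximates the asymptotic p under the null
  diffs <- replicate(10, {
    Yn <- rnorm(n)
    abs(as.numeric(permutation_p(Yn, labels, stat = "anova", B = 4000,
                                 seed = 3)) -
          anova_oneway(Yn, labels)$p)
  })
  expect_lt(mean(diffs), 0.02)
})

test_that("permutation p is uniform over its grid under the null", {
  set.seed(6)
  labels <- rep(1:5, each = 10)
  pv <- replicate(400, as.numeric(permutation_p(rnorm(50), labels,
                                                stat = "pr", B = 199,
                                                seed = sample.int(1e6, 1))))
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("multiplicity control follows the Bonferroni and BH rules", {
  p <- c(g1 = 0.001, g2 = 0.04, g3 = 0.9)
  bon <- adjust_multiplicity(p, "bonferroni", alpha = 0.05)
  expect_identical(bon$significant, "g1")
  expect_equal(unname(bon$adjusted), pmin(1, p * 3), ignore_attr = TRUE)
  bh <- adjust_multiplicity(c(a = 0.01, b = 0.02, c = 0.03, d = 0.5),
                            "BH", alpha = 0.05)
  expect_setequal(bh$significant, c("a", "b", "c"))
  none <- adjust_multiplicity(c(x = 1, y = 1), "bonferroni")
  expect_length(none$significant, 0)
  empty <- adjust_multiplicity(numeric(0))
  expect_length(empty$adjusted, 0)
})

test_that("screening drops unmatched subjects and fails on disjoint sets", {
  cfg <- sim_config(n_subjects = 80, n_genes = 4, snps_per_gene = 8,
                    maf_law = function(m) runif(m, 0.02, 0.04), seed = 19)
  panel <- suppressMessages(simulate_genotypes(cfg))
  tp <- simulate_traits(panel, cfg)
  # drop 5 subjects from the phenotype side only
  keep <- 1:75
  tp$subject_id <- tp$subject_id[keep]
  tp$raw <- tp$raw[keep, ]
  tp$covariates$age <- tp$covariates$age[keep]
  tp$covariates$sex <- tp$covariates$sex[keep]
  tp$covariates$medication <- tp$covariates$medication[keep, ]
  expect_warning(res <- screen(panel, tp, k = 5, seed = 2), "dropped")
  expect_identical(attr(res, "dropped_subjects"), 5L)
  expect_true(all(res$k_used == 5))
  tp$subject_id <- paste0("X", tp$subject_id)
  expect_error(suppressWarnings(screen(panel, tp)), "disjoint")
})

test_that("genes with no SNPs in the MAF window are skipped with a warning", {
  # genes 1 and 3 carry only common variants (MAF 0.5 by construction),
  # gene 2 only rare ones (MAF exactly 0.03)
  n <- 300
  set.seed(27)
  common_col <- function() sample(rep(0:2, each = n / 3))
  rare_col <- function() sample(c(rep(1, 18), rep(0, n - 18)))
  dosage <- cbind(common_col(), common_col(),
                  rare_col(), rare_col(), rare_col(),
                  common_col(), common_col())
  panel <- suppressMessages(genotype_panel(
    dosage, gene_of = c("gene001", "gene001", "gene002", "gene002",
                        "gene002", "gene003", "gene003")))
  cfg <- sim_config(n_subjects = n, n_genes = 1, snps_per_gene = 2,
                    seed = 23)
  tp <- trait_panel(panel$subject_id,
                    matrix(rnorm(n * 3, 120, 10), n, 3),
                    age = sample(30:80, n, TRUE),
                    sex = rbinom(n, 1, 0.5),
                    medication = matrix(rbinom(n * 3, 1, 0.3), n, 3))
  # a window no gene satisfies is fatal
  expect_error(suppressWarnings(screen(panel, tp, maf_lo = 0.2,
                                       maf_hi = 0.25)),
               "no gene had SNPs")
  # the rare window keeps gene 2 only; the others are skipped with a warning
  expect_warning(res <- screen(panel, tp, k = 5, seed = 3), "skipped")
  expect_identical(res$gene, "gene002")
  expect_setequal(attr(res, "skipped_genes"), c("gene001", "gene003"))
})

test_that("a strongly causal gene ranks first in the screen", {
  cfg <- sim_config(n_subjects = 250, n_genes = 8, snps_per_gene = 12,
                    maf_law = function(m) runif(m, 0.011, 0.049),
                    causal_genes = 4L, effect_model = "slope",
                    effect_size = 8, seed = 55)
  sim <- suppressMessages(simulate_replicates(cfg, 1))
  res <- screen(sim$panel, sim$replicates[[1]], B = 300, seed = 5)
  expect_identical(res$gene[1], "gene004")
})
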