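#' Simulation configuration
#'
#' Bundles all parameters of the synthetic genotype/phenotype generator:
#' Hardy-Weinberg genotypes with a rare-variant-rich minor-allele-frequency
#' spectrum, genes as contiguous SNP blocks, and longitudinal traits with
#' covariate effects, gene-level genetic effects and Gaussian noise.
#'
#' @param n_subjects number of unrelated subjects.
#' @param n_genes number of genes (contiguous SNP blocks).
#' @param snps_per_gene SNPs per gene; a single count or a length-2 range
#'   from which per-gene counts are drawn uniformly.
#' @param maf_law function of one argument \code{m} returning \code{m} true
#'   minor-allele frequencies in (0, 0.5). The default draws 80% of SNPs
#'   from Uniform(0.005, 0.05) (rare) and 20% from Uniform(0.05, 0.5),
#'   emulating a sequencing-era spectrum dominated by rare variants.
#' @param n_timepoints number of trait measurements per subject (default 3,
#'   matching repeated blood-pressure exams).
#' @param causal_genes integer indices of causal genes (possibly empty).
#' @param causal_maf_max within a causal gene, SNPs with observed MAF below
#'   this bound are causal (default 0.05: the rare variants drive the trait).
#' @param causal_fraction fraction of those rare SNPs that are causal
#'   (default 1; rounded up to at least one SNP when any are eligible).
#' @param effect_model shape of the genetic effect over time: \code{"level"}
#'   (constant shift per minor-allele burden unit), \code{"slope"}
#'   (effect_size * t, absent at baseline and growing linearly), or
#'   \code{"crossing"} (effect_size * (t - (T-1)/2), sign flips across time).
#' @param effect_size trait units (e.g. mmHg) per unit of minor-allele burden.
#' @param covariate_effects named numeric vector with elements \code{age},
#'   \code{sex}, \code{age_sex}, \code{medication}; trait units.
#' @param intercept baseline trait level (default 120, an SBP-like scale).
#' @param noise_sd residual SD per time point, trait units.
#' @param seed integer master seed; identical configs (including seed) give
#'   bit-identical output.
#'
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_subjects = 500L,
                       n_genes = 50L,
                       snps_per_gene = 20L,
                       maf_law = default_maf_law,
                       n_timepoints = 3L,
                       causal_genes = integer(0),
                       causal_maf_max = 0.05,
                       causal_fraction = 1,
                       effect_model = c("level", "slope", "crossing"),
                       effect_size = 5,
                       covariate_effects = c(age = 0.5, sex = 5,
                                             age_sex = -0.1, medication = -8),
                       intercept = 120,
                       noise_sd = 10,
                       seed = 1L) {
  effect_model <- match.arg(effect_model)
  stopifnot(n_subjects >= 1, n_genes >= 1, all(snps_per_gene >= 1),
            length(snps_per_gene) %in% c(1L, 2L),
            n_timepoints >= 1, noise_sd > 0, is.function(maf_law),
            causal_fraction >= 0, causal_fraction <= 1)
  if (length(causal_genes) &&
      (any(causal_genes < 1) || any(causal_genes > n_genes)))
    stop("causal gene index out of range 1..n_genes")
  need <- c("age", "sex", "age_sex", "medication")
  if (!all(need %in% names(covariate_effects)))
    stop("covariate_effects must name: ", paste(need, collapse = ", "))
  structure(list(
    n_subjects = as.integer(n_subjects), n_genes = as.integer(n_genes),
    snps_per_gene = as.integer(snps_per_gene), maf_law = maf_law,
    n_timepoints = as.integer(n_timepoints),
    causal_genes = as.integer(causal_genes),
    causal_maf_max = causal_maf_max, causal_fraction = causal_fraction,
    effect_model = effect_model, effect_size = effect_size,
    covariate_effects = covariate_effects[need], intercept = intercept,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default minor-allele-frequency law
#'
#' Mixture spectrum: 80% of SNPs rare (Uniform(0.005, 0.05)), 20% common
#' (Uniform(0.05, 0.5)).
#'
#' @param m number of frequencies to draw.
#' @return numeric vector of length \code{m} in (0, 0.5).
#' @export
default_maf_law <- function(m) {
  rare <- stats::runif(m) < 0.8
  ifelse(rare, stats::runif(m, 0.005, 0.05), stats::runif(m, 0.05, 0.5))
}

#' Simulate a genotype panel under Hardy-Weinberg equilibrium
#'
#' Per SNP, a true MAF p is drawn from \code{config$maf_law} and genotypes
#' 0/1/2 are drawn with probabilities ((1-p)^2, 2p(1-p), p^2) (equivalently
#' Binomial(2, p)), subjects unrelated. SNPs are partitioned contiguously
#' into genes. Columns that come out monomorphic are kept here and excluded
#' at panel construction, as with real data.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{genotype_panel} (see \code{\link{genotype_panel}});
#'   monomorphic SNPs are dropped with a message. True MAFs are kept in
#'   attribute \code{"true_maf"} alongside the observed ones.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  spg <- config$snps_per_gene
  per_gene <- if (length(spg) == 2L)
    sample(spg[1]:spg[2], config$n_genes, replace = TRUE)
  else rep(spg, config$n_genes)
  m <- sum(per_gene)
  p <- config$maf_law(m)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 0.5))
    stop("maf_law must return frequencies strictly inside (0, 0.5)")
  n <- config$n_subjects
  dosage <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
  gene_of <- rep(sprintf("gene%03d", seq_len(config$n_genes)), per_gene)
  snp_id <- sprintf("snp%06d", seq_len(m))
  subject_id <- sprintf("S%04d", seq_len(n))
  panel <- genotype_panel(dosage, snp_id = snp_id, gene_of = gene_of,
                          subject_id = subject_id)
  attr(panel, "true_maf") <- p[match(panel$snp_id, snp_id)]
  panel
}

# effect multiplier at time index t (0-based) under the chosen model
effect_at_time <- function(model, effect_size, t, T) {
  switch(model,
         level = rep(effect_size, length(t)),
         slope = effect_size * t,
         crossing = effect_size * (t - (T - 1) / 2))
}

# causal SNP columns (panel indices) for one causal gene
causal_snps_of_gene <- function(panel, gene, config) {
  idx <- which(panel$gene_of == gene)
  rare <- idx[panel$maf[idx] < config$causal_maf_max]
  if (!length(rare)) return(integer(0))
  k <- max(1L, ceiling(config$causal_fraction * length(rare)))
  rare[seq_len(k)]
}

#' Simulate longitudinal traits for a genotype panel
#'
#' trait(i, t) = intercept + age + sex + age x sex + medication effects
#' + sum over causal genes of effect(t) x burden(i, gene) + Gaussian noise,
#' where burden is the subject's minor-allele count over the gene's causal
#' SNPs (those with observed MAF below \code{causal_maf_max}). Covariates:
#' age ~ uniform integers 30..80, sex ~ Bernoulli(0.5), medication use
#' ~ Bernoulli(0.3) independently at each exam.
#'
#' @param panel a \code{genotype_panel} from \code{\link{simulate_genotypes}}.
#' @param config the same \code{\link{sim_config}}.
#' @param seed optional seed for the phenotype draw (defaults to
#'   \code{config$seed + 1}); genotypes are untouched.
#' @return a \code{trait_panel} (see \code{\link{trait_panel}}) with the
#'   per-gene causal SNP sets in attribute \code{"causal_snps"}.
#' @export
simulate_traits <- function(panel, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "genotype_panel"))
  n <- length(panel$subject_id)
  if (n != config$n_subjects)
    stop("panel and config disagree on the number of subjects")
  genes <- unique(panel$gene_of)
  if (length(config$causal_genes) && any(config$causal_genes > length(genes)))
    stop("causal gene index out of range")
  set.seed(as.integer(seed))
  T <- config$n_timepoints
  age <- sample(30:80, n, replace = TRUE)
  sex <- stats::rbinom(n, 1L, 0.5)
  med <- matrix(stats::rbinom(n * T, 1L, 0.3), nrow = n)
  colnames(med) <- paste0("med_t", seq_len(T) - 1L)
  b <- config$covariate_effects
  base <- config$intercept + b["age"] * age + b["sex"] * sex +
    b["age_sex"] * age * sex
  genetic <- matrix(0, n, T)
  causal_snps <- list()
  for (g in config$causal_genes) {
    gname <- genes[g]
    cs <- causal_snps_of_gene(panel, gname, config)
    causal_snps[[gname]] <- panel$snp_id[cs]
    if (!length(cs)) next
    burden <- rowSums(panel$dosage[, cs, drop = FALSE])
    eff <- effect_at_time(config$effect_model, config$effect_size,
                          seq_len(T) - 1L, T)
    genetic <- genetic + outer(burden, eff)
  }
  raw <- as.vector(base) + b["medication"] * med + genetic +
    matrix(stats::rnorm(n * T, 0, config$noise_sd), n, T)
  colnames(raw) <- paste0("trait_t", seq_len(T) - 1L)
  tp <- trait_panel(subject_id = panel$subject_id, raw = raw,
                    age = age, sex = sex, medication = med)
  attr(tp, "causal_snps") <- causal_snps
  attr(tp, "seed") <- as.integer(seed)
  tp
}

#' Simulate replicate phenotype sets over one fixed genotype panel
#'
#' Genotypes are generated once from the master seed; each replicate
#' redraws covariates and noise with a derived, recorded seed so any single
#' replicate can be regenerated in isolation.
#'
#' @param config a \code{\link{sim_config}}.
#' @param n_replicates number of phenotype sets (>= 1).
#' @return list with \code{panel} (the shared \code{genotype_panel}) and
#'   \code{replicates}, a list of \code{trait_panel}s; each carries its
#'   replicate index in attribute \code{"replicate"} and its seed in
#'   attribute \code{"seed"}.
#' @export
simulate_replicates <- function(config, n_replicates) {
  stopifnot(n_replicates >= 1)
  panel <- simulate_genotypes(config)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    s <- (config$seed + 7919L * r) %% .Machine$integer.max
    reps[[r]] <- simulate_traits(panel, config, seed = s)
    attr(reps[[r]], "replicate") <- r
  }
  list(panel = panel, replicates = reps)
}
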