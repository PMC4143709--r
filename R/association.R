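# group sizes and group sums of Y under a partition; the shared kernel of
# the I statistic, the ANOVA decomposition and their permutation nulls
group_sums <- function(Y, labels, k) {
  list(n_i = tabulate(labels, k),
       s_i = as.vector(rowsum(Y, labels, reorder = TRUE)))
}

#' Partition-retention I statistic
#'
#' Measures how strongly a partition separates the group means of an
#' outcome: I = sum_i n_i (Ybar_i - Ybar)^2 / (s^2 / n_i)
#' = sum_i n_i^2 (Ybar_i - Ybar)^2 / s^2, with n_i the size of partition
#' element i, Ybar and s the overall mean and standard deviation
#' (denominator n). In the dual-clustering screen, Y is the 0/1 phenotype
#' cluster indicator and the partition comes from genotype similarity; I
#' then gauges the influence of the gene on the longitudinal trait. I is
#' invariant to affine transforms of Y and carries no dimension.
#'
#' @param Y numeric outcome vector (non-constant).
#' @param part a \code{partition} (or an integer label vector).
#' @param scale \code{"literal"} (default) or \code{"per_n"}, which divides
#'   by n; for fixed n the two differ by a constant factor only, so
#'   rankings, permutation p-values and ROC curves are unchanged.
#' @return the I score (nonnegative).
#' @export
pr_i <- function(Y, part, scale = c("literal", "per_n")) {
  scale <- match.arg(scale)
  labels <- if (inherits(part, "partition")) part$labels else as.integer(part)
  stopifnot(length(Y) == length(labels))
  n <- length(Y)
  m <- mean(Y)
  s2 <- sum((Y - m)^2) / n
  if (s2 == 0) stop("Y is constant; I is undefined (s = 0)")
  gs <- group_sums(Y, labels, max(labels))
  I <- sum((gs$s_i - gs$n_i * m)^2) / s2
  if (scale == "per_n") I <- I / n
  I
}

#' One-way analysis of variance of Y across partition groups
#'
#' Classical decomposition F = (SSB/(k-1)) / (SSW/(n-k)) with the p-value
#' from the upper tail of F(k-1, n-k). A zero within-group sum of squares
#' (perfect separation) is reported at a small-p floor with a degenerate
#' flag rather than p = 0.
#'
#' @param Y numeric outcome vector.
#' @param part a \code{partition} (or an integer label vector).
#' @param floor_B resolution used for the degenerate-case p floor,
#'   reported as 1/(floor_B + 1).
#' @return list with \code{f_stat}, \code{p}, \code{df1}, \code{df2},
#'   \code{degenerate}.
#' @export
anova_oneway <- function(Y, part, floor_B = 1e4) {
  labels <- if (inherits(part, "partition")) part$labels else as.integer(part)
  stopifnot(length(Y) == length(labels))
  n <- length(Y); k <- max(labels)
  if (n <= k) stop("need n > k for within-group degrees of freedom")
  m <- mean(Y)
  gs <- group_sums(Y, labels, k)
  ssb <- sum(gs$s_i^2 / gs$n_i) - n * m^2
  sst <- sum((Y - m)^2)
  ssw <- sst - ssb
  if (ssw <= 0 || !is.finite(ssb / ssw)) {
    return(list(f_stat = Inf, p = 1 / (floor_B + 1), df1 = k - 1,
                df2 = n - k, degenerate = TRUE))
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f_stat = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE),
       df1 = k - 1, df2 = n - k, degenerate = FALSE)
}

#' Permutation p-value for a partition-association statistic
#'
#' Permutes Y over subjects B times and reports
#' p = (1 + #\{permuted stat >= observed\}) / (B + 1), so p >= 1/(B+1).
#' For the I statistic and the ANOVA F the permutation null is computed
#' from group sums in a single vectorized pass; for the kernel score
#' statistic Q from its quadratic form.
#'
#' @param Y numeric outcome vector.
#' @param part a \code{partition} (for \code{stat} \code{"pr"} or
#'   \code{"anova"}).
#' @param kernel a kernel matrix or \code{kernel_matrix} (for
#'   \code{stat = "skat"}).
#' @param stat one of \code{"pr"}, \code{"anova"}, \code{"skat"}.
#' @param B number of permutations (>= 100).
#' @param seed integer seed (the draw is fully reproducible).
#' @param X covariate design for \code{stat = "skat"} (default intercept).
#' @return the permutation p-value, with the observed statistic in
#'   attribute \code{"observed"}.
#' @export
permutation_p <- function(Y, part = NULL, kernel = NULL,
                          stat = c("pr", "anova", "skat"),
                          B = 1000L, seed = 1L, X = NULL) {
  stat <- match.arg(stat)
  if (B < 100) stop("B must be at least 100")
  n <- length(Y)
  set.seed(as.integer(seed))
  Yp <- vapply(seq_len(B), function(b) Y[sample.int(n)], numeric(n))
  if (stat %in% c("pr", "anova")) {
    labels <- if (inherits(part, "partition")) part$labels else as.integer(part)
    k <- max(labels)
    n_i <- tabulate(labels, k)
    Z <- matrix(0, k, n); Z[cbind(labels, seq_len(n))] <- 1
    m <- mean(Y)
    GS <- Z %*% Yp                       # k x B group sums
    obs_gs <- as.vector(Z %*% Y)
    if (stat == "pr") {
      s2 <- sum((Y - m)^2) / n
      if (s2 == 0) stop("Y is constant; statistic undefined")
      obs <- sum((obs_gs - n_i * m)^2) / s2
      perm <- colSums((GS - n_i * m)^2) / s2
    } else {
      sst <- sum((Y - m)^2)
      ssb_perm <- colSums(GS^2 / n_i) - n * m^2
      ssb_obs <- sum(obs_gs^2 / n_i) - n * m^2
      # F is monotone in SSB at fixed SST, so compare on F directly
      f_of <- function(ssb) (ssb / (k - 1)) / ((sst - ssb) / (n - k))
      obs <- f_of(ssb_obs); perm <- f_of(ssb_perm)
    }
  } else {
    K <- if (inherits(kernel, "kernel_matrix")) kernel$values else as.matrix(kernel)
    if (is.null(X)) X <- matrix(1, n, 1)
    P0 <- diag(n) - X %*% solve(crossprod(X), t(X))
    A <- P0 %*% K %*% P0
    obs <- drop(Y %*% A %*% Y)
    perm <- colSums(Yp * (A %*% Yp))
  }
  p <- (1 + sum(perm >= obs)) / (B + 1)
  attr(p, "observed") <- obs
  p
}

#' Multiplicity adjustment over genes
#'
#' Bonferroni family-wise control (reject p <= alpha/m) or
#' Benjamini-Hochberg step-up false-discovery-rate control, via
#' \code{stats::p.adjust}.
#'
#' @param pvals named numeric vector of per-gene p-values in (0, 1].
#' @param method \code{"bonferroni"} or \code{"BH"}.
#' @param alpha significance level (default 0.05).
#' @return list with \code{adjusted} (same names) and \code{significant}
#'   (names of genes with adjusted p <= alpha).
#' @export
adjust_multiplicity <- function(pvals, method = c("bonferroni", "BH"),
                                alpha = 0.05) {
  method <- match.arg(method)
  if (!length(pvals)) return(list(adjusted = numeric(0),
                                  significant = character(0)))
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1))
    stop("p-values must be finite in (0, 1]")
  adj <- stats::p.adjust(pvals, method = method)
  list(adjusted = adj,
       significant = names(pvals)[!is.na(adj) & adj <= alpha])
}

# rebuild a genotype panel on a subject subset (observed MAF recomputed,
# SNPs monomorphic within the subset dropped)
subset_subjects <- function(panel, idx) {
  suppressMessages(genotype_panel(panel$dosage[idx, , drop = FALSE],
                                  snp_id = panel$snp_id,
                                  gene_of = panel$gene_of,
                                  subject_id = panel$subject_id[idx]))
}

#' Gene-by-gene dual-clustering association screen
#'
#' The full pipeline for one genotype panel and one longitudinal trait
#' panel: covariate adjustment, phenotype clustering into
#' \code{k_phenotype} groups (the 0/1 "high/low" indicator becomes Y),
#' then per gene: MAF-window filter, inverse-probability gene similarity,
#' distance transform, Ward partition into \code{k} groups, and the I and
#' ANOVA association scores, with optional permutation p-values and an
#' optional kernel-score comparator.
#'
#' @param panel a \code{genotype_panel}.
#' @param traits a \code{trait_panel} (adjusted or raw; raw is adjusted
#'   here).
#' @param maf_lo,maf_hi observed-MAF window (closed), default 0.01..0.05.
#' @param k genotype partition size (default 10).
#' @param B permutations per gene for the I statistic (0 = none).
#' @param skat if \code{TRUE}, also run the linear weighted-kernel score
#'   test on each gene (fills \code{p_skat}; failures give NA with a
#'   reason, never a dropped gene).
#' @param seed master seed for permutation draws (per-gene seeds derived).
#' @param multiplicity \code{"bonferroni"} or \code{"BH"}.
#' @param alpha significance level.
#' @param rank_by p-value column used for sorting and adjustment:
#'   \code{"auto"} (permutation p when available, else ANOVA p),
#'   \code{"p_perm"}, \code{"p_anova"} or \code{"p_skat"}.
#' @return \code{data.frame} with one row per screened gene: \code{gene},
#'   \code{n_snps}, \code{k_used}, \code{i_score}, \code{f_stat},
#'   \code{p_anova}, \code{p_perm}, \code{p_skat}, \code{skat_note},
#'   \code{p_adj}, \code{significant}; sorted by the ranking p-value.
#'   Attributes: \code{phenotype_partition}, \code{skipped_genes},
#'   \code{dropped_subjects}.
#' @export
screen <- function(panel, traits, maf_lo = 0.01, maf_hi = 0.05, k = 10L,
                   B = 0L, skat = FALSE, seed = 1L,
                   multiplicity = c("bonferroni", "BH"), alpha = 0.05,
                   rank_by = c("auto", "p_perm", "p_anova", "p_skat")) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(traits, "trait_panel"))
  multiplicity <- match.arg(multiplicity)
  rank_by <- match.arg(rank_by)

  common <- intersect(panel$subject_id, traits$subject_id)
  if (!length(common)) stop("genotype and phenotype subject sets are disjoint")
  n_drop <- (length(panel$subject_id) - length(common)) +
    (length(traits$subject_id) - length(common))
  if (n_drop > 0)
    warning(n_drop, " subject record(s) without a genotype/phenotype match dropped")
  panel <- subset_subjects(panel, match(common, panel$subject_id))
  ti <- match(common, traits$subject_id)
  traits$subject_id <- traits$subject_id[ti]
  traits$raw <- traits$raw[ti, , drop = FALSE]
  if (!is.null(traits$adjusted))
    traits$adjusted <- traits$adjusted[ti, , drop = FALSE]
  traits$covariates$age <- traits$covariates$age[ti]
  traits$covariates$sex <- traits$covariates$sex[ti]
  traits$covariates$medication <- traits$covariates$medication[ti, , drop = FALSE]

  if (is.null(traits$adjusted)) traits <- adjust_covariates(traits)
  ph <- cluster_phenotypes(traits)
  Y <- as.integer(ph$labels == attr(ph, "high_group"))

  fp <- filter_snps_by_maf(panel, maf_lo, maf_hi)
  genes <- unique(stats::na.omit(panel$gene_of))
  n <- length(common)
  res <- list(); skipped <- character(0)
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    idx <- which(!is.na(fp$gene_of) & fp$gene_of == g)
    if (!length(idx)) { skipped <- c(skipped, g); next }
    S <- gene_similarity(fp, g)
    D <- similarity_to_distance(S)
    part <- suppressWarnings(cluster_genotypes(D, k, source = paste0("genotype:", g)))
    i_score <- pr_i(Y, part)
    an <- anova_oneway(Y, part)
    p_perm <- NA_real_
    if (B > 0)
      p_perm <- as.numeric(permutation_p(Y, part, stat = "pr", B = B,
                                         seed = (seed + 131L * gi) %% .Machine$integer.max))
    p_skat <- NA_real_; skat_note <- NA_character_
    if (skat) {
      sk <- tryCatch({
        w <- skat_weights(fp$maf[idx])
        K <- skat_kernel(fp$dosage[, idx, drop = FALSE], w, gene = g)
        skat_test(Y, K = K)
      }, error = function(e) e)
      if (inherits(sk, "error")) skat_note <- conditionMessage(sk)
      else p_skat <- sk$p
    }
    res[[g]] <- data.frame(gene = g, n_snps = length(idx), k_used = part$k,
                           i_score = i_score, f_stat = an$f_stat,
                           p_anova = an$p, p_perm = p_perm, p_skat = p_skat,
                           skat_note = skat_note,
                           stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning(length(skipped), " gene(s) skipped: no SNPs in the MAF window [",
            maf_lo, ", ", maf_hi, "]")
  if (!length(res)) stop("no gene had SNPs in the MAF window")
  out <- do.call(rbind, res)
  rank_col <- switch(rank_by,
                     auto = if (B > 0) "p_perm" else "p_anova",
                     p_perm = "p_perm", p_anova = "p_anova", p_skat = "p_skat")
  pv <- out[[rank_col]]
  ok <- is.finite(pv)
  adj <- rep(NA_real_, nrow(out))
  if (any(ok)) {
    names(pv) <- out$gene
    mult <- adjust_multiplicity(pv[ok], method = multiplicity, alpha = alpha)
    adj[ok] <- mult$adjusted
  }
  out$p_adj <- adj
  out$significant <- !is.na(adj) & adj <= alpha
  # NA ranking p-values sort last; ties broken by larger I (stronger signal)
  out <- out[order(is.na(pv), pv, -out$i_score), , drop = FALSE]
  rownames(out) <- NULL
  attr(ph, "subject_id") <- common
  attr(out, "phenotype_partition") <- ph
  attr(out, "skipped_genes") <- skipped
  attr(out, "dropped_subjects") <- n_drop
  attr(out, "rank_by") <- rank_col
  out
}
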