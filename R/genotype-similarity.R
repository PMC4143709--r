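#' Construct a genotype panel
#'
#' Validates and normalizes a subjects x SNPs dosage matrix: dosages are
#' rounded to the nearest called genotype in {0,1,2} (ties round half-up),
#' each SNP is folded so the counted allele is the minor one, the observed
#' MAF is recorded, and monomorphic SNPs are dropped (the inverse-probability
#' similarity is undefined at p = 0).
#'
#' @param dosage numeric matrix, subjects in rows, SNPs in columns,
#'   values in [0, 2]; \code{NA}s are imputed to the SNP's modal called
#'   genotype with a message (set \code{na_action = "drop"} to drop such
#'   SNPs instead).
#' @param snp_id,subject_id identifiers (defaults generated).
#' @param gene_of character vector assigning each SNP to a gene label
#'   (\code{NA} = unassigned; such SNPs are kept but ignored by gene-level
#'   operations).
#' @param na_action \code{"impute"} (default) or \code{"drop"}.
#' @return object of class \code{genotype_panel}: list with \code{dosage}
#'   (integer matrix of minor-allele counts), \code{snp_id}, \code{gene_of},
#'   \code{maf} (observed, in (0, 0.5]), \code{subject_id}.
#' @export
genotype_panel <- function(dosage,
                           snp_id = colnames(dosage),
                           gene_of = rep(NA_character_, ncol(dosage)),
                           subject_id = rownames(dosage),
                           na_action = c("impute", "drop")) {
  na_action <- match.arg(na_action)
  dosage <- as.matrix(dosage)
  if (is.null(snp_id)) snp_id <- sprintf("snp%06d", seq_len(ncol(dosage)))
  if (is.null(subject_id)) subject_id <- sprintf("S%04d", seq_len(nrow(dosage)))
  stopifnot(length(snp_id) == ncol(dosage),
            length(gene_of) == ncol(dosage),
            length(subject_id) == nrow(dosage))
  bad <- which(dosage < 0 | dosage > 2)
  if (length(bad)) stop("dosage values outside [0, 2]")

  n_na <- sum(is.na(dosage))
  if (n_na > 0 && na_action == "drop") {
    keep <- colSums(is.na(dosage)) == 0
    message(sum(!keep), " SNP(s) with missing dosages dropped")
    dosage <- dosage[, keep, drop = FALSE]
    snp_id <- snp_id[keep]; gene_of <- gene_of[keep]
  }

  m <- ncol(dosage)
  rec <- matrix(0L, nrow(dosage), m)
  maf <- numeric(m)
  mono <- logical(m)
  for (k in seq_len(m)) {
    fk <- fold_and_maf(dosage[, k])
    if (fk$monomorphic) { mono[k] <- TRUE; next }
    rec[, k] <- fk$genotype
    maf[k] <- fk$maf
  }
  if (n_na > 0 && na_action == "impute")
    message(n_na, " missing dosage(s) imputed to modal genotype")
  if (any(mono))
    message(sum(mono), " monomorphic SNP(s) excluded")
  keep <- !mono
  structure(list(dosage = rec[, keep, drop = FALSE],
                 snp_id = snp_id[keep],
                 gene_of = gene_of[keep],
                 maf = maf[keep],
                 subject_id = subject_id),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$subject_id), "subjects x",
      length(x$snp_id), "SNPs,",
      length(unique(stats::na.omit(x$gene_of))), "genes\n")
  cat("  observed MAF range:",
      if (length(x$maf)) paste(signif(range(x$maf), 3), collapse = " - ")
      else "(empty)", "\n")
  invisible(x)
}

#' Fold one dosage column to minor-allele counts and compute its MAF
#'
#' Dosages are rounded to the nearest genotype in {0,1,2} (half-up); if the
#' counted allele's frequency exceeds 0.5 the column is recoded g -> 2 - g so
#' g counts the minor allele. Missing values are imputed to the modal called
#' genotype before folding.
#'
#' @param x numeric vector of dosages in [0, 2].
#' @return list with \code{genotype} (integer vector), \code{maf} (observed
#'   frequency of the counted allele, in (0, 0.5]), \code{monomorphic}
#'   (logical; if \code{TRUE} the SNP must be excluded), \code{folded}.
#' @export
fold_and_maf <- function(x) {
  g <- as.integer(floor(x + 0.5))  # round half-up onto {0,1,2}
  if (anyNA(g)) {
    tab <- tabulate(g + 1L, 3L)
    g[is.na(g)] <- which.max(tab) - 1L
  }
  n <- length(g)
  af <- sum(g) / (2 * n)
  folded <- FALSE
  if (af > 0.5) { g <- 2L - g; af <- 1 - af; folded <- TRUE }
  if (af == 0 || stats::var(g) == 0)
    return(list(genotype = g, maf = af, monomorphic = TRUE, folded = folded))
  list(genotype = g, maf = af, monomorphic = FALSE, folded = folded)
}

# The six unordered genotype-pair cases of the inverse-probability score.
# All coefficients live in this one table so any correction is a one-line
# change re-verified by the whole suite. Rows indexed by gi*3 + gj + 1.
ip_score_table <- function(p) {
  a <- 1 / p^2          # inverse prob. of the minor homozygote
  b <- 1 / (1 - p)^2    # inverse prob. of the major homozygote
  c <- 1 / (p * (1 - p))
  v00 <- 2 * p^2
  v11 <- 0.5 * (a + b) - c
  v22 <- 2 * (1 - p)^2
  v01 <- b - 0.5 * c
  v02 <- -c
  v12 <- a - 0.5 * c
  # 3 x 3 lookup, genotype pair (gi, gj)
  cbind(v00, v01, v02,
        v01, v11, v12,
        v02, v12, v22)
}

#' Inverse-probability-weighted similarity of two genotypes at one SNP
#'
#' Scores the unordered genotype pair (g_i, g_j) at a SNP with observed
#' minor-allele frequency p. Matches on minor alleles are up-weighted by
#' inverse genotype probabilities, so sharing a rare allele counts far more
#' than sharing the common one: the (1,1) score grows without bound as
#' p -> 0 while the (0,0) score vanishes. The opposite-homozygote pair
#' {0,2} scores negative for every p.
#'
#' @param gi,gj integer genotypes in {0,1,2} (vectors recycled together).
#' @param p observed MAF in (0, 0.5] (scalar or vector).
#' @return numeric similarity score(s).
#' @export
snp_similarity <- function(gi, gj, p) {
  if (any(p <= 0) || any(p > 0.5)) stop("p must lie in (0, 0.5]")
  if (any(gi != as.integer(gi)) || any(gj != as.integer(gj)))
    stop("genotypes must be integers in {0,1,2} (round dosages upstream)")
  if (any(gi < 0 | gi > 2 | gj < 0 | gj > 2)) stop("genotypes outside {0,1,2}")
  nn <- max(length(gi), length(gj), length(p))
  gi <- rep_len(as.integer(gi), nn); gj <- rep_len(as.integer(gj), nn)
  p <- rep_len(p, nn)
  tab <- ip_score_table(p)  # nn x 9
  tab[cbind(seq_len(nn), gi * 3L + gj + 1L)]
}

#' Gene-level similarity matrix
#'
#' Sums the per-SNP inverse-probability scores over all retained SNPs of a
#' gene, for every subject pair (including the diagonal).
#'
#' @param panel a \code{genotype_panel}.
#' @param gene gene label present in \code{panel$gene_of}.
#' @return object of class \code{similarity_matrix}: list with \code{gene},
#'   \code{values} (symmetric subjects x subjects matrix) and
#'   \code{n_snps_used}.
#' @export
gene_similarity <- function(panel, gene) {
  stopifnot(inherits(panel, "genotype_panel"))
  idx <- which(!is.na(panel$gene_of) & panel$gene_of == gene)
  if (!length(idx))
    stop("gene '", gene, "' has no retained SNPs", call. = FALSE)
  n <- length(panel$subject_id)
  S <- matrix(0, n, n)
  for (k in idx) {
    g <- panel$dosage[, k]
    tab <- ip_score_table(panel$maf[k])  # 1 x 9
    pair_idx <- outer(g * 3L, g, "+") + 1L
    S <- S + matrix(tab[1, pair_idx], n, n)
  }
  dimnames(S) <- list(panel$subject_id, panel$subject_id)
  structure(list(gene = gene, values = S, n_snps_used = length(idx)),
            class = "similarity_matrix")
}

#' Convert a similarity matrix to a distance matrix
#'
#' d(i, j) = -sim(i, j) + max over off-diagonal similarities, so the most
#' similar pair is at distance exactly 0; the diagonal is set to 0. An
#' optional exponential transform d = exp(-lambda * sim) is available as an
#' alternative bounded monotone-decreasing mapping.
#'
#' @param S a \code{similarity_matrix} or a plain symmetric matrix.
#' @param transform \code{"linear"} (default) or \code{"exponential"}.
#' @param lambda rate for the exponential transform.
#' @return symmetric nonnegative matrix with zero diagonal, class
#'   \code{distance_matrix}; the minimum off-diagonal entry is 0 under the
#'   linear transform.
#' @export
similarity_to_distance <- function(S, transform = c("linear", "exponential"),
                                   lambda = 1) {
  transform <- match.arg(transform)
  V <- if (inherits(S, "similarity_matrix")) S$values else as.matrix(S)
  if (nrow(V) < 2) stop("need at least 2 subjects")
  if (any(!is.finite(V))) stop("similarities must be finite")
  off <- row(V) != col(V)
  D <- if (transform == "linear") -V + max(V[off]) else exp(-lambda * V)
  if (transform == "exponential") D <- D - min(D[off])
  diag(D) <- 0
  D[D < 0] <- 0  # guard tiny negative round-off
  structure(D, class = c("distance_matrix", "matrix"))
}

#' Filter SNPs by an observed-MAF window
#'
#' Retains SNPs with lo <= MAF <= hi (closed interval, so the conventional
#' rare-variant window 0.01..0.05 keeps its endpoints); the gene map is
#' restricted accordingly. An empty result is permitted: downstream
#' screening skips genes with no retained SNPs.
#'
#' @param panel a \code{genotype_panel}.
#' @param lo,hi MAF bounds, 0 <= lo < hi <= 0.5.
#' @param inclusive if \code{FALSE}, use the open interval instead.
#' @return the filtered \code{genotype_panel}.
#' @export
filter_snps_by_maf <- function(panel, lo = 0.01, hi = 0.05, inclusive = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"), lo >= 0, lo < hi, hi <= 0.5)
  keep <- if (inclusive) panel$maf >= lo & panel$maf <= hi
          else panel$maf > lo & panel$maf < hi
  out <- panel
  out$dosage <- panel$dosage[, keep, drop = FALSE]
  out$snp_id <- panel$snp_id[keep]
  out$gene_of <- panel$gene_of[keep]
  out$maf <- panel$maf[keep]
  out
}
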