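#' ROC curve over genes from significance scores
#'
#' Sweeps a significance threshold over all observed score values (smaller
#' score = more significant, the natural orientation for p-values). At each
#' threshold, fpr = claimed noncausal genes / all noncausal genes and
#' tpr = claimed causal genes / all causal genes; genes with tied scores
#' are claimed together. The area under the curve is the trapezoid rule.
#' Genes with \code{NA} scores (a method that failed on them) are never
#' claimed before the final all-claimed point, i.e. they rank last; their
#' count is reported.
#'
#' @param scores numeric per-gene scores, smaller = more significant;
#'   \code{NA} allowed.
#' @param causal logical per-gene truth flags (at least one \code{TRUE}
#'   and one \code{FALSE}).
#' @param method label stored on the curve.
#' @param replicate replicate index or \code{"average"}.
#' @return object of class \code{roc_curve}: list with \code{fpr},
#'   \code{tpr} (nondecreasing, starting at (0,0) and ending at (1,1)),
#'   \code{auc}, \code{method}, \code{replicate}, \code{n_na}.
#' @export
roc_from_scores <- function(scores, causal, method = "method",
                            replicate = NA) {
  causal <- as.logical(causal)
  stopifnot(length(scores) == length(causal), !anyNA(causal))
  n_pos <- sum(causal); n_neg <- sum(!causal)
  if (n_pos == 0 || n_neg == 0)
    stop("need at least one causal and one noncausal gene")
  n_na <- sum(is.na(scores))
  ok <- !is.na(scores)
  o <- order(scores[ok])
  s <- scores[ok][o]; cz <- causal[ok][o]
  # group tied scores: cumulative counts at each distinct threshold
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(cz)[last_of_tie]
  fp <- cumsum(!cz)[last_of_tie]
  fpr <- c(0, fp / n_neg, 1)
  tpr <- c(0, tp / n_pos, 1)   # final point claims everything incl. NAs
  keep <- !duplicated(cbind(fpr, tpr))
  fpr <- fpr[keep]; tpr <- tpr[keep]
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc, method = method,
                 replicate = replicate, n_na = n_na),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("roc_curve [", x$method, ", replicate ", as.character(x$replicate),
      "]: AUC = ", format(x$auc, digits = 4),
      if (x$n_na > 0) paste0(" (", x$n_na, " NA scores ranked last)") else "",
      "\n", sep = "")
  invisible(x)
}

# tpr of one curve at the fpr values in `grid` (linear interpolation of the
# upper envelope; vertical segments contribute their topmost tpr)
interp_tpr <- function(curve, grid) {
  f <- curve$fpr; t <- curve$tpr
  env <- tapply(t, f, max)
  x <- as.numeric(names(env)); y <- as.numeric(env)
  stats::approx(x, y, xout = grid, method = "linear", rule = 2, ties = "max")$y
}

#' Vertically averaged ROC curve across replicates
#'
#' Interpolates each replicate's tpr on a fixed fpr grid (0, 0.01, ..., 1)
#' and averages pointwise; the average curve's AUC is the trapezoid area of
#' the averaged curve.
#'
#' @param curves list of \code{roc_curve}s (>= 2).
#' @param grid fpr grid (default 0 to 1 in steps of 0.01).
#' @return a \code{roc_curve} with \code{replicate = "average"}.
#' @export
average_roc <- function(curves, grid = seq(0, 1, by = 0.01)) {
  stopifnot(length(curves) >= 2,
            all(vapply(curves, inherits, TRUE, "roc_curve")))
  TPR <- vapply(curves, interp_tpr, numeric(length(grid)), grid = grid)
  tpr <- rowMeans(TPR)
  auc <- sum(diff(grid) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = grid, tpr = tpr, auc = auc,
                 method = curves[[1]]$method, replicate = "average",
                 n_na = sum(vapply(curves, `[[`, 0, "n_na"))),
            class = "roc_curve")
}

# exact two-sided signed-rank p over all 2^n sign assignments, computed by
# dynamic programming on doubled (integer) midranks so tied |differences|
# are handled exactly
exact_signed_rank_p <- function(d) {
  w <- as.integer(round(2 * rank(abs(d))))
  w_obs <- sum(w[d > 0])
  total <- sum(w)
  # distribution of sum of a random subset of w (each element in/out)
  f <- numeric(total + 1); f[1] <- 1
  for (wi in w) {
    shifted <- c(rep(0, wi), f[seq_len(total + 1 - wi)])
    f <- f + shifted
  }
  f <- f / sum(f)
  p_ge <- sum(f[(w_obs + 1):(total + 1)])
  p_le <- sum(f[1:(w_obs + 1)])
  min(1, 2 * min(p_ge, p_le))
}

#' Paired Wilcoxon signed-rank comparison of per-replicate AUCs
#'
#' Two-sided paired signed-rank test on the per-replicate AUC differences.
#' Zero differences are dropped; for up to 25 nonzero pairs the exact
#' permutation distribution of the signed-rank sum is used (midranks for
#' tied magnitudes), above that the tie-corrected normal approximation.
#'
#' @param auc_a,auc_b numeric vectors of per-replicate AUCs, paired, length
#'   >= 5.
#' @return list with \code{p}, \code{statistic} (signed-rank V of
#'   \code{a - b}), \code{n_nonzero}, \code{exact}.
#' @export
compare_auc <- function(auc_a, auc_b) {
  stopifnot(length(auc_a) == length(auc_b), length(auc_a) >= 5)
  d <- auc_a - auc_b
  d <- d[d != 0]
  if (!length(d))
    return(list(p = 1, statistic = NA_real_, n_nonzero = 0L, exact = TRUE))
  v <- sum(rank(abs(d))[d > 0])
  exact <- length(d) <= 25
  p <- if (exact) exact_signed_rank_p(d)
  else suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                           correct = TRUE))$p.value
  list(p = p, statistic = v, n_nonzero = length(d), exact = exact)
}
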