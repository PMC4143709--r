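# Independent oracles used across the suite. Each is deliberately written
# as a direct, slow transcription of the definition it checks, sharing no
# code with the package implementation.

# inverse-probability pair score, case-by-case symbolic expressions
oracle_snp_similarity <- function(gi, gj, p) {
  if (gi == 0 && gj == 0) return(2 * p^2)
  if (gi == 1 && gj == 1)
    return(0.5 * (1 / p^2 + 1 / (1 - p)^2) - 1 / (p * (1 - p)))
  if (gi == 2 && gj == 2) return(2 * (1 - p)^2)
  if (gi + gj == 1) return(1 / (1 - p)^2 - 0.5 / (p * (1 - p)))
  if ((gi == 0 && gj == 2) || (gi == 2 && gj == 0))
    return(-1 / (p * (1 - p)))
  if (gi + gj == 3) return(1 / p^2 - 0.5 / (p * (1 - p)))
  stop("unreachable")
}

# step-by-step Ward merging on a raw distance matrix: at every step,
# evaluate the Ward (squared-distance Lance-Williams) cost of every
# candidate pair exhaustively and merge the cheapest, ties broken by the
# lexicographically smallest active-cluster index pair
oracle_ward <- function(D) {
  n <- nrow(D)
  members <- as.list(seq_len(n))
  sz <- rep(1, n)
  cur <- D^2
  diag(cur) <- Inf
  merges <- list()
  heights <- numeric(0)
  for (s in seq_len(n - 1)) {
    best <- c(Inf, NA, NA)
    na <- length(members)
    for (i in seq_len(na - 1)) for (j in (i + 1):na)
      if (cur[i, j] < best[1]) best <- c(cur[i, j], i, j)
    i <- best[2]; j <- best[3]
    heights[s] <- sqrt(best[1])
    merges[[s]] <- sort(c(members[[i]], members[[j]]))
    for (k in seq_len(na)) if (k != i && k != j) {
      cur[i, k] <- cur[k, i] <-
        ((sz[i] + sz[k]) * cur[i, k] + (sz[j] + sz[k]) * cur[j, k] -
           sz[k] * cur[i, j]) / (sz[i] + sz[j] + sz[k])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sz[i] <- sz[i] + sz[j]
    members <- members[-j]; sz <- sz[-j]
    cur <- cur[-j, -j, drop = FALSE]
    if (length(members) > 1) diag(cur) <- Inf
  }
  list(merges = merges, heights = heights)
}

# member sets of each merge of an hclust tree, in merge order
hclust_merge_members <- function(hc) {
  out <- list()
  for (s in seq_len(nrow(hc$merge))) {
    mem <- function(x) if (x < 0) -x else out[[x]]
    out[[s]] <- sort(c(mem(hc$merge[s, 1]), mem(hc$merge[s, 2])))
  }
  out
}

# literal group-by-group transcription of the I statistic
oracle_pr_i <- function(Y, labels) {
  n <- length(Y)
  ybar <- mean(Y)
  s2 <- sum((Y - ybar)^2) / n
  total <- 0
  for (g in unique(labels)) {
    yi <- Y[labels == g]
    total <- total + length(yi) * (mean(yi) - ybar)^2 / (s2 / length(yi))
  }
  total
}

# literal sums-of-squares transcription of one-way ANOVA
oracle_anova_f <- function(Y, labels) {
  ybar <- mean(Y)
  k <- length(unique(labels))
  n <- length(Y)
  ssb <- 0; ssw <- 0
  for (g in unique(labels)) {
    yi <- Y[labels == g]
    ssb <- ssb + length(yi) * (mean(yi) - ybar)^2
    ssw <- ssw + sum((yi - mean(yi))^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

# all-thresholds confusion-matrix enumeration of the ROC
oracle_roc <- function(scores, causal) {
  ok <- !is.na(scores)
  thr <- sort(unique(scores[ok]))
  pts <- data.frame(fpr = 0, tpr = 0)
  for (t in thr) {
    claimed <- ok & scores <= t
    pts <- rbind(pts, data.frame(fpr = sum(claimed & !causal) / sum(!causal),
                                 tpr = sum(claimed & causal) / sum(causal)))
  }
  pts <- rbind(pts, data.frame(fpr = 1, tpr = 1))
  pts <- pts[!duplicated(pts), ]
  auc <- 0
  for (i in 2:nrow(pts))
    auc <- auc + (pts$fpr[i] - pts$fpr[i - 1]) *
      (pts$tpr[i] + pts$tpr[i - 1]) / 2
  list(fpr = pts$fpr, tpr = pts$tpr, auc = auc)
}

# exact two-sided signed-rank p by enumeration over all sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# small random genotype panel fixture
random_panel <- function(n = 60, genes = 3, spg = 5, seed = 1,
                         maf = function(m) runif(m, 0.05, 0.45)) {
  cfg <- sim_config(n_subjects = n, n_genes = genes, snps_per_gene = spg,
                    maf_law = maf, seed = seed)
  suppressMessages(simulate_genotypes(cfg))
}

# random symmetric distance matrix with zero diagonal
random_distance <- function(n, seed) {
  set.seed(seed)
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.1, 5)
  D + t(D)
}
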