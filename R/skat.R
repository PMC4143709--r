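#' MAF-based variant weights for the kernel score test
#'
#' w_k = Beta-density(maf_k; a, b)^2 with the standard default
#' (a, b) = (1, 25): sharply decreasing in MAF, so rare variants dominate
#' the kernel. a = b = 1 gives flat weights.
#'
#' @param mafs minor-allele frequencies in (0, 0.5].
#' @param a,b Beta shape parameters (positive).
#' @return positive weights, one per SNP.
#' @export
skat_weights <- function(mafs, a = 1, b = 25) {
  if (any(mafs <= 0) || any(mafs > 0.5)) stop("MAFs must lie in (0, 0.5]")
  if (a <= 0 || b <= 0) stop("Beta shapes must be positive")
  stats::dbeta(mafs, a, b)^2
}

#' Weighted linear genotype kernel for one gene
#'
#' K = G W G' with W = diag(w): the gene-level sum of the per-SNP rank-one
#' similarities sim(i, j; k) = w_k g_ik g_jk. Positive semidefinite by
#' construction.
#'
#' @param G subjects x SNPs genotype (minor-allele count) matrix.
#' @param weights per-SNP weights (default flat).
#' @param gene optional gene label.
#' @return object of class \code{kernel_matrix}: list with \code{gene},
#'   \code{values} (subjects x subjects), \code{weights}.
#' @export
skat_kernel <- function(G, weights = rep(1, ncol(G)), gene = NA_character_) {
  G <- as.matrix(G)
  stopifnot(length(weights) == ncol(G), all(weights >= 0))
  K <- G %*% (weights * t(G))
  structure(list(gene = gene, values = K, weights = weights, G = G),
            class = "kernel_matrix")
}

# Liu-type moment matching of sum(lambda_i chi^2_1) to a (noncentral)
# chi-square: returns the upper-tail p at q
liu_pvalue <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-12 * max(lambda, 0)]
  if (!length(lambda)) return(1)
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    aa <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * aa^3 - aa^2
    l <- aa^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s2
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- l + delta; sigma_x <- sqrt(2 * (l + 2 * delta))
  tstar <- (q - mu_q) / sigma_q
  stats::pchisq(tstar * sigma_x + mu_x, df = l, ncp = delta,
                lower.tail = FALSE)
}

#' Linear weighted-kernel variance-component score test
#'
#' The comparator test: Q = r' K r with r the OLS residuals of the response
#' on the covariate design X (intercept at minimum). Here the response is
#' the 0/1 phenotype-cluster indicator treated as continuous (the linear,
#' Gaussian form of the test). Under the null Q is a mixture
#' sum(lambda_i chi^2_1) with lambda the eigenvalues of
#' sigma^2 P0 K P0; the p-value comes from Liu-type moment matching, with
#' a seeded permutation fallback if the approximation fails.
#'
#' @param y numeric response (cluster indicator 0/1, or any trait).
#' @param X covariate design matrix (default intercept only); must be full
#'   rank.
#' @param K a \code{kernel_matrix} (or plain PSD matrix).
#' @param method \code{"liu"} (default) or \code{"permutation"}.
#' @param B permutations for the fallback/permutation path.
#' @param seed seed for the permutation path.
#' @return list with \code{Q}, \code{p}, \code{method} (\code{"liu"} or
#'   \code{"permutation"}), \code{lambda}.
#' @export
skat_test <- function(y, X = NULL, K, method = c("liu", "permutation"),
                      B = 1000L, seed = 1L) {
  method <- match.arg(method)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("covariate design X is rank-deficient")
  Kv <- if (inherits(K, "kernel_matrix")) K$values else as.matrix(K)
  stopifnot(nrow(Kv) == n)
  r <- qr.resid(qrX, y)
  Q <- drop(r %*% Kv %*% r)
  if (sum(r^2) <= (100 * .Machine$double.eps)^2 * max(1, sum(y^2)))
    return(list(Q = 0, p = 1, method = "degenerate", lambda = numeric(0)))
  sigma2 <- sum(r^2) / (n - qrX$rank)
  # nonzero eigenvalues of P0 K P0: when K = G W G' they equal the
  # eigenvalues of Z'Z with Z the residualized sqrt(W)-scaled genotype
  # columns (an m x m problem, m = #SNPs); otherwise fall back to the
  # full projected kernel
  if (inherits(K, "kernel_matrix") && !is.null(K$G)) {
    Z <- qr.resid(qrX, sweep(K$G, 2, sqrt(K$weights), "*"))
    ev <- eigen(crossprod(Z), symmetric = TRUE, only.values = TRUE)$values
  } else {
    PKP <- Kv - X %*% solve(crossprod(X), crossprod(X, Kv))
    PKP <- PKP - (PKP %*% X) %*% solve(crossprod(X), t(X))
    ev <- eigen((PKP + t(PKP)) / 2, symmetric = TRUE,
                only.values = TRUE)$values
  }
  lambda <- sigma2 * ev[ev > 1e-10 * max(abs(ev), .Machine$double.eps)]
  p <- if (method == "liu" && length(lambda))
    tryCatch(liu_pvalue(Q, lambda), error = function(e) NA_real_)
  else NA_real_
  used <- "liu"
  if (!is.finite(p) || method == "permutation") {
    p <- as.numeric(permutation_p(y, kernel = Kv, stat = "skat", B = B,
                                  seed = seed, X = X))
    used <- "permutation"
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  list(Q = Q, p = p, method = used, lambda = lambda)
}
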