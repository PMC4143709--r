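#' Ward hierarchical clustering of a precomputed distance matrix
#'
#' Agglomerative clustering applied directly to the supplied dissimilarities
#' with the Ward criterion (Lance-Williams update on squared distances, the
#' "ward.D2" convention), as the distances here come from a transformed
#' similarity rather than a Euclidean embedding.
#'
#' @param D a \code{distance_matrix}, a \code{dist}, or a symmetric numeric
#'   matrix with zero diagonal.
#' @return an \code{hclust} tree (merge list, non-decreasing heights,
#'   leaf order).
#' @export
ward_linkage <- function(D) {
  d <- if (inherits(D, "dist")) D else stats::as.dist(as.matrix(D))
  if (any(!is.finite(d))) stop("distances must be finite")
  if (any(d < 0)) stop("distances must be nonnegative")
  if (attr(d, "Size") < 2) stop("need at least 2 subjects")
  stats::hclust(d, method = "ward.D2")
}

#' Cut a dendrogram into k groups
#'
#' Undoes the last k-1 merges and canonicalizes labels: group 1 is the group
#' containing the first subject, then first-appearance order, so partitions
#' are comparable across runs and subject orderings.
#'
#' @param tree an \code{hclust} object.
#' @param k number of groups, 1 <= k <= n.
#' @param source provenance tag, e.g. \code{"genotype:MAP4"} or
#'   \code{"phenotype"}.
#' @return object of class \code{partition}: list with \code{labels}
#'   (integer vector in 1..k, named by subject when the tree has labels),
#'   \code{k}, \code{source}.
#' @export
cut_tree <- function(tree, k, source = "unspecified") {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k must lie in 1..n")
  raw <- stats::cutree(tree, k = k)
  partition(canonical_labels(raw), source = source)
}

# relabel groups by order of first appearance
canonical_labels <- function(labels) {
  u <- unique(labels)
  out <- match(labels, u)
  names(out) <- names(labels)
  out
}

#' Construct a partition object
#'
#' @param labels integer group labels (1..k, every group nonempty).
#' @param source provenance tag.
#' @return object of class \code{partition}.
#' @export
partition <- function(labels, source = "unspecified") {
  labels <- as.integer(labels)
  k <- max(labels)
  if (!all(seq_len(k) %in% labels))
    stop("every group in 1..k must be nonempty")
  structure(list(labels = labels, k = k, source = source),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("partition (", x$source, "): ", length(x$labels), " subjects in ",
      x$k, " groups of sizes ",
      paste(tabulate(x$labels, x$k), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Partition subjects by genotype similarity
#'
#' Ward clustering of an inverse-probability distance matrix cut into k
#' groups. Partition sizes 5 to 10 are the studied range; other values are
#' allowed but flagged.
#'
#' @param D a \code{distance_matrix} (one gene).
#' @param k number of groups (default 10).
#' @param source provenance tag.
#' @return a \code{partition} with \code{source} recorded.
#' @export
cluster_genotypes <- function(D, k = 10L, source = "genotype") {
  if (k < 5 || k > 10)
    warning("k = ", k, " is outside the studied partition-size range 5..10")
  cut_tree(ward_linkage(D), k, source = source)
}

#' Partition subjects by their longitudinal trait trajectories
#'
#' Ward clustering of Euclidean distances between covariate-adjusted
#' trajectory vectors, cut into 2 groups. The group with the larger mean
#' trajectory is labelled "high" (e.g. the high-blood-pressure cluster);
#' group means are attached so callers can interpret the split.
#'
#' @param traits a \code{trait_panel} with adjusted values (see
#'   \code{\link{adjust_covariates}}), or a plain subjects x T matrix.
#' @param k number of groups (default 2).
#' @return a \code{partition} with attributes \code{group_means} (k x T
#'   matrix of mean trajectories), \code{high_group} (label of the group
#'   with the larger overall mean) and \code{degenerate} (\code{TRUE} when
#'   all merge heights are 0).
#' @export
cluster_phenotypes <- function(traits, k = 2L) {
  M <- if (inherits(traits, "trait_panel")) assemble_vectors(traits)
       else as.matrix(traits)
  if (anyNA(M)) stop("missing trait values; run assemble_vectors() first")
  tree <- stats::hclust(stats::dist(M), method = "ward.D2")
  part <- cut_tree(tree, k, source = "phenotype")
  gm <- apply(M, 2, function(col) tapply(col, part$labels, mean))
  gm <- matrix(gm, nrow = k, dimnames = list(seq_len(k), colnames(M)))
  attr(part, "group_means") <- gm
  attr(part, "high_group") <- unname(which.max(rowMeans(gm)))
  attr(part, "degenerate") <- all(tree$height == 0)
  if (attr(part, "degenerate"))
    warning("all trajectories identical; phenotype split is arbitrary")
  part
}
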