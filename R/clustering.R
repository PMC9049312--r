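#' Hierarchical clustering of traits on their correlation matrix
#'
#' Builds an agglomerative clustering tree over the K phenotypes using the
#' dissimilarity \eqn{d(j,k) = 1 - \hat\Sigma_{jk}}, where \eqn{\hat\Sigma}
#' is the sample correlation matrix of the traits. Negative correlations
#' give distances above 1 and are used as-is: the clustered linear
#' combination is premised on positively correlated clusters, so
#' anti-correlated traits should end up in different clusters.
#'
#' @param sigma_hat K x K symmetric correlation matrix with unit diagonal.
#' @param linkage Agglomeration rule: `"average"` (UPGMA, the default),
#'   `"complete"` or `"single"`.
#' @return A `trait_tree` object (also of class `hclust`) with K - 1 merges;
#'   for K = 1, a degenerate tree with zero merges.
#' @examples
#' s <- matrix(c(1, .8, .1, .8, 1, .1, .1, .1, 1), 3, 3)
#' build_tree(s)
#' @export
build_tree <- function(sigma_hat, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (is.matrix(sigma_hat) && nrow(sigma_hat) == 0L) {
    abort("cannot cluster zero traits")
  }
  .assert_square_corr(sigma_hat)
  K <- nrow(sigma_hat)
  labels <- colnames(sigma_hat)
  if (is.null(labels)) labels <- paste0("trait", seq_len(K))
  if (K == 1L) {
    tree <- structure(
      list(merge = matrix(integer(), 0L, 2L), height = numeric(),
           order = 1L, labels = labels, method = linkage,
           dist.method = "1 - correlation", call = sys.call()),
      class = c("trait_tree", "hclust"))
    return(tree)
  }
  tree <- hclust(as.dist(1 - sigma_hat), method = linkage)
  tree$labels <- labels
  tree$dist.method <- "1 - correlation"
  class(tree) <- c("trait_tree", "hclust")
  tree
}

#' Membership matrix at a given number of clusters
#'
#' Cuts a trait tree into `L` clusters and returns the K x L 0/1 membership
#' matrix `B`, whose (k, l) entry is 1 exactly when trait k belongs to
#' cluster l. Every row sums to 1 and every column is non-empty.
#'
#' @param tree A `trait_tree` from [build_tree()].
#' @param L Number of clusters, between 1 and K.
#' @return A K x L integer 0/1 matrix; rows named by trait, columns
#'   `cluster1..clusterL` numbered by first appearance in trait order.
#' @export
cut_tree <- function(tree, L) {
  K <- length(tree$labels) %||% (nrow(tree$merge) + 1L)
  if (length(L) != 1L || is.na(L) || L != as.integer(L) || L < 1L || L > K) {
    abort(sprintf("`L` must be an integer in 1..%d", K))
  }
  L <- as.integer(L)
  cl <- if (K == 1L) 1L else cutree(tree, k = L)
  B <- matrix(0L, K, L,
              dimnames = list(tree$labels, paste0("cluster", seq_len(L))))
  B[cbind(seq_len(K), cl)] <- 1L
  B
}

#' All membership matrices of one trait tree
#'
#' Clusters once and returns the membership matrix for every cut
#' L = 1..K. The partitions are nested: each cluster at level L lies inside
#' exactly one cluster at level L - 1.
#'
#' @param x A K x K correlation matrix or a `trait_tree`.
#' @inheritParams build_tree
#' @return A list of K membership matrices, element L having L columns.
#' @export
all_cuts <- function(x, linkage = c("average", "complete", "single")) {
  tree <- if (inherits(x, "hclust")) x else build_tree(x, match.arg(linkage))
  K <- length(tree$labels) %||% (nrow(tree$merge) + 1L)
  purrr::map(seq_len(K), function(L) cut_tree(tree, L))
}

#' Export a trait tree as a Newick string
#'
#' @param tree A `trait_tree` with at least 2 leaves.
#' @return A single Newick-format string with trait names as leaf labels.
#' @export
as_newick <- function(tree) {
  if (!inherits(tree, "hclust")) abort("`tree` must be a clustering tree")
  if (nrow(tree$merge) < 1L) abort("a Newick export needs at least 2 traits")
  cls <- class(tree)
  class(tree) <- "hclust"
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
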