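#' @include AllClasses.R
NULL

#' Hierarchical clustering of samples or genes
#'
#' Agglomerative clustering via `stats::hclust` with the metric and
#' linkage recorded on the result so every tree is reproducible. The
#' default — Euclidean distance on the supplied values with average
#' linkage — is the common heatmap convention; for sample clustering the
#' usual input is a row-z-scored log2 matrix (see [zscoreRows()]).
#' Merge ties are resolved deterministically by `hclust`'s
#' lowest-index-first convention, so the tree depends only on the input
#' order.
#'
#' @param x an [ImmuneCohort] (any scale; values are used as-is).
#' @param axis cluster `"samples"` (columns) or `"genes"` (rows).
#' @param metric `"euclidean"`, `"manhattan"`, `"maximum"` or
#'   `"correlation"` (1 - Pearson).
#' @param linkage any `hclust` linkage (e.g. `"average"`,
#'   `"complete"`, `"single"`, `"ward.D2"`).
#' @return a [LinkageResult].
#' @examples
#' m <- matrix(rnorm(40), 4, dimnames = list(paste0("g", 1:4),
#'                                           paste0("s", 1:10)))
#' tree <- hierarchicalCluster(ImmuneCohort(m), "samples")
#' leafOrder(tree)
#' @export
hierarchicalCluster <- function(x, axis = c("samples", "genes"),
                                metric = "euclidean",
                                linkage = "average") {
  stopifnot(is(x, "ImmuneCohort"))
  axis <- match.arg(axis)
  v <- exprsMatrix(x)
  if (anyNA(v) || any(!is.finite(v)))
    stop("matrix contains missing or non-finite values", call. = FALSE)
  m <- if (axis == "samples") t(v) else v
  if (nrow(m) < 2L)
    stop("need at least 2 ", axis, " to cluster", call. = FALSE)
  d <- if (metric == "correlation") stats::as.dist(1 - stats::cor(t(m)))
    else stats::dist(m, method = metric)
  hc <- stats::hclust(d, method = linkage)
  new("LinkageResult", tree = list(hclust = hc), metric = metric,
      linkage = linkage, axis = axis)
}

#' @rdname hierarchicalCluster
#' @param tree a [LinkageResult].
#' @return `leafOrder()`: the item labels in dendrogram leaf order, for
#'   heatmap assembly.
#' @export
leafOrder <- function(tree) {
  stopifnot(is(tree, "LinkageResult"))
  hc <- tree@tree$hclust
  hc$labels[hc$order]
}

#' Cut a tree into k groups
#'
#' @param tree a [LinkageResult].
#' @param k number of groups, 1 <= k <= n.
#' @return named integer vector of group memberships (deterministic:
#'   groups numbered by first appearance in input order).
#' @export
cutToK <- function(tree, k) {
  stopifnot(is(tree, "LinkageResult"))
  hc <- tree@tree$hclust
  n <- length(hc$order)
  if (k < 1L || k > n)
    stop("k must be between 1 and ", n, call. = FALSE)
  stats::cutree(hc, k = k)
}

#' Agreement between two partitions (adjusted Rand index)
#'
#' Chance-corrected agreement in [-1, 1]; 1 iff the partitions are
#' identical up to relabeling. Delegates to
#' `mclust::adjustedRandIndex`.
#'
#' @param a,b label vectors over the same items. If both are named the
#'   items are matched by name.
#' @return the adjusted Rand index.
#' @export
labelAgreement <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("partitions are over different item sets", call. = FALSE)
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("partitions have different lengths", call. = FALSE)
  }
  mclust::adjustedRandIndex(a, b)
}

#' Export a tree in Newick format
#'
#' @param tree a [LinkageResult].
#' @param path output file path.
#' @export
exportNewick <- function(tree, path) {
  stopifnot(is(tree, "LinkageResult"))
  ape::write.tree(ape::as.phylo(tree@tree$hclust), file = path)
  invisible(path)
}

#' Reorder a matrix for heatmap display
#'
#' Returns the expression matrix with rows and columns permuted to the
#' dendrogram leaf orders of the supplied trees (either may be `NULL` to
#' leave that axis untouched). A minimal export for eyeballing with
#' `image()`; publication-grade rendering is out of scope.
#'
#' @param x an [ImmuneCohort].
#' @param sampleTree,geneTree [LinkageResult] objects from
#'   [hierarchicalCluster()].
#' @return the reordered numeric matrix.
#' @export
heatmapMatrix <- function(x, sampleTree = NULL, geneTree = NULL) {
  v <- exprsMatrix(x)
  if (!is.null(geneTree)) v <- v[leafOrder(geneTree), , drop = FALSE]
  if (!is.null(sampleTree)) v <- v[, leafOrder(sampleTree), drop = FALSE]
  v
}
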