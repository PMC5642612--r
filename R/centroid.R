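#' @include AllClasses.R
NULL

#' Fit the dual-centroid classifier
#'
#' For each of the four clusters computes two centroids over the signature
#' genes: the main centroid (arithmetic mean of the log2 expression of the
#' cluster's samples) and the alternative centroid (mean of all samples
#' that do not belong to the cluster) — eight centroid vectors in total.
#'
#' @param x a labeled [ImmuneCohort] on the log2 scale with all four
#'   clusters present.
#' @param signature a [SignatureSet] (or character vector of genes).
#'   Signature genes missing from the matrix are dropped with a warning.
#' @param zscore standardize genes before distance computation; the
#'   training means/sds are frozen into the model. Off by default:
#'   distances are computed on unstandardized log2 values.
#' @return a [CentroidModel].
#' @export
fitCentroids <- function(x, signature, zscore = FALSE) {
  stopifnot(is(x, "ImmuneCohort"))
  labels <- clusterLabels(x)
  if (is.null(labels)) stop("cohort has no cluster labels", call. = FALSE)
  absent <- setdiff(CLUSTER_LEVELS, labels)
  if (length(absent))
    stop("cluster(s) absent from labels: ",
         paste(absent, collapse = ", "), call. = FALSE)
  genes <- if (is(signature, "SignatureSet")) signatureGenes(signature)
    else normalizeSymbols(signature)
  keep <- genes[genes %in% rownames(x)]
  if (length(keep) == 0L)
    stop("no signature genes present in the matrix", call. = FALSE)
  if (length(keep) < length(genes))
    warning(length(genes) - length(keep),
            " signature gene(s) missing from the matrix (dropped)")
  X <- exprsMatrix(x)[keep, , drop = FALSE]
  center <- scale <- numeric()
  if (zscore) {
    center <- rowMeans(X)
    scale <- sqrt(rowSums((X - center)^2) / (ncol(X) - 1L))
    if (any(scale == 0))
      stop("zero-variance signature gene; cannot z-score", call. = FALSE)
    X <- (X - center) / scale
    names(center) <- names(scale) <- keep
  }
  main <- vapply(CLUSTER_LEVELS, function(cl)
    rowMeans(X[, labels == cl, drop = FALSE]), numeric(length(keep)))
  alt <- vapply(CLUSTER_LEVELS, function(cl)
    rowMeans(X[, labels != cl, drop = FALSE]), numeric(length(keep)))
  dimnames(main) <- dimnames(alt) <- list(keep, CLUSTER_LEVELS)
  new("CentroidModel", genes = keep, clusters = CLUSTER_LEVELS,
      main = main, alt = alt, zscore = zscore,
      center = unname(center), scale = unname(scale))
}

# distances of columns of X (genes x samples) to each centroid column
centroidDistances <- function(X, C) {
  d <- vapply(seq_len(ncol(C)), function(j)
    sqrt(colSums((X - C[, j])^2)), numeric(ncol(X)))
  if (is.null(dim(d))) d <- matrix(d, nrow = ncol(X))
  colnames(d) <- colnames(C)
  rownames(d) <- colnames(X)
  d
}

applyModelScaling <- function(X, model) {
  if (model@zscore) (X - model@center) / model@scale else X
}

#' Assign a single sample to a cluster
#'
#' Computes the Euclidean distance of the sample to each of the eight
#' centroids. The sample is assigned to the cluster whose main centroid
#' is nearest, but only if that distance is strictly smaller than the
#' distance to the same cluster's alternative centroid; otherwise (and on
#' a tie among main-centroid minima, with a warning) the sample is
#' `"UNCLASSIFIED"`.
#'
#' @param sample numeric expression vector over the model's signature
#'   genes (in model gene order, or named).
#' @param model a [CentroidModel].
#' @return a single label: `"I"`, `"II"`, `"III"`, `"IV"` or
#'   `"UNCLASSIFIED"`.
#' @export
assignSample <- function(sample, model) {
  stopifnot(is(model, "CentroidModel"))
  if (!is.null(names(sample))) sample <- sample[model@genes]
  if (length(sample) != length(model@genes))
    stop("sample vector length does not match model genes", call. = FALSE)
  if (any(!is.finite(sample)))
    stop("non-finite values in sample vector", call. = FALSE)
  X <- matrix(sample, ncol = 1L,
              dimnames = list(model@genes, "s"))
  X <- applyModelScaling(X, model)
  dm <- centroidDistances(X, model@main)[1L, ]
  da <- centroidDistances(X, model@alt)[1L, ]
  decideLabel(dm, da, model@clusters)
}

decideLabel <- function(dm, da, clusters) {
  best <- which(dm == min(dm))
  if (length(best) > 1L) {
    warning("tie among main-centroid distances; sample unclassified")
    return(UNCLASSIFIED)
  }
  if (dm[best] < da[best]) clusters[best] else UNCLASSIFIED
}

#' Assign every sample of a cohort
#'
#' Applies the dual-centroid rule of [assignSample()] to each sample.
#' Signature genes missing from the cohort are dropped from the model
#' symmetrically for this cohort (warning; a stronger warning above 10%
#' missing).
#'
#' @param x an [ImmuneCohort] on the log2 scale.
#' @param model a [CentroidModel].
#' @return an [AssignmentResult].
#' @export
assignCohort <- function(x, model) {
  stopifnot(is(x, "ImmuneCohort"), is(model, "CentroidModel"))
  if (ncol(x) == 0L || nrow(x) == 0L)
    stop("empty expression matrix", call. = FALSE)
  keep <- model@genes %in% rownames(x)
  if (!any(keep))
    stop("none of the model genes are present in the cohort",
         call. = FALSE)
  if (any(!keep)) {
    frac <- mean(!keep)
    warning(sum(!keep), " model gene(s) missing from the cohort ",
            "(dropped symmetrically)",
            if (frac > 0.1) " -- more than 10% of the signature is missing",
            call. = FALSE)
  }
  idx <- which(keep)
  X <- exprsMatrix(x)[model@genes[idx], , drop = FALSE]
  if (any(!is.finite(X)))
    stop("non-finite expression values", call. = FALSE)
  if (model@zscore)
    X <- (X - model@center[idx]) / model@scale[idx]
  dm <- centroidDistances(X, model@main[idx, , drop = FALSE])
  da <- centroidDistances(X, model@alt[idx, , drop = FALSE])
  labels <- vapply(seq_len(nrow(dm)), function(i)
    decideLabel(dm[i, ], da[i, ], model@clusters), character(1))
  names(labels) <- colnames(x)
  new("AssignmentResult", labels = labels, distMain = dm, distAlt = da)
}

#' Write an assignment table
#'
#' One row per sample: assigned label and the eight centroid distances.
#'
#' @param x an [AssignmentResult].
#' @param path output TSV path.
#' @export
writeAssignmentTSV <- function(x, path) {
  stopifnot(is(x, "AssignmentResult"))
  df <- data.frame(sample = names(x@labels), assigned = unname(x@labels),
                   stats::setNames(as.data.frame(x@distMain),
                                   paste0("d_main_", colnames(x@distMain))),
                   stats::setNames(as.data.frame(x@distAlt),
                                   paste0("d_alt_", colnames(x@distAlt))),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
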