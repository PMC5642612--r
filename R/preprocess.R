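#' @include AllClasses.R io.R
NULL

#' Log2-transform a raw-scale expression cohort
#'
#' Applies `log2(x + pseudocount)` entry-wise. The default pseudocount of
#' 1 is the usual choice for RSEM-style normalized values, which contain
#' exact zeros.
#'
#' @param x an [ImmuneCohort] on the raw scale.
#' @param pseudocount non-negative value added before taking logs. A
#'   pseudocount of 0 is an error whenever the matrix contains zeros.
#' @return the cohort on the log2 scale.
#' @examples
#' m <- matrix(c(0, 7, 1, 3), 2, dimnames = list(c("A", "B"), c("s1", "s2")))
#' exprsMatrix(log2Transform(ImmuneCohort(m, scale = "raw")))
#' @export
log2Transform <- function(x, pseudocount = 1) {
  stopifnot(is(x, "ImmuneCohort"))
  if (!identical(expressionScale(x), "raw"))
    stop("log2Transform() requires a raw-scale cohort (scale is '",
         expressionScale(x), "')", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be non-negative",
                            call. = FALSE)
  v <- exprsMatrix(x)
  if (any(v < 0)) stop("negative values in raw-scale matrix",
                       call. = FALSE)
  if (pseudocount == 0 && any(v == 0))
    stop("pseudocount 0 with zero values would produce -Inf",
         call. = FALSE)
  out <- x
  SummarizedExperiment::assay(out, "exprs") <- log2(v + pseudocount)
  metadata(out)$scale <- "log2"
  validObject(out)
  out
}

#' Restrict a cohort to the genes of a panel
#'
#' Returns the cohort restricted to `panel` genes present in the matrix,
#' in panel order. Panel genes absent from the matrix are dropped with a
#' warning and recorded in `metadata(x)$missingGenes`.
#'
#' @param x an [ImmuneCohort].
#' @param panel a [GenePanel].
#' @return the restricted cohort; the missing panel genes are in
#'   `metadata()$missingGenes`.
#' @export
subsetToPanel <- function(x, panel) {
  stopifnot(is(x, "ImmuneCohort"), is(panel, "GenePanel"))
  pg <- panelGenes(panel)
  keep <- pg[pg %in% rownames(x)]
  if (length(keep) == 0L)
    stop("no panel genes found in the expression matrix", call. = FALSE)
  missing <- setdiff(pg, keep)
  if (length(missing))
    warning(length(missing), " of ", length(pg),
            " panel genes absent from the matrix (dropped)")
  out <- x[keep, ]
  out <- as(out, "ImmuneCohort")
  metadata(out)$missingGenes <- missing
  out
}

#' Gene-wise z-scoring
#'
#' Centers and scales each gene (row) to mean 0 and sd 1, using the
#' sample standard deviation (n - 1 denominator). Intended for display
#' (heatmap) purposes; ranking and centroid fitting operate on the log2
#' scale.
#'
#' @param x an [ImmuneCohort] on the log2 scale.
#' @return the cohort on the zscore scale.
#' @export
zscoreRows <- function(x) {
  stopifnot(is(x, "ImmuneCohort"))
  if (!identical(expressionScale(x), "log2"))
    stop("zscoreRows() requires a log2-scale cohort", call. = FALSE)
  v <- exprsMatrix(x)
  mu <- rowMeans(v)
  sdv <- sqrt(rowSums((v - mu)^2) / (ncol(v) - 1L))
  zero <- sdv == 0
  if (any(zero))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(v)[zero], 5), collapse = ", "),
         call. = FALSE)
  out <- x
  SummarizedExperiment::assay(out, "exprs") <- (v - mu) / sdv
  metadata(out)$scale <- "zscore"
  validObject(out)
  out
}
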