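#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#'   rowData<- colData<-
NULL

CLUSTER_LEVELS <- c("I", "II", "III", "IV")
UNCLASSIFIED <- "UNCLASSIFIED"

#' GenePanel: a named set of gene symbols
#'
#' A gene panel is an ordered set of HGNC-style gene symbols with a short
#' name and a free-text provenance tag. Symbols are stored trimmed and
#' upper-cased; duplicates (after case-normalisation) are collapsed at
#' construction time.
#'
#' @slot name single character identifier.
#' @slot genes character vector of unique, upper-case gene symbols.
#' @slot source free-text provenance tag.
#' @export
setClass("GenePanel",
  representation(name = "character", genes = "character", source = "character"))

setValidity("GenePanel", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@genes) == 0L)
    msg <- c(msg, "panel must contain at least one gene")
  if (any(is.na(object@genes)) || any(!nzchar(trimws(object@genes))))
    msg <- c(msg, "gene symbols must be non-empty strings")
  if (anyDuplicated(toupper(object@genes)))
    msg <- c(msg, "duplicate gene symbols after case-normalisation")
  if (length(msg)) msg else TRUE
})

#' PanelRegistry: a collection of gene panels and their union
#'
#' Houses named [GenePanel] objects together with their combined (union)
#' panel and a per-gene membership table recording which source panels
#' contain each gene.
#'
#' @slot panels named list of [GenePanel] objects.
#' @slot combined [GenePanel] holding the sorted union of all member panels.
#' @slot membership data.frame with columns `gene` and `panels`
#'   (comma-separated source panel names).
#' @export
setClass("PanelRegistry",
  representation(panels = "list", combined = "GenePanel",
                 membership = "data.frame"))

setValidity("PanelRegistry", function(object) {
  msg <- character()
  if (length(object@panels) == 0L)
    msg <- c(msg, "registry must contain at least one panel")
  if (!all(vapply(object@panels, is, logical(1), "GenePanel")))
    msg <- c(msg, "all registry members must be GenePanel objects")
  else {
    expect <- sort(unique(toupper(unlist(lapply(object@panels,
                                                function(p) p@genes)))))
    if (!identical(sort(object@combined@genes), expect))
      msg <- c(msg, "'combined' does not equal the union of member panels")
  }
  if (length(msg)) msg else TRUE
})

#' ImmuneCohort: a gene-by-sample expression container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a tracked
#' expression scale (`raw`, `log2` or `zscore`, kept in
#' `metadata(x)$scale`), optional per-sample cluster labels
#' (`colData(x)$cluster`) and optional per-gene truth status
#' (`rowData(x)$status`, used by the synthetic generators).
#'
#' @export
setClass("ImmuneCohort", contains = "SummarizedExperiment")

setValidity("ImmuneCohort", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  sc <- metadata(object)$scale
  if (is.null(sc) || !sc %in% c("raw", "log2", "zscore"))
    msg <- c(msg, "metadata 'scale' must be one of 'raw', 'log2', 'zscore'")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "rownames (gene symbols) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "colnames (sample IDs) must be present and unique")
  if ("exprs" %in% SummarizedExperiment::assayNames(object)) {
    v <- assay(object, "exprs")
    if (identical(sc, "raw") && any(v < 0, na.rm = TRUE))
      msg <- c(msg, "raw-scale values must be non-negative")
    if (!identical(sc, "raw") && any(!is.finite(v)))
      msg <- c(msg, "log2/zscore values must all be finite")
    if (anyNA(v)) msg <- c(msg, "expression values must not be missing")
  }
  if ("cluster" %in% colnames(colData(object)) &&
      anyNA(colData(object)$cluster))
    msg <- c(msg, "cluster labels must not contain NA")
  if (length(msg)) msg else TRUE
})

#' RankingTable: a one-vs-rest gene ranking for one panel and target cluster
#'
#' @slot panel name of the panel the ranking was computed over.
#' @slot targetCluster the cluster discriminated from the rest.
#' @slot table data.frame ordered by aggregate rank, with one row per gene
#'   and columns `gene`, five per-ranker scores (`score_*`), five per-ranker
#'   ranks (`rank_*`), `meanRank` (mean of the five per-ranker ranks) and
#'   `aggRank` (1..m after lexicographic tie-breaking).
#' @export
setClass("RankingTable",
  representation(panel = "character", targetCluster = "character",
                 table = "data.frame"))

setValidity("RankingTable", function(object) {
  tb <- object@table
  msg <- character()
  need <- c("gene", "meanRank", "aggRank")
  if (!all(need %in% colnames(tb)))
    msg <- c(msg, "ranking table must have gene/meanRank/aggRank columns")
  else {
    if (!identical(tb$aggRank, seq_len(nrow(tb))))
      msg <- c(msg, "aggregate ranks must be 1..m without gaps")
    if (anyDuplicated(tb$gene))
      msg <- c(msg, "duplicate genes in ranking table")
  }
  if (length(msg)) msg else TRUE
})

#' SignatureSet: a merged top-fraction gene signature
#'
#' @slot genes sorted character vector of signature gene symbols.
#' @slot fraction the top fraction q used per ranking table.
#' @slot sourceTables identifiers (panel:cluster) of the contributing tables.
#' @export
setClass("SignatureSet",
  representation(genes = "character", fraction = "numeric",
                 sourceTables = "character"))

setValidity("SignatureSet", function(object) {
  msg <- character()
  if (length(object@genes) == 0L) msg <- c(msg, "empty signature")
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate signature genes")
  if (length(object@fraction) != 1L || object@fraction <= 0 ||
      object@fraction > 1)
    msg <- c(msg, "'fraction' must be a single value in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' CentroidModel: main and alternative centroids per cluster
#'
#' For each of the four clusters the model stores a main centroid (mean
#' log2 expression of the cluster's training samples over the signature
#' genes) and an alternative centroid (mean over all training samples not
#' in that cluster): eight centroid vectors in total.
#'
#' @slot genes signature genes (row order of the centroid matrices).
#' @slot clusters cluster names, `c("I","II","III","IV")`.
#' @slot main numeric matrix, genes x clusters, main centroids.
#' @slot alt numeric matrix, genes x clusters, alternative centroids.
#' @slot zscore logical; whether gene-wise standardisation (frozen from the
#'   training cohort) is applied before distances.
#' @slot center,scale numeric vectors of training means/sds per gene
#'   (length 0 when `zscore` is FALSE).
#' @export
setClass("CentroidModel",
  representation(genes = "character", clusters = "character",
                 main = "matrix", alt = "matrix",
                 zscore = "logical", center = "numeric", scale = "numeric"))

setValidity("CentroidModel", function(object) {
  msg <- character()
  g <- length(object@genes)
  if (length(object@clusters) != 4L)
    msg <- c(msg, "exactly four clusters required")
  if (!identical(dim(object@main), c(g, 4L)) ||
      !identical(dim(object@alt), c(g, 4L)))
    msg <- c(msg, "centroid matrices must be |genes| x 4")
  if (any(!is.finite(object@main)) || any(!is.finite(object@alt)))
    msg <- c(msg, "all 8 centroid vectors must be finite")
  if (object@zscore &&
      (length(object@center) != g || length(object@scale) != g))
    msg <- c(msg, "zscore model requires center/scale per gene")
  if (length(msg)) msg else TRUE
})

#' AssignmentResult: per-sample centroid distances and assigned labels
#'
#' @slot labels named character vector of assigned labels (cluster name or
#'   `"UNCLASSIFIED"`), one per sample.
#' @slot distMain,distAlt numeric matrices (samples x 4) of Euclidean
#'   distances to the main and alternative centroids.
#' @export
setClass("AssignmentResult",
  representation(labels = "character", distMain = "matrix",
                 distAlt = "matrix"))

setValidity("AssignmentResult", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (nrow(object@distMain) != n || nrow(object@distAlt) != n)
    msg <- c(msg, "distance matrices must have one row per sample")
  if (!all(object@labels %in% c(CLUSTER_LEVELS, UNCLASSIFIED)))
    msg <- c(msg, "labels must be cluster names or UNCLASSIFIED")
  if (length(msg)) msg else TRUE
})

#' LinkageResult: a hierarchical clustering tree with recorded parameters
#'
#' Wraps a `stats::hclust` merge tree together with the metric and linkage
#' used, so downstream cuts, leaf orders and exports are reproducible.
#'
#' @slot tree list holding the underlying `hclust` object.
#' @slot metric,linkage names of the distance metric and linkage used.
#' @slot axis `"samples"` or `"genes"`.
#' @export
setClass("LinkageResult",
  representation(tree = "list", metric = "character",
                 linkage = "character", axis = "character"))

setValidity("LinkageResult", function(object) {
  hc <- object@tree$hclust
  msg <- character()
  if (is.null(hc) || !inherits(hc, "hclust"))
    msg <- c(msg, "tree must contain an 'hclust' object")
  else if (nrow(hc$merge) != length(hc$order) - 1L)
    msg <- c(msg, "n leaves require n-1 merges")
  if (length(msg)) msg else TRUE
})

#' AnnotationCatalog: gene-set categories over a reference list
#'
#' @slot referenceSize total number of genes N in the reference list.
#' @slot categories named list of character vectors (category gene sets).
#' @slot referenceGenes optional explicit reference gene universe (may be
#'   empty, in which case list sizes are taken at face value).
#' @export
setClass("AnnotationCatalog",
  representation(referenceSize = "integer", categories = "list",
                 referenceGenes = "character"))

setValidity("AnnotationCatalog", function(object) {
  msg <- character()
  N <- object@referenceSize
  if (length(N) != 1L || is.na(N) || N <= 0L)
    msg <- c(msg, "referenceSize must be a single positive integer")
  K <- lengths(object@categories)
  if (length(K) == 0L || is.null(names(object@categories)))
    msg <- c(msg, "categories must be a non-empty named list")
  else if (any(K < 1L) || any(K > N))
    msg <- c(msg, "every category must satisfy 1 <= K <= N")
  if (length(msg)) msg else TRUE
})

#' EnrichmentResult: rows of a binomial over/under-representation analysis
#'
#' @slot table data.frame with one row per category: `category`, `K`
#'   (reference count), `k` (observed count), `n` (analysed-list size),
#'   `E` (expected count), `direction` (`"+"`/`"-"`), `FE` (fold
#'   enrichment), `p_raw`, `B` (Bonferroni count) and `p_corr`.
#' @slot n,N,B analysed-list size, reference size and Bonferroni count.
#' @export
setClass("EnrichmentResult",
  representation(table = "data.frame", n = "integer", N = "integer",
                 B = "integer"))

setValidity("EnrichmentResult", function(object) {
  tb <- object@table
  need <- c("category", "K", "k", "n", "E", "direction", "FE",
            "p_raw", "B", "p_corr")
  msg <- character()
  if (!all(need %in% colnames(tb)))
    msg <- c(msg, paste("table must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (any(tb$p_corr < tb$p_raw - 1e-15))
      msg <- c(msg, "corrected p must be >= raw p")
    if (any(tb$p_corr > 1 + 1e-15) || any(tb$p_raw < 0))
      msg <- c(msg, "p-values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
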