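#' @include AllClasses.R
NULL

#' Accessors for immunosig classes
#'
#' Small accessor generics: `panelGenes()` and `panelName()` for
#' [GenePanel], `combinedPanel()` and `panelMembership()` for
#' [PanelRegistry], `signatureGenes()` for [SignatureSet],
#' `clusterLabels()` / `expressionScale()` / `exprsMatrix()` for
#' [ImmuneCohort], `assignedLabels()` and `assignmentDistances()` for
#' [AssignmentResult], `rankingFrame()` for [RankingTable],
#' `enrichmentFrame()` for [EnrichmentResult], and `centroidMatrix()`
#' for [CentroidModel].
#'
#' @param x an immunosig object.
#' @param ... unused.
#' @return the underlying vector, matrix or data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))
#' @rdname accessors
#' @export
setMethod("panelGenes", "GenePanel", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("panelName", function(x) standardGeneric("panelName"))
#' @rdname accessors
#' @export
setMethod("panelName", "GenePanel", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("length", "GenePanel", function(x) length(x@genes))

#' @rdname accessors
#' @export
setGeneric("combinedPanel", function(x) standardGeneric("combinedPanel"))
#' @rdname accessors
#' @export
setMethod("combinedPanel", "PanelRegistry", function(x) x@combined)

#' @rdname accessors
#' @export
setGeneric("panelMembership", function(x) standardGeneric("panelMembership"))
#' @rdname accessors
#' @export
setMethod("panelMembership", "PanelRegistry", function(x) x@membership)

#' @rdname accessors
#' @param name panel name.
#' @export
setGeneric("getPanel", function(x, name) standardGeneric("getPanel"))
#' @rdname accessors
#' @export
setMethod("getPanel", "PanelRegistry", function(x, name) {
  if (!name %in% names(x@panels))
    stop("no panel named '", name, "' in registry", call. = FALSE)
  x@panels[[name]]
})

#' @rdname accessors
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))
#' @rdname accessors
#' @export
setMethod("signatureGenes", "SignatureSet", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("length", "SignatureSet", function(x) length(x@genes))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ImmuneCohort", function(x) {
  cd <- colData(x)
  if (!"cluster" %in% colnames(cd)) return(NULL)
  stats::setNames(as.character(cd$cluster), colnames(x))
})

#' @rdname accessors
#' @export
setGeneric("expressionScale", function(x) standardGeneric("expressionScale"))
#' @rdname accessors
#' @export
setMethod("expressionScale", "ImmuneCohort", function(x) metadata(x)$scale)

#' @rdname accessors
#' @export
setGeneric("exprsMatrix", function(x) standardGeneric("exprsMatrix"))
#' @rdname accessors
#' @export
setMethod("exprsMatrix", "ImmuneCohort", function(x) assay(x, "exprs"))

#' @rdname accessors
#' @export
setGeneric("assignedLabels", function(x) standardGeneric("assignedLabels"))
#' @rdname accessors
#' @export
setMethod("assignedLabels", "AssignmentResult", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("assignmentDistances",
           function(x) standardGeneric("assignmentDistances"))
#' @rdname accessors
#' @export
setMethod("assignmentDistances", "AssignmentResult", function(x)
  list(main = x@distMain, alt = x@distAlt))

#' @rdname accessors
#' @export
setGeneric("rankingFrame", function(x) standardGeneric("rankingFrame"))
#' @rdname accessors
#' @export
setMethod("rankingFrame", "RankingTable", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("enrichmentFrame", function(x) standardGeneric("enrichmentFrame"))
#' @rdname accessors
#' @export
setMethod("enrichmentFrame", "EnrichmentResult", function(x) x@table)

#' @rdname accessors
#' @param which `"main"` or `"alt"`.
#' @export
setGeneric("centroidMatrix",
           function(x, which = c("main", "alt")) standardGeneric("centroidMatrix"))
#' @rdname accessors
#' @export
setMethod("centroidMatrix", "CentroidModel", function(x, which = c("main", "alt")) {
  which <- match.arg(which)
  if (which == "main") x@main else x@alt
})

setMethod("show", "GenePanel", function(object) {
  cat("GenePanel '", object@name, "': ", length(object@genes), " genes",
      if (nzchar(object@source)) paste0(" [", object@source, "]"), "\n",
      sep = "")
})

setMethod("show", "PanelRegistry", function(object) {
  cat("PanelRegistry with", length(object@panels), "panels:\n")
  for (p in object@panels)
    cat("  ", p@name, ": ", length(p@genes), " genes\n", sep = "")
  cat("  combined: ", length(object@combined@genes), " unique genes\n",
      sep = "")
})

setMethod("show", "RankingTable", function(object) {
  cat("RankingTable (panel '", object@panel, "', cluster ",
      object@targetCluster, " vs rest): ", nrow(object@table),
      " genes ranked\n", sep = "")
  cat("  top genes:",
      paste(utils::head(object@table$gene, 5), collapse = ", "), "\n")
})

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet: ", length(object@genes), " genes (top fraction q = ",
      object@fraction, " over ", length(object@sourceTables),
      " ranking tables)\n", sep = "")
})

setMethod("show", "CentroidModel", function(object) {
  cat("CentroidModel: ", length(object@genes), " signature genes, ",
      2L * length(object@clusters), " centroid vectors (main + alternative",
      " per cluster)\n", sep = "")
  if (object@zscore) cat("  gene-wise z-scoring: on (training statistics frozen)\n")
})

setMethod("show", "AssignmentResult", function(object) {
  cat("AssignmentResult for", length(object@labels), "samples\n")
  print(table(factor(object@labels,
                     levels = c(CLUSTER_LEVELS, UNCLASSIFIED))))
})

setMethod("show", "LinkageResult", function(object) {
  hc <- object@tree$hclust
  cat("LinkageResult: ", length(hc$order), " ", object@axis,
      " (metric = ", object@metric, ", linkage = ", object@linkage, ")\n",
      sep = "")
})

setMethod("show", "AnnotationCatalog", function(object) {
  cat("AnnotationCatalog: ", length(object@categories),
      " categories over a reference list of ", object@referenceSize,
      " genes\n", sep = "")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult: ", nrow(object@table), " categories (n = ",
      object@n, ", N = ", object@N, ", Bonferroni count = ", object@B,
      ")\n", sep = "")
  print(utils::head(formatEnrichment(object), 5))
})
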