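#' @include AllClasses.R
NULL

#' Construct an expression cohort
#'
#' Wraps a numeric gene-by-sample matrix into an [ImmuneCohort]
#' (a `SummarizedExperiment` subclass) with a tracked expression scale and
#' optional cluster labels / gene status.
#'
#' @param values numeric matrix, genes x samples, with row and column names.
#' @param scale one of `"raw"`, `"log2"`, `"zscore"`.
#' @param cluster optional per-sample cluster labels (named or in column
#'   order).
#' @param status optional per-gene status (e.g. `"responsive"` /
#'   `"background"`), in row order.
#' @return an [ImmuneCohort].
#' @export
ImmuneCohort <- function(values, scale = c("log2", "raw", "zscore"),
                         cluster = NULL, status = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  if (!is.null(cluster)) {
    if (!is.null(names(cluster))) cluster <- cluster[colnames(values)]
    cd$cluster <- as.character(cluster)
  }
  rd <- S4Vectors::DataFrame(row.names = rownames(values))
  if (!is.null(status)) rd$status <- status
  se <- SummarizedExperiment(assays = list(exprs = values),
                             rowData = rd, colData = cd)
  metadata(se)$scale <- scale
  new("ImmuneCohort", se)
}

#' Read / write an expression TSV
#'
#' The on-disk convention is a tab-separated table with genes as rows, a
#' header row of sample IDs, and a first column of gene symbols labelled
#' `gene` or `gene_id`.
#'
#' @param path file path.
#' @param scale expression scale to record on the returned cohort.
#' @return `readExpressionTSV()` returns an [ImmuneCohort];
#'   `writeExpressionTSV()` returns `path` invisibly.
#' @export
readExpressionTSV <- function(path, scale = c("log2", "raw", "zscore")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("expression file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  first <- tolower(colnames(df)[1L])
  if (!first %in% c("gene", "gene_id"))
    stop("first column must be labelled 'gene' or 'gene_id', got '",
         colnames(df)[1L], "'", call. = FALSE)
  genes <- df[[1L]]
  if (anyDuplicated(genes))
    stop("duplicate gene symbols in ", path, call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- genes
  ImmuneCohort(m, scale = scale)
}

#' @rdname readExpressionTSV
#' @param x an [ImmuneCohort].
#' @export
writeExpressionTSV <- function(x, path) {
  stopifnot(is(x, "ImmuneCohort"))
  df <- data.frame(gene = rownames(x), exprsMatrix(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a two-column sample labels TSV
#'
#' Columns `sample` and `cluster`, tab-separated, with header.
#'
#' @param path file path.
#' @return `readLabelsTSV()` returns a named character vector of cluster
#'   labels.
#' @export
readLabelsTSV <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "cluster") %in% colnames(df)))
  stats::setNames(as.character(df$cluster), df$sample)
}

#' @rdname readLabelsTSV
#' @param labels named character vector (sample -> cluster).
#' @export
writeLabelsTSV <- function(labels, path) {
  utils::write.table(data.frame(sample = names(labels),
                                cluster = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene-set catalogs in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields (name, description,
#' members...). Reading is delegated to `fgsea::gmtPathways()`. Because a
#' GMT file does not carry the size of the reference gene list, `N` (or an
#' explicit reference gene universe) must be supplied to build an
#' [AnnotationCatalog].
#'
#' @param path GMT file path.
#' @param referenceSize reference-list size N; defaults to the number of
#'   unique genes across all sets (or the length of `referenceGenes`).
#' @param referenceGenes optional explicit reference gene universe.
#' @return `readAnnotationCatalog()` returns an [AnnotationCatalog].
#' @export
readAnnotationCatalog <- function(path, referenceSize = NULL,
                                  referenceGenes = character()) {
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, normalizeSymbols)
  referenceGenes <- normalizeSymbols(referenceGenes)
  if (is.null(referenceSize))
    referenceSize <- if (length(referenceGenes)) length(referenceGenes)
      else length(unique(unlist(sets)))
  new("AnnotationCatalog", referenceSize = as.integer(referenceSize),
      categories = sets, referenceGenes = referenceGenes)
}

#' @rdname readAnnotationCatalog
#' @param catalog an [AnnotationCatalog].
#' @export
writeAnnotationGMT <- function(catalog, path) {
  stopifnot(is(catalog, "AnnotationCatalog"))
  lines <- vapply(names(catalog@categories), function(nm)
    paste(c(nm, "na", catalog@categories[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize / deserialize a centroid model
#'
#' The on-disk form is a TSV bundle: a JSON header line (prefixed `#`)
#' carrying the options and cluster names, followed by a table with the
#' gene list and the eight centroid columns.
#'
#' @param model a [CentroidModel].
#' @param path file path.
#' @export
writeCentroidModel <- function(model, path) {
  stopifnot(is(model, "CentroidModel"))
  hdr <- jsonlite::toJSON(list(clusters = model@clusters,
                               zscore = model@zscore), auto_unbox = TRUE)
  df <- data.frame(gene = model@genes,
                   stats::setNames(as.data.frame(model@main),
                                   paste0("main_", model@clusters)),
                   stats::setNames(as.data.frame(model@alt),
                                   paste0("alt_", model@clusters)),
                   check.names = FALSE)
  if (model@zscore) { df$center <- model@center; df$scale <- model@scale }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCentroidModel
#' @export
readCentroidModel <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(sub("^#", "", lines[1L]))
  df <- utils::read.delim(text = lines[-1L], stringsAsFactors = FALSE)
  cl <- hdr$clusters
  main <- as.matrix(df[paste0("main_", cl)])
  alt <- as.matrix(df[paste0("alt_", cl)])
  dimnames(main) <- dimnames(alt) <- list(df$gene, cl)
  new("CentroidModel", genes = df$gene, clusters = cl, main = main,
      alt = alt, zscore = isTRUE(hdr$zscore),
      center = if (isTRUE(hdr$zscore)) df$center else numeric(),
      scale = if (isTRUE(hdr$zscore)) df$scale else numeric())
}
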