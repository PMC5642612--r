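#' @include AllClasses.R panels.R io.R preprocess.R rank.R centroid.R hier.R enrichment.R
NULL

#' Pipeline configuration
#'
#' Collects the file paths and stage parameters of an end-to-end run.
#' All referenced files must exist at run time.
#'
#' @param expression1 expression TSV of the labeled discovery cohort.
#' @param labels1 two-column labels TSV for cohort 1.
#' @param expression2 optional expression TSV of the validation cohort.
#' @param panelPaths optional named character vector of panel files; when
#'   `NULL` the packaged registry ([immunePanelRegistry()]) is used.
#' @param catalogGMT optional GMT file for the enrichment stage.
#' @param catalogN reference-list size for the catalog.
#' @param inputScale scale of the expression TSVs (`"raw"` is
#'   log2-transformed with `pseudocount`).
#' @param pseudocount pseudocount for the log2 transform.
#' @param qPanel top fraction for the per-panel signature (default 0.20).
#' @param qCombined top fraction for the combined-panel signature
#'   (default 0.05).
#' @param classifierPanel panel whose signature feeds the centroid
#'   classifier.
#' @param metric,linkage hierarchical clustering parameters.
#' @param zscoreClassifier standardize genes in the classifier.
#' @param bonferroniCount optional Bonferroni count override.
#' @param seed integer seed recorded in the manifest.
#' @param outDir output directory (created if absent).
#' @return a validated configuration list.
#' @export
pipelineConfig <- function(expression1, labels1, expression2 = NULL,
                           panelPaths = NULL, catalogGMT = NULL,
                           catalogN = NULL,
                           inputScale = c("log2", "raw"),
                           pseudocount = 1, qPanel = 0.20,
                           qCombined = 0.05,
                           classifierPanel = "nanostring",
                           metric = "euclidean", linkage = "average",
                           zscoreClassifier = FALSE,
                           bonferroniCount = NULL, seed = 1L,
                           outDir = tempfile("immunosig_run")) {
  inputScale <- match.arg(inputScale)
  stopifnot(qPanel > 0, qPanel <= 1, qCombined > 0, qCombined <= 1)
  for (f in c(expression1, labels1, expression2, panelPaths, catalogGMT))
    if (!is.null(f) && !file.exists(f))
      stop("input file not found: ", f, call. = FALSE)
  list(expression1 = expression1, labels1 = labels1,
       expression2 = expression2, panelPaths = panelPaths,
       catalogGMT = catalogGMT, catalogN = catalogN,
       inputScale = inputScale, pseudocount = pseudocount,
       qPanel = qPanel, qCombined = qCombined,
       classifierPanel = classifierPanel, metric = metric,
       linkage = linkage, zscoreClassifier = zscoreClassifier,
       bonferroniCount = bonferroniCount, seed = as.integer(seed),
       outDir = outDir)
}

stageStep <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full subtyping pipeline
#'
#' Executes preprocess, one-vs-rest ranking over every panel and the
#' combined panel, top-fraction signature construction (per-panel
#' fraction and combined fraction), centroid fitting on the labeled
#' discovery cohort, assignment of the validation cohort, unsupervised
#' hierarchical clustering of both cohorts on the combined signature,
#' and (when a catalog is configured) over-representation analysis of
#' both signatures. Every output is written under `config$outDir` and a
#' JSON manifest records the inputs, parameters and output checksums, so
#' two runs with an identical configuration are byte-identical.
#'
#' @param config from [pipelineConfig()].
#' @return the manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  out <- character()
  emit <- function(path) { out <<- c(out, path); path }

  cohort1 <- stageStep("preprocess", {
    co <- readExpressionTSV(config$expression1, scale = config$inputScale)
    if (config$inputScale == "raw")
      co <- log2Transform(co, config$pseudocount)
    labs <- readLabelsTSV(config$labels1)
    colData(co)$cluster <- unname(labs[colnames(co)])
    validObject(co)
    co
  })

  registry <- stageStep("panels", {
    if (is.null(config$panelPaths)) immunePanelRegistry()
    else panelRegistry(Map(loadPanel, config$panelPaths,
                           names(config$panelPaths)))
  })

  tables <- stageStep("rank", {
    tabs <- buildRankingTables(cohort1, registry, combined = TRUE)
    for (nm in names(tabs))
      writeRankingTSV(tabs[[nm]],
                      emit(file.path(config$outDir,
                                     paste0("ranking_", gsub(":", "_", nm),
                                            ".tsv"))))
    tabs
  })

  sigs <- stageStep("select", {
    panelTabs <- tables[grep(paste0("^", config$classifierPanel, ":"),
                             names(tables))]
    combTabs <- tables[grep("^combined:", names(tables))]
    sigPanel <- topFractionUnion(panelTabs, config$qPanel)
    sigComb <- topFractionUnion(combTabs, config$qCombined)
    writeSignature(sigPanel,
                   emit(file.path(config$outDir, "signature_panel.txt")))
    writeSignature(sigComb,
                   emit(file.path(config$outDir, "signature_combined.txt")))
    list(panel = sigPanel, combined = sigComb)
  })

  model <- stageStep("fit", {
    m <- fitCentroids(cohort1, sigs$panel,
                      zscore = config$zscoreClassifier)
    writeCentroidModel(m, emit(file.path(config$outDir,
                                         "centroid_model.tsv")))
    m
  })

  assign1 <- stageStep("assign", {
    a1 <- assignCohort(cohort1, model)
    writeAssignmentTSV(a1, emit(file.path(config$outDir,
                                          "assignment_cohort1.tsv")))
    a1
  })

  cohort2 <- NULL
  if (!is.null(config$expression2)) {
    cohort2 <- stageStep("preprocess2", {
      co <- readExpressionTSV(config$expression2,
                              scale = config$inputScale)
      if (config$inputScale == "raw")
        co <- log2Transform(co, config$pseudocount)
      co
    })
    stageStep("assign2", {
      a2 <- assignCohort(cohort2, model)
      writeAssignmentTSV(a2, emit(file.path(config$outDir,
                                            "assignment_cohort2.tsv")))
    })
  }

  stageStep("cluster", {
    for (nm in c("cohort1", if (!is.null(cohort2)) "cohort2")) {
      co <- if (nm == "cohort1") cohort1 else cohort2
      sub <- suppressWarnings(
        subsetToPanel(co, GenePanel(signatureGenes(sigs$combined),
                                    "signature")))
      tree <- hierarchicalCluster(zscoreRows(sub), "samples",
                                  metric = config$metric,
                                  linkage = config$linkage)
      writeLines(leafOrder(tree),
                 emit(file.path(config$outDir,
                                paste0("leaforder_", nm, ".txt"))))
      exportNewick(tree, emit(file.path(config$outDir,
                                        paste0("tree_", nm, ".nwk"))))
      k4 <- cutToK(tree, 4L)
      writeLabelsTSV(stats::setNames(as.character(k4), names(k4)),
                     emit(file.path(config$outDir,
                                    paste0("cut4_", nm, ".tsv"))))
    }
  })

  if (!is.null(config$catalogGMT)) {
    stageStep("enrich", {
      catalog <- readAnnotationCatalog(config$catalogGMT,
                                       referenceSize = config$catalogN)
      for (nm in c("panel", "combined")) {
        er <- runOverrepresentation(signatureGenes(sigs[[nm]]), catalog,
                                    B = config$bonferroniCount)
        writeEnrichmentTSV(er,
                           emit(file.path(config$outDir,
                                          paste0("enrichment_", nm,
                                                 ".tsv"))))
      }
    })
  }

  manifest <- list(
    package = "immunosig",
    version = as.character(utils::packageVersion("immunosig")),
    seed = config$seed,
    parameters = config[c("inputScale", "pseudocount", "qPanel",
                          "qCombined", "classifierPanel", "metric",
                          "linkage", "zscoreClassifier")],
    inputs = as.list(tools::md5sum(unlist(
      config[c("expression1", "labels1", "expression2", "catalogGMT")],
      use.names = FALSE))),
    outputs = as.list(tools::md5sum(out)),
    counts = list(rankingTables = length(tables),
                  signatures = 2L,
                  models = 1L,
                  assignmentTables = 1L + !is.null(config$expression2),
                  enrichmentTables = if (is.null(config$catalogGMT)) 0L
                    else 2L))
  jsonlite::write_json(manifest,
                       file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
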