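#' @include AllClasses.R io.R
NULL

#' Configuration for the synthetic four-cluster cohort generator
#'
#' The generator emulates a bulk expression cohort partitioned into four
#' molecular clusters (I-IV) in which a subset of immune-panel genes
#' ("responsive" genes) carries a monotone expression gradient from
#' cluster I (low) to cluster IV (high), on a background of uninformative
#' genes. All quantities are on the log2 scale.
#'
#' Defaults mirror the scale of the real training cohort the analysis is
#' designed for: cluster sizes (30, 30, 31, 31) for n = 122, a gradient of
#' (0, 1, 2, 3) log2 units, per-gene Gaussian noise with sd 0.5, half the
#' panel responsive, and 2000 background genes.
#'
#' @param clusterSizes 4 positive integers, samples per cluster I-IV.
#' @param nBackgroundGenes number of uninformative background genes.
#' @param responsiveFraction fraction of panel genes carrying the gradient.
#' @param gradient 4 mean shifts (log2 units), one per cluster; expected
#'   non-decreasing (a warning is emitted otherwise, since a non-monotone
#'   gradient no longer emulates the I-to-IV activation gradient).
#' @param noiseSd per-gene Gaussian noise sd (log2 units), > 0.
#' @param baselineMean,baselineSd log2-scale baseline expression
#'   distribution per gene.
#' @param seed integer RNG seed.
#' @return a validated configuration list.
#' @export
syntheticConfig <- function(clusterSizes = c(30L, 30L, 31L, 31L),
                            nBackgroundGenes = 2000L,
                            responsiveFraction = 0.5,
                            gradient = c(0, 1, 2, 3),
                            noiseSd = 0.5,
                            baselineMean = 6, baselineSd = 2,
                            seed = 1L) {
  stopifnot(length(clusterSizes) == 4L, all(clusterSizes >= 1L),
            length(gradient) == 4L, noiseSd > 0,
            responsiveFraction >= 0, responsiveFraction <= 1,
            nBackgroundGenes >= 0L, baselineSd >= 0)
  if (is.unsorted(gradient))
    warning("gradient is not non-decreasing; the cohort will not show a ",
            "monotone I-to-IV activation gradient")
  list(clusterSizes = as.integer(clusterSizes),
       nBackgroundGenes = as.integer(nBackgroundGenes),
       responsiveFraction = responsiveFraction,
       gradient = as.numeric(gradient), noiseSd = noiseSd,
       baselineMean = baselineMean, baselineSd = baselineSd,
       seed = as.integer(seed))
}

#' Generate a labeled synthetic cohort
#'
#' Responsive panel genes have cluster-conditional mean
#' `baseline + gradient[cluster]`; background genes and non-responsive
#' panel genes have mean `baseline` in every cluster. Noise is additive
#' Gaussian on the log2 scale, and the final matrix is floored at 0 so
#' that the optional raw-scale export `2^x - 1` is a valid non-negative
#' expression matrix that round-trips exactly through `log2(x + 1)`.
#'
#' Cluster blocks are generated in a canonical internal order (sorted by
#' gradient value, then size), so regenerating with a jointly permuted
#' `(clusterSizes, gradient)` yields the same cohort up to relabeling of
#' the clusters.
#'
#' Two quantities are deterministic functions of the gene list rather
#' than of the seed: the responsive subset (the first
#' `responsiveFraction` of the sorted panel) and the per-gene baseline
#' levels (a dedicated fixed RNG stream). Cohorts generated with
#' different seeds therefore represent new samples of the same genes —
#' the structure a discovery/validation cohort pair assumes — and the
#' seed governs sampling noise only.
#'
#' @param config a configuration from [syntheticConfig()].
#' @param panel a [GenePanel]; responsive genes are drawn from it.
#' @return an [ImmuneCohort] on the log2 scale with `colData$cluster`
#'   labels, `rowData$status` (`"responsive"`/`"background"`) and
#'   `rowData$panel` (logical) truth flags.
#' @examples
#' cfg <- syntheticConfig(clusterSizes = c(5, 5, 5, 5), seed = 7,
#'                        nBackgroundGenes = 50)
#' cohort <- generateCohort(cfg, GenePanel(LETTERS[1:20], "demo"))
#' table(clusterLabels(cohort))
#' @export
generateCohort <- function(config, panel) {
  stopifnot(is(panel, "GenePanel"))
  pg <- panelGenes(panel)
  nGenes <- length(pg) + config$nBackgroundGenes
  if (nGenes == 0L) stop("degenerate config: zero genes", call. = FALSE)
  bg <- if (config$nBackgroundGenes > 0L)
    sprintf("SYNBG%05d", seq_len(config$nBackgroundGenes)) else character()
  if (length(intersect(bg, pg)))
    stop("background gene names collide with panel symbols", call. = FALSE)
  genes <- c(pg, bg)

  # the responsive subset is a deterministic function of the panel (the
  # first responsiveFraction of the sorted panel), never of the seed:
  # independently generated cohorts from the same panel must carry the
  # gradient on the same genes, as a discovery/validation design assumes
  nResp <- ceiling(config$responsiveFraction * length(pg))
  responsive <- if (nResp > 0L) sort(pg)[seq_len(nResp)] else character()
  # per-gene baselines are drawn from a dedicated fixed RNG stream: a
  # gene's characteristic expression level is a property of the gene, so
  # cohorts generated with different seeds represent new samples of the
  # same genes (as a discovery/validation pair requires); the config
  # seed governs sampling noise only
  set.seed(20972L)
  baseline <- stats::rnorm(nGenes, config$baselineMean, config$baselineSd)
  set.seed(config$seed)

  # canonical block order: invariance under joint permutation of
  # (clusterSizes, gradient)
  ord <- order(config$gradient, config$clusterSizes)
  blocks <- vector("list", 4L)
  blockLabel <- character(4L)
  for (b in seq_len(4L)) {
    ci <- ord[b]
    s <- config$clusterSizes[ci]
    m <- matrix(stats::rnorm(nGenes * s, 0, config$noiseSd), nGenes, s) +
      baseline
    m[match(responsive, genes), ] <-
      m[match(responsive, genes), , drop = FALSE] + config$gradient[ci]
    blocks[[b]] <- m
    blockLabel[b] <- CLUSTER_LEVELS[ci]
  }
  X <- do.call(cbind, blocks)
  labels <- rep(blockLabel, vapply(blocks, ncol, integer(1)))
  # present samples in cluster order I..IV
  reorder <- order(match(labels, CLUSTER_LEVELS))
  X <- X[, reorder, drop = FALSE]
  labels <- labels[reorder]
  X <- pmax(X, 0)
  rownames(X) <- genes
  colnames(X) <- sprintf("S%04d", seq_len(ncol(X)))
  status <- ifelse(genes %in% responsive, "responsive", "background")
  out <- ImmuneCohort(X, scale = "log2", cluster = labels, status = status)
  rowData(out)$panel <- genes %in% pg
  metadata(out)$config <- config
  out
}

#' Generate a cohort with cluster-specific marker genes
#'
#' A companion generator to [generateCohort()] for the case where each
#' cluster carries its own private marker genes (elevated by
#' `markerEffect` log2 units in that cluster only) rather than a shared
#' monotone gradient. This is the structure under which one-vs-rest
#' ranking has a well-defined per-cluster truth, used to measure signature
#' recovery.
#'
#' @param clusterSizes 4 positive integers.
#' @param markersPerCluster number of private marker genes per cluster.
#' @param nNullGenes number of uninformative genes.
#' @param markerEffect log2 shift of a marker in its own cluster.
#' @param noiseSd,baselineMean,baselineSd as in [syntheticConfig()].
#' @param seed integer RNG seed.
#' @return an [ImmuneCohort] (log2 scale) with `rowData$markerCluster`
#'   (`NA` for null genes) and the marker sets in
#'   `metadata(x)$markers`.
#' @export
generateMarkerCohort <- function(clusterSizes = c(30L, 30L, 31L, 31L),
                                 markersPerCluster = 10L,
                                 nNullGenes = 160L,
                                 markerEffect = 2,
                                 noiseSd = 0.5,
                                 baselineMean = 6, baselineSd = 2,
                                 seed = 1L) {
  stopifnot(length(clusterSizes) == 4L, all(clusterSizes >= 1L),
            markersPerCluster >= 1L, noiseSd > 0)
  nMark <- 4L * markersPerCluster
  genes <- c(sprintf("MK%s%02d", rep(CLUSTER_LEVELS, each = markersPerCluster),
                     rep(seq_len(markersPerCluster), 4L)),
             sprintf("NULL%04d", seq_len(nNullGenes)))
  markers <- split(genes[seq_len(nMark)],
                   rep(CLUSTER_LEVELS, each = markersPerCluster))[CLUSTER_LEVELS]
  labels <- rep(CLUSTER_LEVELS, clusterSizes)
  n <- length(labels)
  set.seed(20972L)  # gene-level baselines: fixed stream, as in generateCohort
  baseline <- stats::rnorm(length(genes), baselineMean, baselineSd)
  set.seed(seed)
  X <- matrix(stats::rnorm(length(genes) * n, 0, noiseSd),
              length(genes), n) + baseline
  for (cl in CLUSTER_LEVELS)
    X[match(markers[[cl]], genes), labels == cl] <-
      X[match(markers[[cl]], genes), labels == cl, drop = FALSE] + markerEffect
  X <- pmax(X, 0)
  rownames(X) <- genes
  colnames(X) <- sprintf("S%04d", seq_len(n))
  mc <- rep(NA_character_, length(genes))
  mc[seq_len(nMark)] <- rep(CLUSTER_LEVELS, each = markersPerCluster)
  out <- ImmuneCohort(X, scale = "log2", cluster = labels)
  rowData(out)$markerCluster <- mc
  metadata(out)$markers <- markers
  out
}

#' Export a log2-scale cohort on the raw scale
#'
#' Applies `2^x - 1` entry-wise, the exact inverse of the
#' `log2(x + 1)` transform in [log2Transform()].
#'
#' @param x an [ImmuneCohort] on the log2 scale.
#' @return an [ImmuneCohort] on the raw scale.
#' @export
asRawScale <- function(x) {
  stopifnot(is(x, "ImmuneCohort"))
  if (!identical(expressionScale(x), "log2"))
    stop("raw-scale export requires a log2-scale cohort", call. = FALSE)
  out <- x
  SummarizedExperiment::assay(out, "exprs") <- 2^exprsMatrix(x) - 1
  metadata(out)$scale <- "raw"
  validObject(out)
  out
}

#' Generate a synthetic gene-set annotation catalog
#'
#' Builds a catalog in which one category is constructed to overlap a
#' supplied gene list far above chance (exactly `overlapSize` members)
#' while all other categories are drawn uniformly from the reference
#' universe (chance-level overlap). A stand-in for a real annotation
#' database when testing the over-representation statistic.
#'
#' @param categorySizes integer vector of category sizes (one category per
#'   element); names are used as category IDs when present.
#' @param referenceSize size N of the reference gene universe.
#' @param overlapWith gene list the enriched category must overlap.
#' @param enrichedCategory index (or name) of the category to enrich.
#' @param overlapSize number of `overlapWith` genes forced into the
#'   enriched category (0 forces an empty overlap).
#' @param seed integer RNG seed.
#' @return an [AnnotationCatalog] with an explicit reference universe.
#' @export
generateAnnotation <- function(categorySizes, referenceSize,
                               overlapWith, enrichedCategory = 1L,
                               overlapSize, seed = 1L) {
  stopifnot(length(categorySizes) >= 1L, all(categorySizes >= 1L),
            referenceSize >= max(categorySizes))
  overlapWith <- normalizeSymbols(overlapWith)
  if (is.character(enrichedCategory))
    enrichedCategory <- match(enrichedCategory, names(categorySizes))
  if (overlapSize > categorySizes[enrichedCategory])
    stop("requested overlap (", overlapSize,
         ") larger than category size (",
         categorySizes[enrichedCategory], ")", call. = FALSE)
  if (overlapSize > length(overlapWith))
    stop("requested overlap larger than the supplied gene list",
         call. = FALSE)
  if (length(overlapWith) > referenceSize)
    stop("gene list larger than the reference universe", call. = FALSE)
  set.seed(seed)
  filler <- sprintf("SYNREF%05d", seq_len(referenceSize - length(overlapWith)))
  reference <- c(overlapWith, filler)
  nms <- names(categorySizes)
  if (is.null(nms)) nms <- sprintf("CAT%03d", seq_along(categorySizes))
  cats <- vector("list", length(categorySizes))
  for (i in seq_along(categorySizes)) {
    if (i == enrichedCategory) {
      forced <- if (overlapSize > 0L) sample(overlapWith, overlapSize)
        else character()
      rest <- sample(setdiff(reference, overlapWith),
                     categorySizes[i] - overlapSize)
      cats[[i]] <- c(forced, rest)
    } else {
      cats[[i]] <- sample(reference, categorySizes[i])
    }
  }
  names(cats) <- nms
  new("AnnotationCatalog", referenceSize = as.integer(referenceSize),
      categories = cats, referenceGenes = reference)
}
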