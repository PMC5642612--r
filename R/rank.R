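#' @include AllClasses.R preprocess.R
NULL

# The five one-vs-rest discriminators. All operate on the log2 scale and
# are shift-tolerant (adding a constant to one gene across all samples
# changes no score). A gene constant across all samples scores 0 (worst)
# in every ranker; a gene with zero within-group variance but distinct
# group means is a perfect separator (score Inf for the ratio statistics).
ensembleScores <- function(X, y) {
  n1 <- sum(y); n0 <- sum(!y); n <- n1 + n0
  m1 <- rowMeans(X[, y, drop = FALSE])
  m0 <- rowMeans(X[, !y, drop = FALSE])
  v1 <- rowSums((X[, y, drop = FALSE] - m1)^2) / (n1 - 1L)
  v0 <- rowSums((X[, !y, drop = FALSE] - m0)^2) / (n0 - 1L)
  dm <- abs(m1 - m0)

  # (1) absolute Welch two-sample t
  se <- sqrt(v1 / n1 + v0 / n0)
  tstat <- ifelse(se == 0, ifelse(dm > 0, Inf, 0), dm / se)
  # (2) rank-sum discriminator |AUC - 0.5| (midranks for ties)
  R <- t(apply(X, 1L, rank))
  auc <- (rowSums(R[, y, drop = FALSE]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  aucs <- abs(auc - 0.5)
  # (3) signal-to-noise ratio
  sdsum <- sqrt(v1) + sqrt(v0)
  snr <- ifelse(sdsum == 0, ifelse(dm > 0, Inf, 0), dm / sdsum)
  # (4) absolute difference of group means (log2 fold change of means)
  # (5) mutual information with expression binarized at the pooled median
  med <- apply(X, 1L, stats::median)
  B <- X > med
  a <- rowSums(B[, y, drop = FALSE])          # high, target
  b <- rowSums(B) - a                         # high, rest
  cc <- n1 - a                                # low, target
  d <- n0 - b                                 # low, rest
  mi <- miFromCounts(a, b, cc, d, n)

  data.frame(score_t = tstat, score_auc = aucs, score_snr = snr,
             score_meandiff = dm, score_mi = mi)
}

miFromCounts <- function(a, b, cc, d, n) {
  term <- function(nij, ni., n.j) {
    p <- nij / n
    out <- numeric(length(p))
    pos <- p > 0
    out[pos] <- p[pos] * log(p[pos] * n * n /
                               (ni.[pos] * n.j[pos]))
    out
  }
  hi <- a + b; lo <- cc + d; tg <- a + cc; rs <- b + d
  term(a, hi, tg) + term(b, hi, rs) + term(cc, lo, tg) + term(d, lo, rs)
}

#' One-vs-rest gene ranking by a five-ranker ensemble
#'
#' Ranks every gene of a labeled log2-scale cohort on its ability to
#' discriminate the samples of one cluster from all remaining samples.
#' The ensemble combines five discriminators: the absolute Welch
#' two-sample t statistic; the rank-sum statistic expressed as
#' `|AUC - 0.5|`; the signal-to-noise ratio `|mu1 - mu0| / (sd1 + sd0)`;
#' the absolute difference of group means; and the mutual information
#' between the one-vs-rest label and expression binarized at the pooled
#' median. Each ranker orders the genes (rank 1 = most discriminative,
#' midranks for ties); the aggregate rank is the mean of the five
#' per-ranker ranks, with residual ties broken lexicographically by gene
#' symbol so the final aggregate ranks are 1..m with no gaps.
#'
#' @param x an [ImmuneCohort] on the log2 scale with cluster labels (or
#'   labels supplied via `labels`).
#' @param target the cluster to discriminate from the rest.
#' @param labels optional named label vector overriding
#'   `clusterLabels(x)`.
#' @param panelName name recorded on the resulting table.
#' @return a [RankingTable].
#' @export
rankOneVsRest <- function(x, target, labels = clusterLabels(x),
                          panelName = "panel") {
  stopifnot(is(x, "ImmuneCohort"))
  if (!identical(expressionScale(x), "log2"))
    stop("ranking operates on the log2 scale", call. = FALSE)
  if (is.null(labels)) stop("no cluster labels available", call. = FALSE)
  labels <- labels[colnames(x)]
  if (anyNA(labels)) stop("labels missing for some samples", call. = FALSE)
  if (!target %in% labels)
    stop("target cluster '", target, "' not present in labels",
         call. = FALSE)
  y <- labels == target
  if (sum(y) < 2L || sum(!y) < 2L)
    stop("need at least 2 samples in the target cluster and in the rest",
         call. = FALSE)
  X <- exprsMatrix(x)
  sc <- ensembleScores(X, y)
  ranks <- as.data.frame(lapply(sc, function(s) rank(-s, ties.method = "average")))
  colnames(ranks) <- sub("^score_", "rank_", colnames(sc))
  meanRank <- rowMeans(ranks)
  ord <- order(meanRank, rownames(X))
  tb <- data.frame(gene = rownames(X), sc, ranks, meanRank = meanRank,
                   stringsAsFactors = FALSE, row.names = NULL)
  tb <- tb[ord, , drop = FALSE]
  tb$aggRank <- seq_len(nrow(tb))
  rownames(tb) <- NULL
  new("RankingTable", panel = panelName, targetCluster = as.character(target),
      table = tb)
}

#' Build the full grid of one-vs-rest ranking tables
#'
#' For each panel in the registry and each cluster present in the labels,
#' restricts the cohort to the panel genes and ranks them one-vs-rest:
#' four panels and four clusters yield 16 tables. With
#' `combined = TRUE` (the default) the combined (union) panel adds four
#' more tables, named `"combined"`.
#'
#' @param x a labeled [ImmuneCohort] on the log2 scale.
#' @param registry a [PanelRegistry].
#' @param clusters clusters to rank against the rest; defaults to the
#'   sorted unique labels.
#' @param combined also rank over the combined union panel.
#' @return named list of [RankingTable] objects
#'   (`"<panel>:<cluster>"`).
#' @export
buildRankingTables <- function(x, registry, clusters = NULL,
                               combined = TRUE) {
  stopifnot(is(registry, "PanelRegistry"))
  labels <- clusterLabels(x)
  if (is.null(labels)) stop("cohort has no cluster labels", call. = FALSE)
  if (is.null(clusters))
    clusters <- intersect(CLUSTER_LEVELS, unique(labels))
  panels <- registry@panels
  if (combined) panels <- c(panels, list(combined = combinedPanel(registry)))
  out <- list()
  for (pn in names(panels)) {
    sub <- suppressWarnings(subsetToPanel(x, panels[[pn]]))
    for (cl in clusters)
      out[[paste0(pn, ":", cl)]] <- rankOneVsRest(sub, cl, panelName = pn)
  }
  out
}

#' Merge the top fraction of several ranking tables into a signature
#'
#' Takes the `ceiling(q * m)` best-ranked genes of each table and returns
#' their sorted set union. This is the construction used both per panel
#' (q = 0.20, the "top 20%" per-panel signatures) and over the combined
#' panel (q = 0.05, the merged unique signature).
#'
#' @param tables list of [RankingTable] objects.
#' @param q top fraction in (0, 1]; `q * m < 1` for any table is an
#'   error.
#' @return a [SignatureSet].
#' @export
topFractionUnion <- function(tables, q) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, is, logical(1), "RankingTable")))
  if (q <= 0 || q > 1) stop("q must be in (0, 1]", call. = FALSE)
  picked <- lapply(tables, function(tt) {
    m <- nrow(tt@table)
    if (q * m < 1)
      stop("q = ", q, " selects no genes from a table of ", m, " genes",
           call. = FALSE)
    tt@table$gene[seq_len(ceiling(q * m))]
  })
  src <- vapply(tables, function(tt)
    paste0(tt@panel, ":", tt@targetCluster), character(1))
  new("SignatureSet", genes = sort(unique(unlist(picked))), fraction = q,
      sourceTables = unname(src))
}

#' Write a ranking table or signature to disk
#'
#' Ranking tables are written as TSV with the per-ranker scores and ranks;
#' signatures as plain-text gene lists (one symbol per line).
#'
#' @param x a [RankingTable] or [SignatureSet].
#' @param path output file path.
#' @export
writeRankingTSV <- function(x, path) {
  stopifnot(is(x, "RankingTable"))
  utils::write.table(x@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeRankingTSV
#' @export
writeSignature <- function(x, path) {
  stopifnot(is(x, "SignatureSet"))
  writeLines(x@genes, path)
  invisible(path)
}
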