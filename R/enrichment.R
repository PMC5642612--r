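#' @include AllClasses.R
NULL

#' Expected category count under random sampling from the reference
#'
#' `E = n * K / N`: the number of analysed-list genes expected to fall in
#' a category containing `K` of the `N` reference genes, for an analysed
#' list of `n` genes. Kept unrounded internally; reports use 2 decimals.
#'
#' @param n analysed-list size (genes mapped to the reference).
#' @param K category reference count.
#' @param N reference-list size (> 0).
#' @return the expected count.
#' @examples
#' round(expectedCount(385, 17, 20972), 2)  # 0.31
#' @export
expectedCount <- function(n, K, N) {
  if (N <= 0) stop("reference size N must be positive", call. = FALSE)
  stopifnot(n >= 0, K >= 0, K <= N)
  n * K / N
}

#' Fold enrichment and direction
#'
#' `FE = k / E` using the unrounded expected count; direction is `"+"`
#' when `k >= E` (over-representation) and `"-"` otherwise. `E == 0`
#' with `k > 0` is flagged as infinite enrichment (`FE = Inf`) rather
#' than reported as a number.
#'
#' @param k observed category count in the analysed list.
#' @param E expected count from [expectedCount()].
#' @return list with elements `FE` and `direction`.
#' @export
foldEnrichment <- function(k, E) {
  stopifnot(E >= 0, k >= 0)
  if (E == 0)
    return(list(FE = if (k > 0) Inf else NaN,
                direction = if (k > 0) "+" else "-"))
  list(FE = k / E, direction = if (k >= E) "+" else "-")
}

#' One-sided binomial tail probability
#'
#' The over/under-representation p-value: with `X ~ Binomial(n, p)` and
#' `p = K / N`, direction `"+"` gives `P(X >= k)` and `"-"` gives
#' `P(X <= k)`. Evaluated through `stats::pbinom`, which works on the
#' log scale internally and is numerically safe for the extreme tails
#' that enrichment analyses produce.
#'
#' @param k observed count, `0 <= k <= n`.
#' @param n number of trials (analysed-list size).
#' @param p success probability `K / N`, in (0, 1).
#' @param direction `"+"` or `"-"`.
#' @return the one-sided tail probability.
#' @export
binomialTailP <- function(k, n, p, direction = c("+", "-")) {
  direction <- match.arg(direction)
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("p must lie strictly between 0 and 1", call. = FALSE)
  stopifnot(k >= 0, k <= n)
  if (direction == "+")
    stats::pbinom(k - 1, n, p, lower.tail = FALSE)
  else
    stats::pbinom(k, n, p)
}

#' Bonferroni correction
#'
#' @param p raw p-value(s).
#' @param B Bonferroni count (number of tests), >= 1.
#' @return `min(1, p * B)`.
#' @export
bonferroni <- function(p, B) {
  if (B < 1) stop("Bonferroni count must be >= 1", call. = FALSE)
  pmin(1, p * B)
}

# one fully-computed row of the over/under-representation analysis
enrichmentRow <- function(category, K, k, n, N, B) {
  E <- expectedCount(n, K, N)
  fe <- foldEnrichment(k, E)
  p <- binomialTailP(k, n, K / N, fe$direction)
  data.frame(category = category, K = K, k = k, n = n, E = E,
             direction = fe$direction, FE = fe$FE, p_raw = p, B = B,
             p_corr = bonferroni(p, B), stringsAsFactors = FALSE)
}

#' Over/under-representation analysis from explicit counts
#'
#' Computes the full analysis table directly from per-category reference
#' counts `K` and observed counts `k`, for a given analysed-list size
#' `n` and reference size `N` — the form in which published annotation
#' tables print their inputs.
#'
#' @param categories category names.
#' @param K per-category reference counts.
#' @param k per-category observed counts.
#' @param n analysed-list size (number of list genes mapped to the
#'   reference; annotation databases may map one symbol to several
#'   reference entries, so `n` is taken as an input).
#' @param N reference-list size.
#' @param B Bonferroni count; defaults to the number of categories.
#' @return an [EnrichmentResult] with rows sorted by fold enrichment
#'   (descending) within the `"+"` direction, then `"-"` rows.
#' @examples
#' enrichmentFromCounts("JAK/STAT signaling pathway", K = 17, k = 6,
#'                      n = 385, N = 20972, B = 158)
#' @export
enrichmentFromCounts <- function(categories, K, k, n, N, B = NULL) {
  stopifnot(length(categories) == length(K), length(K) == length(k))
  if (is.null(B)) B <- length(categories)
  rows <- do.call(rbind, Map(enrichmentRow, categories, K, k,
                             MoreArgs = list(n = n, N = N, B = B)))
  rows <- rows[order(rows$direction == "-", -rows$FE), , drop = FALSE]
  rownames(rows) <- NULL
  new("EnrichmentResult", table = rows, n = as.integer(n),
      N = as.integer(N), B = as.integer(B))
}

#' Over/under-representation analysis of a gene list against a catalog
#'
#' Scores a gene list against every category of an annotation catalog
#' using the one-sided binomial model: for each category the observed
#' count `k` is the size of the intersection of the list with the
#' category, the expected count is `n * K / N`, and the p-value is the
#' binomial tail in the direction of the deviation, Bonferroni-corrected.
#'
#' When the catalog carries an explicit reference universe, list genes
#' absent from it are dropped (reported via a message) and `n` is the
#' number of mapped genes; otherwise `n` is the list size (or the `n`
#' argument, for catalogs whose symbol-to-entry mapping multiplicity is
#' known externally).
#'
#' @param geneList character vector of gene symbols.
#' @param catalog an [AnnotationCatalog].
#' @param B Bonferroni count; defaults to the number of categories
#'   tested.
#' @param n optional override of the analysed-list size.
#' @return an [EnrichmentResult].
#' @export
runOverrepresentation <- function(geneList, catalog, B = NULL, n = NULL) {
  stopifnot(is(catalog, "AnnotationCatalog"))
  if (length(geneList) == 0L) stop("empty gene list", call. = FALSE)
  geneList <- unique(normalizeSymbols(geneList))
  if (length(catalog@referenceGenes)) {
    mapped <- geneList[geneList %in% catalog@referenceGenes]
    dropped <- length(geneList) - length(mapped)
    if (length(mapped) == 0L)
      stop("no gene of the list maps to the reference", call. = FALSE)
    if (dropped > 0L)
      message(dropped, " gene(s) not in the reference list (dropped)")
  } else {
    mapped <- geneList
  }
  if (is.null(n)) n <- length(mapped)
  N <- catalog@referenceSize
  if (is.null(B)) B <- length(catalog@categories)
  k <- vapply(catalog@categories, function(set)
    sum(mapped %in% set), integer(1))
  K <- lengths(catalog@categories)
  enrichmentFromCounts(names(catalog@categories), K, k, n = n, N = N,
                       B = B)
}

#' Format an enrichment table at reporting precision
#'
#' Expected counts and fold enrichments to 2 decimals, p-values to 3
#' significant figures in scientific notation — the convention of
#' published annotation tables. Full precision stays in
#' [enrichmentFrame()].
#'
#' @param x an [EnrichmentResult].
#' @return a data.frame of formatted character/numeric columns.
#' @export
formatEnrichment <- function(x) {
  stopifnot(is(x, "EnrichmentResult"))
  tb <- enrichmentFrame(x)
  data.frame(category = tb$category, K = tb$K, k = tb$k,
             expected = sprintf("%.2f", tb$E),
             direction = tb$direction,
             foldEnrichment = ifelse(is.finite(tb$FE),
                                     sprintf("%.2f", tb$FE), "Inf"),
             p = toupper(sprintf("%.2e", signif(tb$p_corr, 3))),
             stringsAsFactors = FALSE)
}

#' Write an enrichment table as TSV
#'
#' @param x an [EnrichmentResult].
#' @param path output path.
#' @export
writeEnrichmentTSV <- function(x, path) {
  utils::write.table(enrichmentFrame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
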