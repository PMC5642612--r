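#' @include AllClasses.R
NULL

normalizeSymbols <- function(x) toupper(trimws(x))

#' Construct a gene panel
#'
#' Symbols are trimmed and upper-cased; duplicates after case-normalisation
#' are collapsed (first occurrence kept) and the number collapsed is
#' reported via a message. Empty or whitespace-only symbols are an error.
#'
#' @param genes character vector of gene symbols.
#' @param name short panel identifier.
#' @param source free-text provenance tag.
#' @return a [GenePanel].
#' @examples
#' GenePanel(c("A2M", "C1R", "CCND3"), name = "demo")
#' @export
GenePanel <- function(genes, name, source = "") {
  if (length(genes) == 0L)
    stop("panel '", name, "' contains no genes", call. = FALSE)
  if (any(is.na(genes)) || any(!nzchar(trimws(genes))))
    stop("panel '", name, "' contains empty or missing symbols",
         call. = FALSE)
  g <- normalizeSymbols(genes)
  ndup <- sum(duplicated(g))
  if (ndup > 0L)
    message("panel '", name, "': collapsed ", ndup, " duplicate symbol",
            if (ndup > 1L) "s", " after case-normalisation")
  new("GenePanel", name = name, genes = unique(g), source = source)
}

#' Load a gene panel from a plain-text or two-column CSV file
#'
#' Accepts either one gene symbol per line, or a two-column CSV whose first
#' column holds symbols (a second column, e.g. a panel tag, is ignored).
#' Lines with more than two comma-separated fields are rejected with the
#' offending line number.
#'
#' @param path file path.
#' @param name panel identifier.
#' @param source provenance tag; defaults to the file name.
#' @return a [GenePanel].
#' @export
loadPanel <- function(path, name, source = basename(path)) {
  if (!file.exists(path))
    stop("panel file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("panel file is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(lengths(fields) > 2L)
  if (length(bad))
    stop("unparseable line ", bad[1L], " in ", path,
         " (expected 1 or 2 comma-separated fields)", call. = FALSE)
  GenePanel(vapply(fields, `[[`, character(1), 1L), name = name,
            source = source)
}

#' Union of gene panels
#'
#' Returns the set union of one or more panels with a stable (sorted)
#' gene order. Provenance of each gene (which source panels contained it)
#' is available from the [PanelRegistry] built by [panelRegistry()].
#'
#' @param panels list of [GenePanel] objects (at least one).
#' @param name name for the combined panel.
#' @return a [GenePanel] holding the sorted union.
#' @export
unionPanels <- function(panels, name = "combined") {
  if (length(panels) < 1L)
    stop("at least one panel required", call. = FALSE)
  stopifnot(all(vapply(panels, is, logical(1), "GenePanel")))
  genes <- sort(unique(unlist(lapply(panels, panelGenes))))
  new("GenePanel", name = name, genes = genes,
      source = paste("union of:",
                     paste(vapply(panels, panelName, character(1)),
                           collapse = ", ")))
}

#' Build a panel registry
#'
#' @param panels list of [GenePanel] objects; names default to the panels'
#'   own names.
#' @return a [PanelRegistry] with the combined (union) panel and a
#'   per-gene membership table.
#' @export
panelRegistry <- function(panels) {
  if (is.null(names(panels)))
    names(panels) <- vapply(panels, panelName, character(1))
  combined <- unionPanels(panels)
  member <- vapply(panelGenes(combined), function(g)
    paste(names(panels)[vapply(panels, function(p) g %in% p@genes,
                               logical(1))], collapse = ","),
    character(1))
  new("PanelRegistry", panels = panels, combined = combined,
      membership = data.frame(gene = panelGenes(combined),
                              panels = unname(member),
                              stringsAsFactors = FALSE))
}

#' Query panel membership
#'
#' @param registry a [PanelRegistry].
#' @param symbols gene symbols (case-insensitive).
#' @return logical vector: TRUE iff the symbol appears in at least one
#'   source panel.
#' @export
inRegistry <- function(registry, symbols) {
  stopifnot(is(registry, "PanelRegistry"))
  normalizeSymbols(symbols) %in% panelGenes(combinedPanel(registry))
}

#' The packaged immune panel registry
#'
#' Loads the four packaged immune gene panels and combines them:
#'
#' * `nanostring` — the 722-gene pan-cancer immune profiling panel
#'   (packaged verbatim as a plain-text fixture);
#' * `ifn_alpha` (97 genes), `ifn_gamma` (200 genes) and `cytotoxic`
#'   (115 genes) — synthetic stand-in panels of the stated sizes. These
#'   three are constructed lists (their filenames carry the
#'   `_synthetic` tag): each mixes real symbols drawn from the 722-gene
#'   panel with clearly synthetic `SYN*` placeholders, arranged so the
#'   combined unique set contains exactly 924 genes. Users with the real
#'   pathway lists can substitute them via [loadPanel()] and
#'   [panelRegistry()].
#'
#' @return a [PanelRegistry] whose combined panel has 924 genes.
#' @examples
#' reg <- immunePanelRegistry()
#' length(combinedPanel(reg))
#' @export
immunePanelRegistry <- function() {
  ext <- function(f) system.file("extdata", f, package = "immunosig",
                                 mustWork = TRUE)
  panels <- list(
    nanostring = loadPanel(ext("panel_nanostring.txt"), "nanostring",
                           source = "nCounter PanCancer immune profiling panel (722 genes)"),
    ifn_alpha = loadPanel(ext("panel_ifn_alpha_synthetic.txt"), "ifn_alpha",
                          source = "synthetic stand-in, IFN-alpha pathway (97 genes)"),
    ifn_gamma = loadPanel(ext("panel_ifn_gamma_synthetic.txt"), "ifn_gamma",
                          source = "synthetic stand-in, IFN-gamma pathway (200 genes)"),
    cytotoxic = loadPanel(ext("panel_cytotoxic_synthetic.txt"), "cytotoxic",
                          source = "synthetic stand-in, T-cell cytotoxicity (115 genes)"))
  panelRegistry(panels)
}
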