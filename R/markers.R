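#' Marker gene panels for CTC phenotyping
#'
#' The five fixed marker panels used throughout the pipeline: twelve
#' epithelial markers, the leukocyte marker \emph{PTPRC} (CD45), the
#' endothelial marker \emph{PECAM1} (CD31), eleven stem-cell-related markers
#' and seven EMT-related markers. Gene identifiers are HGNC symbols and are
#' matched case-insensitively against expression matrices.
#'
#' @return A named list of character vectors with elements
#'   `epithelial`, `leukocyte`, `endothelial`, `stem` and `emt`.
#' @examples
#' marker_panels()$emt
#' @export
marker_panels <- function() {
  list(
    epithelial = c("CDH1", "EPCAM", "CLDN1", "CLDN2", "CLDN3", "CLDN4",
                   "CLDN7", "KRT8", "KRT18", "KRT19", "KRT20", "VIL1"),
    leukocyte = "PTPRC",
    endothelial = "PECAM1",
    stem = c("LGR5", "ALDH2", "CD44", "PROM1", "ABCB2", "SALL4", "KLF4",
             "MYC", "NANOG", "SOX2", "POU5F1"),
    emt = c("VIM", "SPARC", "ITGB1", "TFAP4", "ZEB2", "SNAI1", "CDH2")
  )
}

#' All 32 panel genes in panel order
#' @return Character vector of the distinct genes across all five panels.
#' @keywords internal
panel_genes <- function() {
  unique(unlist(marker_panels(), use.names = FALSE))
}

# Case-insensitive lookup of panel genes among matrix rownames.
# Returns an integer vector, NA where the gene is absent; warns once per call
# about missing genes (they score as zero downstream).
match_genes <- function(genes, gene_ids, warn = TRUE) {
  idx <- match(toupper(genes), toupper(gene_ids))
  if (warn && anyNA(idx)) {
    warning(sprintf("panel genes absent from matrix (treated as zero): %s",
                    paste(genes[is.na(idx)], collapse = ", ")),
            call. = FALSE)
  }
  idx
}

# Submatrix of panel genes (genes x cells), absent genes filled with zeros.
panel_submatrix <- function(expr, genes, warn = TRUE) {
  idx <- match_genes(genes, rownames(expr$values), warn = warn)
  out <- matrix(0, nrow = length(genes), ncol = ncol(expr$values),
                dimnames = list(genes, colnames(expr$values)))
  hit <- !is.na(idx)
  out[hit, ] <- expr$values[idx[hit], , drop = FALSE]
  out
}
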