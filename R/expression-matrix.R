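#' Construct a CTC expression matrix
#'
#' The core data container of the pipeline: a non-negative gene x cell TPM
#' matrix together with per-cell metadata. Genes are rows (HGNC symbols),
#' cells are columns.
#'
#' @param values Numeric matrix, genes as rows and cells as columns, with
#'   unique `rownames` (gene symbols) and unique `colnames` (cell IDs).
#'   All entries must be finite and >= 0.
#' @param cell_meta Data frame with one row per cell and columns
#'   `cell_id`, `patient_id`, `unique_reads` (non-negative integer count of
#'   uniquely mapped reads) and `is_cluster` (logical; `TRUE` for CTC-cluster
#'   objects, i.e. two or more physically conjoined cells captured as one).
#'   Rows are matched to matrix columns by `cell_id`.
#' @return An object of class `ctc_expr`: a list with elements `values`
#'   and `cell_meta` (reordered to match the matrix columns).
#' @seealso [read_expression_matrix()], [generate_cells()]
#' @export
expression_matrix <- function(values, cell_meta) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  gene_ids <- rownames(values)
  cell_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("`values` must carry gene rownames and cell colnames", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifiers: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing", call. = FALSE)
  if (any(values < 0))
    stop("expression values must be non-negative (TPM)", call. = FALSE)

  cell_meta <- as.data.frame(cell_meta)
  req <- c("cell_id", "patient_id", "unique_reads", "is_cluster")
  missing_cols <- setdiff(req, names(cell_meta))
  if (length(missing_cols))
    stop("cell_meta lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  m <- match(cell_ids, cell_meta$cell_id)
  if (anyNA(m))
    stop("cell_meta missing metadata for cell(s): ",
         paste(cell_ids[is.na(m)], collapse = ", "), call. = FALSE)
  cell_meta <- cell_meta[m, , drop = FALSE]
  rownames(cell_meta) <- NULL
  if (anyNA(cell_meta$patient_id))
    stop("every cell must have a patient_id", call. = FALSE)
  cell_meta$is_cluster <- as.logical(cell_meta$is_cluster)

  structure(list(values = values, cell_meta = cell_meta), class = "ctc_expr")
}

#' @export
print.ctc_expr <- function(x, ...) {
  cat(sprintf("ctc_expr: %d genes x %d cells, %d patient(s), %d cluster object(s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$cell_meta$patient_id)),
              sum(x$cell_meta$is_cluster)))
  invisible(x)
}

#' @export
dim.ctc_expr <- function(x) dim(x$values)

#' Subset an expression matrix to a set of cells
#' @param expr A `ctc_expr` object.
#' @param cell_ids Character vector of cell IDs to keep (order preserved).
#' @return A `ctc_expr` restricted to those cells.
#' @export
subset_cells <- function(expr, cell_ids) {
  stopifnot(inherits(expr, "ctc_expr"))
  missing <- setdiff(cell_ids, colnames(expr$values))
  if (length(missing))
    stop("unknown cell id(s): ", paste(missing, collapse = ", "), call. = FALSE)
  expression_matrix(expr$values[, cell_ids, drop = FALSE],
                    expr$cell_meta[match(cell_ids, expr$cell_meta$cell_id), ,
                                   drop = FALSE])
}
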