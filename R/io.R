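#' Read an expression matrix and its cell metadata from disk
#'
#' The expression file is a delimited table whose first column (named
#' `gene`) holds gene symbols and whose remaining columns hold one cell
#' each, header row giving cell IDs. The metadata file is a CSV with
#' columns `cell_id`, `patient_id`, `unique_reads`, `is_cluster`.
#'
#' @param path Path to the expression table (TSV or CSV).
#' @param meta_path Path to the cell metadata CSV.
#' @param sep Field separator for the expression table; `NULL` (default)
#'   infers it from the file extension (`.csv` -> comma, otherwise tab).
#' @return A [expression_matrix()] object.
#' @export
read_expression_matrix <- function(path, meta_path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(tab) < 2)
    stop("expression table needs a gene column plus at least one cell column",
         call. = FALSE)
  genes <- tab[[1]]
  body <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(storage))
    stop("non-numeric or missing expression value(s) in ", path, call. = FALSE)
  dimnames(storage) <- list(genes, colnames(tab)[-1])
  meta <- read_cell_metadata(meta_path)
  expression_matrix(storage, meta)
}

#' Read per-cell metadata
#' @param path CSV with columns `cell_id`, `patient_id`, `unique_reads`,
#'   `is_cluster`.
#' @return Data frame of cell metadata.
#' @export
read_cell_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cell_id", "patient_id", "unique_reads", "is_cluster")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols))
    stop("metadata lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  meta$unique_reads <- as.integer(meta$unique_reads)
  meta$is_cluster <- as.logical(meta$is_cluster)
  meta
}

#' Write an expression matrix and its metadata to disk
#'
#' @param expr A `ctc_expr` object.
#' @param path Output path for the expression table.
#' @param meta_path Output path for the metadata CSV.
#' @param sep Field separator for the expression table (default tab).
#' @return Invisibly, `expr`.
#' @export
write_expression_matrix <- function(expr, path, meta_path, sep = "\t") {
  stopifnot(inherits(expr, "ctc_expr"))
  tab <- data.frame(gene = rownames(expr$values), expr$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  # format() would lose precision; write full double representation
  utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  utils::write.csv(expr$cell_meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(expr)
}

#' Read a per-patient clinical table
#'
#' Required columns: `patient_id`, `treatment_line` (positive integer,
#' 1 = first line), `pfs_days`, `pfs_event`, `os_days`, `os_event`.
#' Progression-free survival (PFS) runs from treatment start to confirmed
#' progression or death; overall survival (OS) from treatment start to
#' death; the event flags are `FALSE` for patients censored at last
#' follow-up. Survival times may be missing (`NA`) but never non-positive.
#' Unknown columns are preserved.
#'
#' @param path CSV path.
#' @return Data frame with one row per patient.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  clin <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical(clin)
}

#' Validate a clinical table already held in memory
#' @param clin Data frame of patient records.
#' @return The validated (type-coerced) data frame.
#' @export
validate_clinical <- function(clin) {
  req <- c("patient_id", "treatment_line", "pfs_days", "pfs_event",
           "os_days", "os_event")
  missing_cols <- setdiff(req, names(clin))
  if (length(missing_cols))
    stop("clinical table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(clin$patient_id))
    stop("duplicate patient_id in clinical table", call. = FALSE)
  clin$treatment_line <- as.integer(clin$treatment_line)
  if (any(is.na(clin$treatment_line)) || any(clin$treatment_line < 1))
    stop("treatment_line must be a positive integer", call. = FALSE)
  for (col in c("pfs_days", "os_days")) {
    clin[[col]] <- as.numeric(clin[[col]])
    if (any(clin[[col]] <= 0, na.rm = TRUE))
      stop(col, " must be strictly positive when present", call. = FALSE)
  }
  for (col in c("pfs_event", "os_event")) clin[[col]] <- as.logical(clin[[col]])
  if (any(!is.na(clin$pfs_event) & is.na(clin$pfs_days)))
    stop("pfs_event defined without pfs_days", call. = FALSE)
  if (any(!is.na(clin$os_event) & is.na(clin$os_days)))
    stop("os_event defined without os_days", call. = FALSE)
  clin
}

#' Write a clinical table
#' @param clin Data frame of patient records.
#' @param path CSV output path.
#' @return Invisibly, `clin`.
#' @export
write_clinical_table <- function(clin, path) {
  utils::write.csv(clin, path, row.names = FALSE, quote = FALSE)
  invisible(clin)
}
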