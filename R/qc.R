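#' Read-count quality control
#'
#' Flags each cell by its uniquely mapped read count. A cell passes when
#' `unique_reads` is strictly greater than `min_reads`; nothing is dropped
#' at this stage.
#'
#' @param expr A [expression_matrix()] object.
#' @param min_reads Read-count floor (strict inequality), default 100000.
#' @return Data frame `cell_id`, `unique_reads`, `reads_pass`.
#' @export
filter_by_reads <- function(expr, min_reads = 100000L) {
  stopifnot(inherits(expr, "ctc_expr"))
  meta <- expr$cell_meta
  if (anyNA(meta$unique_reads))
    stop("unique_reads missing for cell(s): ",
         paste(meta$cell_id[is.na(meta$unique_reads)], collapse = ", "),
         call. = FALSE)
  data.frame(cell_id = meta$cell_id,
             unique_reads = meta$unique_reads,
             reads_pass = meta$unique_reads > min_reads,
             stringsAsFactors = FALSE)
}

#' Classify contaminant cells by lineage marker expression
#'
#' Applies the marker elimination rules: a non-cluster cell expressing the
#' leukocyte marker PTPRC at or above `positivity_tpm` is a leukocyte; a
#' cluster object expressing PTPRC is a CTC cluster with mixed leukocytes;
#' a cell expressing the endothelial marker PECAM1 (with PTPRC below
#' threshold) is endothelial. When both markers are positive in a
#' non-cluster cell the leukocyte call takes precedence. Everything else is
#' class `"none"`.
#'
#' @param expr A [expression_matrix()] object.
#' @param positivity_tpm TPM at or above which a marker is positive
#'   (default 1).
#' @return Data frame `cell_id`, `is_cluster`, `contaminant_class` with
#'   classes in `{none, leukocyte, endothelial, mixed_cluster}`.
#' @export
classify_contaminants <- function(expr, positivity_tpm = 1.0) {
  stopifnot(inherits(expr, "ctc_expr"))
  ptprc <- as.numeric(panel_submatrix(expr, "PTPRC", warn = TRUE))
  pecam <- as.numeric(panel_submatrix(expr, "PECAM1", warn = TRUE))
  clus <- expr$cell_meta$is_cluster
  cls <- rep("none", ncol(expr$values))
  cls[pecam >= positivity_tpm & ptprc < positivity_tpm] <- "endothelial"
  cls[ptprc >= positivity_tpm & !clus] <- "leukocyte"
  cls[ptprc >= positivity_tpm & clus] <- "mixed_cluster"
  data.frame(cell_id = expr$cell_meta$cell_id,
             is_cluster = clus,
             contaminant_class = cls,
             stringsAsFactors = FALSE)
}

#' Full quality-control pass
#'
#' Combines read-count QC and contaminant classification. A cell is
#' retained iff it passes the read floor and has contaminant class
#' `"none"`.
#'
#' @param expr A [expression_matrix()] object.
#' @param config Pipeline configuration ([default_config()]).
#' @return Data frame `cell_id`, `unique_reads`, `reads_pass`,
#'   `contaminant_class`, `retained`.
#' @export
qc_filter <- function(expr, config = default_config()) {
  reads <- filter_by_reads(expr, config$min_reads)
  contam <- classify_contaminants(expr, config$positivity_tpm)
  out <- merge(reads, contam[, c("cell_id", "contaminant_class")],
               by = "cell_id", sort = FALSE)
  out <- out[match(expr$cell_meta$cell_id, out$cell_id), , drop = FALSE]
  out$retained <- out$reads_pass & out$contaminant_class == "none"
  rownames(out) <- NULL
  out
}

#' Summarize a QC table
#'
#' @param qc QC table from [qc_filter()] (or any data frame with a logical
#'   `retained` column).
#' @return List with `candidates`, `retained`, `eliminated` and
#'   `retained_pct` (percentage rounded half-up to the nearest integer).
#' @export
qc_summary <- function(qc) {
  if (NROW(qc) == 0) stop("empty QC table: no candidate cells", call. = FALSE)
  candidates <- nrow(qc)
  retained <- sum(qc$retained)
  list(candidates = candidates,
       retained = retained,
       eliminated = candidates - retained,
       retained_pct = round_half_up(100 * retained / candidates))
}

# round-half-up to integer (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)
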