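#' Run the full CTC phenotyping pipeline
#'
#' Executes, in order: read-count and contaminant QC, marker-space
#' phenotyping of the retained cells, 3 x 4 cross-classification with
#' chi-square adjusted-residual analysis, per-patient detection rates with
#' Fisher exact comparisons, within-patient heterogeneity, and survival
#' stratification by CTC burden. The pipeline is a pure function of
#' (inputs, config): rerunning with identical inputs yields an identical
#' report.
#'
#' @param expr A [expression_matrix()] of candidate cells.
#' @param clinical Clinical table ([read_clinical_table()]).
#' @param config Configuration list ([default_config()]).
#' @return Object of class `ctc_report`: a list with elements `config`,
#'   `qc`, `qc_summary`, `annotations`, `contingency`, `chi_square`,
#'   `residuals`, `detection`, `fisher`, `heterogeneity`, `ctc_counts`,
#'   `survival`.
#' @export
run_pipeline <- function(expr, clinical, config = default_config()) {
  clinical <- validate_clinical(clinical)
  qc <- qc_filter(expr, config)
  qs <- qc_summary(qc)
  qs$reads_tier_pct <-
    round_half_up(100 * mean(qc$unique_reads > config$reported_reads_tier))
  if (qs$retained == 0) {
    stop(sprintf(
      "no cells survive QC (%d candidates: %d failed read floor, %d contaminants)",
      qs$candidates, sum(!qc$reads_pass),
      sum(qc$contaminant_class != "none")), call. = FALSE)
  }
  retained <- subset_cells(expr, qc$cell_id[qc$retained])
  ann <- annotate_cells(retained, config)

  contingency <- cross_tabulate(ann)
  chi <- tryCatch(suppressWarnings(chi_square_test(contingency)),
                  error = function(e) list(statistic = NA_real_,
                                           df = NA_real_, p_value = NA_real_,
                                           error = conditionMessage(e)))
  res <- tryCatch(adjusted_residuals(contingency),
                  error = function(e) NULL)

  detection <- patient_positivity(ann, clinical)
  fisher <- detection_fisher(detection)
  counts <- patient_ctc_counts(ann, clinical)
  surv <- survival_report(counts, clinical,
                          line_filter = config$line_filter,
                          variant = config$gehan_variant)

  structure(list(
    config = config,
    qc = qc,
    qc_summary = qs,
    annotations = ann,
    contingency = contingency,
    chi_square = chi,
    residuals = res,
    detection = detection,
    fisher = fisher,
    heterogeneity = heterogeneity_summary(ann),
    ctc_counts = counts,
    survival = surv
  ), class = "ctc_report")
}

#' Fisher exact comparisons of detection rates
#'
#' Compares the epithelial detection rate against the EMT rate and against
#' the combined rate, each as an independent 2 x 2 table of
#' positive/negative patients.
#'
#' @param detection Detection table from [patient_positivity()].
#' @return Data frame `comparison`, `p_value`.
#' @export
detection_fisher <- function(detection) {
  row_of <- function(type) {
    d <- detection[detection$ctc_type == type, ]
    c(d$positive, d$negative)
  }
  cmp <- function(a, b) {
    fisher_exact_2x2(rbind(row_of(a), row_of(b)))
  }
  data.frame(
    comparison = c("epithelial_vs_emt", "epithelial_vs_epithelial_or_emt"),
    p_value = c(cmp("epithelial", "emt"),
                cmp("epithelial", "epithelial_or_emt")),
    stringsAsFactors = FALSE
  )
}

#' Paired McNemar comparisons of detection rates
#'
#' Non-default alternative to [detection_fisher()]: because each patient
#' contributes to both detection rates, the two positivity indicators are
#' paired, and McNemar's test on the discordant patients is the matched
#' analysis. Provided for sensitivity analysis; the Fisher comparison of
#' independent 2 x 2 groups is the default reported one.
#'
#' @param annotations Annotation table of retained cells.
#' @param clinical Clinical table defining the cohort.
#' @return Data frame `comparison`, `p_value`.
#' @export
detection_mcnemar <- function(annotations, clinical) {
  counts <- patient_ctc_counts(annotations, clinical)
  epi <- counts$epithelial_ctc_count >= 1
  emt <- counts$emt_ctc_count >= 1
  either <- epi | emt
  pair_p <- function(a, b) {
    tab <- table(factor(a, c(FALSE, TRUE)), factor(b, c(FALSE, TRUE)))
    stats::mcnemar.test(tab)$p.value
  }
  data.frame(
    comparison = c("epithelial_vs_emt", "epithelial_vs_epithelial_or_emt"),
    p_value = c(pair_p(epi, emt), pair_p(epi, either)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ctc_report <- function(x, ...) {
  qs <- x$qc_summary
  cat(sprintf("CTC phenotyping report: %d candidates, %d retained (%d%%)\n",
              qs$candidates, qs$retained, qs$retained_pct))
  cat("contingency (epithelial x EMT/stem):\n")
  print(x$contingency)
  if (!is.na(x$chi_square$statistic))
    cat(sprintf("chi-square %.2f on %d df, p = %.3g\n",
                x$chi_square$statistic, x$chi_square$df,
                x$chi_square$p_value))
  cat("detection rates:\n")
  print(x$detection, row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits a JSON summary (`report.json`) plus one TSV per table:
#' `qc.tsv`, `annotations.tsv`, `contingency.tsv`, `residuals.tsv`,
#' `detection.tsv`, `ctc_counts.tsv`, `survival.tsv`.
#'
#' @param report A `ctc_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the path to `report.json`.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "ctc_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, name) {
    utils::write.table(d, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(report$qc, "qc.tsv")
  tsv(report$annotations, "annotations.tsv")
  ctab <- data.frame(epithelial = rownames(report$contingency),
                     report$contingency, check.names = FALSE)
  tsv(ctab, "contingency.tsv")
  if (!is.null(report$residuals)) tsv(report$residuals, "residuals.tsv")
  tsv(report$detection, "detection.tsv")
  tsv(report$ctc_counts, "ctc_counts.tsv")
  tsv(report$survival, "survival.tsv")
  json <- list(
    config = report$config,
    qc_summary = report$qc_summary,
    contingency = report$contingency,
    chi_square = report$chi_square[c("statistic", "df", "p_value")],
    detection = report$detection,
    fisher = report$fisher,
    heterogeneity = report$heterogeneity,
    survival = report$survival
  )
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Score phenotype recovery on labelled synthetic data
#'
#' Given a synthetic expression matrix with ground-truth archetype labels,
#' runs QC and phenotyping and reports (1) contaminant removal: the
#' fraction of leukocyte/endothelial/mixed-cluster cells not retained, and
#' (2) CTC classification accuracy: the fraction of retained CTC-class
#' cells whose assigned (epithelial, EMT/stem) group pair matches the
#' archetype's expected pair ([expected_archetype_groups()]).
#'
#' @param expr Synthetic [expression_matrix()].
#' @param labels Data frame `cell_id`, `archetype` (from
#'   [generate_cells()] / [generate_cohort()]).
#' @param config Pipeline configuration.
#' @return List `contaminant_removal`, `ctc_accuracy`,
#'   `n_contaminant`, `n_ctc_retained`, `per_archetype` (named accuracy
#'   vector).
#' @export
evaluate_recovery <- function(expr, labels, config = default_config()) {
  qc <- qc_filter(expr, config)
  contam_classes <- c("leukocyte", "endothelial", "mixed_cluster")
  truth <- labels$archetype[match(qc$cell_id, labels$cell_id)]
  is_contam <- truth %in% contam_classes
  removal <- if (any(is_contam)) mean(!qc$retained[is_contam]) else NA_real_

  retained_ids <- qc$cell_id[qc$retained]
  ann <- annotate_cells(subset_cells(expr, retained_ids), config)
  exp_map <- expected_archetype_groups()
  ann$archetype <- labels$archetype[match(ann$cell_id, labels$cell_id)]
  ctc <- ann[ann$archetype %in% exp_map$archetype, , drop = FALSE]
  m <- match(ctc$archetype, exp_map$archetype)
  hit <- ctc$epithelial_group == exp_map$epithelial_group[m] &
    ctc$emt_stem_group == exp_map$emt_stem_group[m]
  per <- tapply(hit, ctc$archetype, mean)
  list(contaminant_removal = removal,
       ctc_accuracy = if (nrow(ctc)) mean(hit) else NA_real_,
       n_contaminant = sum(is_contam),
       n_ctc_retained = nrow(ctc),
       per_archetype = per)
}
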