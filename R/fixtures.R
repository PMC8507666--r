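#' Reference 59-cell CTC phenotype labels
#'
#' A built-in annotation fixture reproducing the group structure of a
#' reported 27-patient metastatic colorectal cancer single-CTC cohort:
#' 59 retained CTCs/CTC clusters whose 3 x 4 cross-classification is
#' (7,0,1,0 / 0,0,7,3 / 0,9,4,28) with rows High/Middle/Low epithelial and
#' columns HighStem_LowEMT / LowStem_MiddleEMT / LowStem_LowEMT /
#' LowStem_HighEMT. Patient assignment is arranged so that, of the 27
#' patients, 8 are epithelial-CTC positive, 20 EMT-CTC positive and 24
#' positive for either type; 13 patients carry cells of two or more
#' categories, 6 of them the Category 2 + 4 combination; the 7
#' high-epithelial/high-stem cells are CTC-cluster objects.
#'
#' @return Annotation data frame as produced by [annotate_cells()]
#'   (without scores): `cell_id`, `patient_id`, `is_cluster`,
#'   `epithelial_group`, `emt_stem_group`, `category`.
#' @seealso [reference_cohort_patients()]
#' @export
reference_ctc_labels <- function() {
  # one row per (patient, epithelial group, EMT/stem group, n cells)
  spec <- list(
    # high-epithelial / high-stem cluster cells
    list("P01", "High", "HighStem_LowEMT", 3, TRUE),
    list("P02", "High", "HighStem_LowEMT", 2, TRUE),
    list("P03", "High", "HighStem_LowEMT", 1, TRUE),
    list("P04", "High", "HighStem_LowEMT", 1, TRUE),
    list("P04", "High", "LowStem_LowEMT", 1, FALSE),
    # middle-epithelial cells
    list("P03", "Middle", "LowStem_LowEMT", 1, FALSE),
    list("P04", "Middle", "LowStem_LowEMT", 4, FALSE),
    list("P05", "Middle", "LowStem_LowEMT", 2, FALSE),
    list("P06", "Middle", "LowStem_HighEMT", 1, FALSE),
    list("P07", "Middle", "LowStem_HighEMT", 1, FALSE),
    list("P08", "Middle", "LowStem_HighEMT", 1, FALSE),
    # low-epithelial cells
    list("P05", "Low", "LowStem_HighEMT", 1, FALSE),
    list("P09", "Low", "LowStem_MiddleEMT", 1, FALSE),
    list("P09", "Low", "LowStem_HighEMT", 1, FALSE),
    list("P10", "Low", "LowStem_MiddleEMT", 1, FALSE),
    list("P10", "Low", "LowStem_HighEMT", 1, FALSE),
    list("P11", "Low", "LowStem_MiddleEMT", 1, FALSE),
    list("P11", "Low", "LowStem_HighEMT", 1, FALSE),
    list("P12", "Low", "LowStem_MiddleEMT", 1, FALSE),
    list("P12", "Low", "LowStem_HighEMT", 1, FALSE),
    list("P13", "Low", "LowStem_HighEMT", 2, FALSE),
    list("P14", "Low", "LowStem_MiddleEMT", 1, FALSE),
    list("P14", "Low", "LowStem_HighEMT", 2, FALSE),
    list("P15", "Low", "LowStem_MiddleEMT", 2, FALSE),
    list("P15", "Low", "LowStem_HighEMT", 1, FALSE),
    list("P16", "Low", "LowStem_MiddleEMT", 2, FALSE),
    list("P16", "Low", "LowStem_LowEMT", 1, FALSE),
    list("P17", "Low", "LowStem_HighEMT", 3, FALSE),
    list("P17", "Low", "LowStem_LowEMT", 1, FALSE),
    list("P18", "Low", "LowStem_HighEMT", 3, FALSE),
    list("P18", "Low", "LowStem_LowEMT", 1, FALSE),
    list("P19", "Low", "LowStem_HighEMT", 3, FALSE),
    list("P19", "Low", "LowStem_LowEMT", 1, FALSE),
    list("P20", "Low", "LowStem_HighEMT", 3, FALSE),
    list("P21", "Low", "LowStem_HighEMT", 2, FALSE),
    list("P22", "Low", "LowStem_HighEMT", 2, FALSE),
    list("P23", "Low", "LowStem_HighEMT", 1, FALSE),
    list("P24", "Low", "LowStem_HighEMT", 1, FALSE)
  )
  rows <- do.call(rbind, lapply(spec, function(s) {
    data.frame(patient_id = s[[1]], epithelial_group = s[[2]],
               emt_stem_group = s[[3]], n = s[[4]], is_cluster = s[[5]],
               stringsAsFactors = FALSE)
  }))
  ann <- rows[rep(seq_len(nrow(rows)), rows$n),
              c("patient_id", "is_cluster", "epithelial_group",
                "emt_stem_group")]
  ann <- data.frame(cell_id = sprintf("ctc%02d", seq_len(nrow(ann))), ann,
                    stringsAsFactors = FALSE)
  rownames(ann) <- NULL
  ann$category <- assign_categories(ann)
  ann
}

#' Patient IDs of the reference cohort
#'
#' The 27 patients backing [reference_ctc_labels()] (24 with retained
#' cells, 3 CTC-negative).
#'
#' @return Character vector of 27 patient IDs.
#' @export
reference_cohort_patients <- function() sprintf("P%02d", 1:27)

#' Synthetic clinical companion for the reference cohort
#'
#' Patient-level survival times of the reference cohort were never
#' published, so this generates a synthetic clinical table for the 27
#' reference patients: treatment lines drawn with ~80% second-or-later,
#' exponential PFS/OS with a hazard increase for patients with two or more
#' EMT CTCs in [reference_ctc_labels()], uniform censoring. Use it to
#' exercise pipeline plumbing, not to reproduce reported survival numbers.
#'
#' @param seed Integer seed.
#' @param hazard_ratio_emt Hazard ratio for the high-EMT-burden stratum
#'   (default 2).
#' @return Clinical table as in [read_clinical_table()].
#' @export
synthetic_reference_clinical <- function(seed = 1L, hazard_ratio_emt = 2) {
  set.seed(seed)
  pids <- reference_cohort_patients()
  ann <- reference_ctc_labels()
  clin0 <- data.frame(patient_id = pids, stringsAsFactors = FALSE)
  emt_counts <- patient_ctc_counts(ann, clin0)$emt_ctc_count
  hr <- ifelse(emt_counts >= 2, hazard_ratio_emt, 1)
  n <- length(pids)
  t_pfs <- stats::rexp(n, log(2) / 76 * hr)
  t_os <- stats::rexp(n, log(2) / 300 * hr)
  c_pfs <- stats::runif(n, 100, 800)
  c_os <- stats::runif(n, 100, 800)
  validate_clinical(data.frame(
    patient_id = pids,
    treatment_line = sample(1:4, n, replace = TRUE,
                            prob = c(0.2, 0.45, 0.25, 0.1)),
    pfs_days = pmin(t_pfs, c_pfs),
    pfs_event = t_pfs <= c_pfs,
    os_days = pmin(t_os, c_os),
    os_event = t_os <= c_os,
    stringsAsFactors = FALSE))
}
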