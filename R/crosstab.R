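#' Cross-tabulate epithelial vs EMT/stem groups
#'
#' Builds the 3 x 4 contingency table of cell counts: rows `High`,
#' `Middle`, `Low` epithelial, columns `HighStem_LowEMT`,
#' `LowStem_MiddleEMT`, `LowStem_LowEMT`, `LowStem_HighEMT`.
#'
#' @param annotations Annotation table from [annotate_cells()] (needs
#'   `epithelial_group` and `emt_stem_group` columns).
#' @return Integer matrix with named dimnames; `sum()` of the table equals
#'   the number of annotated cells.
#' @export
cross_tabulate <- function(annotations) {
  rows <- c("High", "Middle", "Low")
  cols <- c("HighStem_LowEMT", "LowStem_MiddleEMT", "LowStem_LowEMT",
            "LowStem_HighEMT")
  tab <- table(factor(annotations$epithelial_group, levels = rows),
               factor(annotations$emt_stem_group, levels = cols))
  out <- matrix(as.integer(tab), nrow = length(rows),
                dimnames = list(epithelial = rows, emt_stem = cols))
  out
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic without continuity correction; expected counts
#' `E = row_total x col_total / n`, `df = (r-1)(c-1)`. A warning is issued
#' when any expected count falls below 5 (the asymptotic p-value is then
#' approximate).
#'
#' @param table Non-negative integer matrix (r x c, both >= 2).
#' @return List `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_test <- function(table) {
  check_margins(table)
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(ct$expected < 5)) {
    warning("expected count < 5 in at least one cell; chi-square p-value is approximate",
            call. = FALSE)
  }
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}

check_margins <- function(table) {
  if (sum(table) == 0) stop("empty contingency table", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate margin: a row or column total is zero", call. = FALSE)
  invisible(table)
}

#' Adjusted standardized residual analysis
#'
#' Post-hoc cell-wise analysis of a contingency table using Haberman
#' adjusted standardized residuals,
#' `(O - E) / sqrt(E (1 - row_total/n) (1 - col_total/n))`, which are
#' approximately standard normal under independence. Each cell is coded by
#' sign and magnitude against the two-sided cutpoints 1.96 (p < 0.05) and
#' 2.58 (p < 0.01): `high_p01`, `high_p05`, `ns`, `low_p05`, `low_p01`.
#'
#' @param table Non-negative integer matrix with nondegenerate margins.
#' @return Data frame with one row per cell: `row`, `col`, `observed`,
#'   `expected`, `adjusted_residual`, `significance`.
#' @export
adjusted_residuals <- function(table) {
  check_margins(table)
  n <- sum(table)
  rt <- rowSums(table)
  ct <- colSums(table)
  expected <- outer(rt, ct) / n
  adj <- (table - expected) /
    sqrt(expected * outer(1 - rt / n, 1 - ct / n))
  sig <- ifelse(adj >= 2.58, "high_p01",
         ifelse(adj >= 1.96, "high_p05",
         ifelse(adj <= -2.58, "low_p01",
         ifelse(adj <= -1.96, "low_p05", "ns"))))
  grid <- expand.grid(row = rownames(table, do.NULL = FALSE),
                      col = colnames(table, do.NULL = FALSE),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(grid,
             observed = as.vector(table),
             expected = as.vector(expected),
             adjusted_residual = as.vector(adj),
             significance = as.vector(sig),
             stringsAsFactors = FALSE)
}

#' Count significant contingency cells
#'
#' @param residuals Output of [adjusted_residuals()].
#' @param direction `"high"` (over-represented) or `"low"`.
#' @param alpha 0.05 or 0.01.
#' @return Number of cells significant in that direction at that level.
#' @export
count_significant <- function(residuals, direction = c("high", "low"),
                              alpha = 0.05) {
  direction <- match.arg(direction)
  stopifnot(alpha %in% c(0.05, 0.01))
  codes <- if (alpha == 0.05) {
    paste0(direction, c("_p05", "_p01"))
  } else {
    paste0(direction, "_p01")
  }
  sum(residuals$significance %in% codes)
}

#' Assign CTC categories 1-4
#'
#' The four phenotype categories found to be significantly enriched in the
#' cross-classification: Category 1 = high epithelial and high stem/low
#' EMT; Category 2 = low epithelial and low stem/middle EMT; Category 3 =
#' middle epithelial and low stem/low EMT; Category 4 = low epithelial and
#' low stem/high EMT. Any other group pair maps to `"other"`.
#'
#' @param annotations Annotation table with `epithelial_group` and
#'   `emt_stem_group` columns.
#' @return Character vector of category labels (`"1"`..`"4"`, `"other"`).
#' @export
assign_categories <- function(annotations) {
  key <- paste(annotations$epithelial_group, annotations$emt_stem_group)
  map <- c("High HighStem_LowEMT" = "1",
           "Low LowStem_MiddleEMT" = "2",
           "Middle LowStem_LowEMT" = "3",
           "Low LowStem_HighEMT" = "4")
  out <- unname(map[key])
  out[is.na(out)] <- "other"
  out
}

#' Per-patient CTC-type detection rates
#'
#' A patient is positive for a CTC type when they have at least one cell of
#' it: epithelial CTC = cell in the `Middle` or `High` epithelial group;
#' EMT CTC = cell in the `LowStem_MiddleEMT` or `LowStem_HighEMT` group;
#' the combined type is positive when either is. Patients with no retained
#' cells count as negative. Rates are percentages of the full cohort,
#' rounded half-up to integers.
#'
#' @param annotations Annotation table of retained cells.
#' @param clinical Clinical table defining the cohort (one row per
#'   patient).
#' @return Data frame with rows `epithelial`, `emt`, `epithelial_or_emt`
#'   and columns `ctc_type`, `positive`, `negative`, `rate_pct`.
#' @export
patient_positivity <- function(annotations, clinical) {
  unknown <- setdiff(annotations$patient_id, clinical$patient_id)
  if (length(unknown))
    stop("annotation references patient(s) absent from clinical table: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  counts <- patient_ctc_counts(annotations, clinical)
  n <- nrow(clinical)
  pos <- c(epithelial = sum(counts$epithelial_ctc_count >= 1),
           emt = sum(counts$emt_ctc_count >= 1),
           epithelial_or_emt = sum(counts$epithelial_ctc_count >= 1 |
                                     counts$emt_ctc_count >= 1))
  data.frame(ctc_type = names(pos),
             positive = unname(pos),
             negative = n - unname(pos),
             rate_pct = round_half_up(100 * unname(pos) / n),
             stringsAsFactors = FALSE)
}

#' Per-patient CTC-type counts
#'
#' @param annotations Annotation table of retained cells.
#' @param clinical Clinical table (defines the patient set; patients with
#'   no cells get zero counts).
#' @return Data frame `patient_id`, `epithelial_ctc_count`,
#'   `emt_ctc_count`, `total_ctc_count`.
#' @export
patient_ctc_counts <- function(annotations, clinical) {
  pids <- clinical$patient_id
  epi <- annotations$epithelial_group %in% c("Middle", "High")
  emt <- annotations$emt_stem_group %in% c("LowStem_MiddleEMT",
                                           "LowStem_HighEMT")
  cnt <- function(flag) {
    t <- table(factor(annotations$patient_id[flag], levels = pids))
    as.integer(t)
  }
  data.frame(patient_id = pids,
             epithelial_ctc_count = cnt(epi),
             emt_ctc_count = cnt(emt),
             total_ctc_count = cnt(rep(TRUE, nrow(annotations))),
             stringsAsFactors = FALSE)
}

#' Fisher exact test for a 2 x 2 table
#'
#' Exact two-sided p-value by hypergeometric enumeration with margins
#' fixed: the sum of probabilities of all compatible tables whose
#' probability does not exceed that of the observed table (within a
#' relative tolerance of 1e-7 for ties, as is conventional).
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(table) == 0) stop("empty 2x2 table", call. = FALSE)
  m <- sum(table[1, ])          # margin of row 1
  n2 <- sum(table[2, ])
  k <- sum(table[, 1])          # margin of column 1
  x <- table[1, 1]
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(x, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Within-patient phenotype heterogeneity
#'
#' Counts patients whose retained cells span two or more distinct
#' categories (Categories 1-4 plus `"other"` as a fifth class) and, among
#' those patients, the fraction containing each observed unordered category
#' pair.
#'
#' @param annotations Annotation table with `category` assigned.
#' @return List `n_multi_category` and `combo_fractions` (named numeric
#'   vector over pairs such as `"2+4"`; fraction of multi-category patients
#'   whose category set contains the pair).
#' @export
heterogeneity_summary <- function(annotations) {
  sets <- lapply(split(annotations$category, annotations$patient_id),
                 function(x) sort(unique(x)))
  multi <- Filter(function(s) length(s) >= 2, sets)
  n_multi <- length(multi)
  if (n_multi == 0)
    return(list(n_multi_category = 0L, combo_fractions = numeric(0)))
  pair_names <- unique(unlist(lapply(multi, function(s) {
    cmb <- utils::combn(s, 2)
    apply(cmb, 2, paste, collapse = "+")
  })))
  fr <- vapply(pair_names, function(p) {
    pair <- strsplit(p, "+", fixed = TRUE)[[1]]
    mean(vapply(multi, function(s) all(pair %in% s), logical(1)))
  }, numeric(1))
  list(n_multi_category = n_multi, combo_fractions = fr)
}
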