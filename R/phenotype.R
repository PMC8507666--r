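#' Log-transform TPM values
#'
#' `log10(x + 1)`, elementwise: the scale on which marker heatmaps are drawn
#' and on which panel scores and clustering distances are computed. The
#' pseudocount maps zero expression to exactly zero.
#'
#' @param values Non-negative numeric vector or matrix of TPM values.
#' @return Transformed values, same shape.
#' @export
log_transform <- function(values) {
  if (any(values < 0, na.rm = TRUE))
    stop("TPM values must be non-negative", call. = FALSE)
  log10(values + 1)
}

#' Marker-panel expression score per cell
#'
#' The panel score of a cell is the sum (default) or mean of
#' `log10(TPM + 1)` over the panel genes. Panel genes absent from the
#' matrix contribute zero (with a warning).
#'
#' @param expr A [expression_matrix()] object.
#' @param panel Character vector of gene symbols, or a panel name from
#'   [marker_panels()] (`"epithelial"`, `"stem"`, `"emt"`, ...).
#' @param method `"sum"` (default) or `"mean"`.
#' @return Named numeric vector, one score per cell.
#' @export
gene_set_score <- function(expr, panel, method = c("sum", "mean")) {
  method <- match.arg(method)
  if (length(panel) == 1 && panel %in% names(marker_panels()))
    panel <- marker_panels()[[panel]]
  sub <- log_transform(panel_submatrix(expr, panel, warn = TRUE))
  if (method == "sum") colSums(sub) else colMeans(sub)
}

#' Hierarchical clustering of cells in marker space
#'
#' Agglomerative clustering with Ward linkage on Euclidean distances of the
#' supplied log-scale marker submatrix, dendrogram cut to exactly `k`
#' clusters. Deterministic for a fixed input ordering.
#'
#' @param mat Numeric matrix, marker genes as rows and cells as columns,
#'   already on the log10(TPM+1) scale.
#' @param k Number of clusters.
#' @return Integer vector of cluster labels (1..k), named by cell ID.
#' @export
cluster_cells <- function(mat, k) {
  n <- ncol(mat)
  if (n < k)
    stop(sprintf("cannot cut %d cell(s) into %d clusters", n, k),
         call. = FALSE)
  if (k == 1) return(stats::setNames(rep(1L, n), colnames(mat)))
  hc <- stats::hclust(stats::dist(t(mat)), method = "ward.D2")
  stats::cutree(hc, k = k)
}

# Rank clusters by a per-cluster summary and resolve ties by descending
# cluster size (logged). Returns the cluster ids in ranking order.
rank_clusters <- function(labels, stat_per_cluster, decreasing = FALSE) {
  sizes <- as.integer(table(labels)[names(stat_per_cluster)])
  if (anyDuplicated(stat_per_cluster)) {
    message("tie in cluster mean scores; broken by cluster size (descending)")
  }
  key <- if (decreasing) -stat_per_cluster else stat_per_cluster
  ord <- order(key, -sizes)
  names(stat_per_cluster)[ord]
}

#' Name epithelial clusters Low/Middle/High
#'
#' The three clusters are ranked by mean epithelial panel score and named
#' `Low`, `Middle`, `High` in ascending order. Ties in cluster means are
#' broken by cluster size, larger cluster taking the lower name.
#'
#' @param labels Cluster labels from [cluster_cells()] (exactly 3 clusters).
#' @param scores Epithelial score per cell, same order as `labels`.
#' @return Character vector of group names per cell.
#' @export
name_epithelial_groups <- function(labels, scores) {
  if (length(unique(labels)) != 3)
    stop("expected exactly 3 epithelial clusters", call. = FALSE)
  means <- tapply(scores, labels, mean)
  ranked <- rank_clusters(labels, means, decreasing = FALSE)
  nm <- stats::setNames(c("Low", "Middle", "High"), ranked)
  unname(nm[as.character(labels)])
}

#' Name EMT/stem clusters
#'
#' The cluster with the highest mean stem score becomes
#' `HighStem_LowEMT`; the remaining three are ranked by mean EMT score
#' descending into `LowStem_HighEMT`, `LowStem_MiddleEMT`,
#' `LowStem_LowEMT`. Ties are broken by cluster size descending.
#'
#' @param labels Cluster labels (exactly 4 clusters).
#' @param stem_scores,emt_scores Per-cell stem and EMT panel scores.
#' @return Character vector of group names per cell.
#' @export
name_emt_stem_groups <- function(labels, stem_scores, emt_scores) {
  if (length(unique(labels)) != 4)
    stop("expected exactly 4 EMT/stem clusters", call. = FALSE)
  stem_means <- tapply(stem_scores, labels, mean)
  high_stem <- rank_clusters(labels, stem_means, decreasing = TRUE)[1]
  rest <- setdiff(names(stem_means), high_stem)
  emt_means <- tapply(emt_scores, labels, mean)[rest]
  sub_labels <- labels[as.character(labels) %in% rest]
  ranked <- rank_clusters(sub_labels, emt_means, decreasing = TRUE)
  nm <- stats::setNames(
    c("HighStem_LowEMT", "LowStem_HighEMT", "LowStem_MiddleEMT",
      "LowStem_LowEMT"),
    c(high_stem, ranked))
  unname(nm[as.character(labels)])
}

#' Compare panel scores between two cell groups
#'
#' Two-sided Mann-Whitney U test of the score distributions. Small, untied
#' samples use the exact permutation distribution; otherwise the normal
#' approximation with tie correction is used. Two identical degenerate
#' groups (zero variance, zero shift) give p = 1.
#'
#' @param scores_a,scores_b Numeric score vectors (both nonempty).
#' @return Two-sided p-value.
#' @export
compare_group_scores <- function(scores_a, scores_b) {
  if (length(scores_a) == 0 || length(scores_b) == 0)
    stop("both groups must be nonempty", call. = FALSE)
  if (length(unique(c(scores_a, scores_b))) == 1) return(1)
  suppressWarnings(
    stats::wilcox.test(scores_a, scores_b, correct = FALSE)$p.value
  )
}

#' Phenotype all retained cells
#'
#' Runs the two marker-space clusterings and produces the per-cell
#' annotation table: epithelial grouping on the epithelial + leukocyte +
#' endothelial panels (14 genes, k = 3) and EMT/stem grouping on the stem +
#' EMT panels (18 genes, k = 4), both on log10(TPM+1) values, followed by
#' category assignment ([assign_categories()]).
#'
#' @param expr A [expression_matrix()] restricted to QC-retained cells
#'   (see [subset_cells()]).
#' @param config Pipeline configuration.
#' @return Data frame with columns `cell_id`, `patient_id`, `is_cluster`,
#'   `epithelial_score`, `stem_score`, `emt_score`, `epithelial_group`,
#'   `emt_stem_group`, `category`.
#' @export
annotate_cells <- function(expr, config = default_config()) {
  stopifnot(inherits(expr, "ctc_expr"))
  panels <- marker_panels()
  method <- config$score_method
  epi_score <- gene_set_score(expr, panels$epithelial, method)
  stem_score <- gene_set_score(expr, panels$stem, method)
  emt_score <- gene_set_score(expr, panels$emt, method)

  epi_genes <- c(panels$epithelial, panels$leukocyte, panels$endothelial)
  epi_mat <- log_transform(panel_submatrix(expr, epi_genes, warn = FALSE))
  epi_labels <- cluster_cells(epi_mat, config$k_epithelial)
  epi_group <- name_epithelial_groups(epi_labels, epi_score)

  es_genes <- c(panels$stem, panels$emt)
  es_mat <- log_transform(panel_submatrix(expr, es_genes, warn = FALSE))
  es_labels <- cluster_cells(es_mat, config$k_emt_stem)
  es_group <- name_emt_stem_groups(es_labels, stem_score, emt_score)

  ann <- data.frame(
    cell_id = expr$cell_meta$cell_id,
    patient_id = expr$cell_meta$patient_id,
    is_cluster = expr$cell_meta$is_cluster,
    epithelial_score = unname(epi_score),
    stem_score = unname(stem_score),
    emt_score = unname(emt_score),
    epithelial_group = epi_group,
    emt_stem_group = es_group,
    stringsAsFactors = FALSE
  )
  ann$category <- assign_categories(ann)
  ann
}
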