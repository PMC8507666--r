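#' Cell archetype specifications for the synthetic generator
#'
#' Defines the expression program of each simulated cell archetype: which
#' marker genes are "on", at what log10-TPM mean and spread, with what
#' dropout probability, plus sparse background expression over all other
#' genes. The archetypes emulate the phenotypes the classifier is built to
#' recover: epithelial CTCs of middle and high marker expression, EMT CTCs
#' (strong and intermediate), stem-like CTC clusters co-expressing
#' epithelial markers, leukocytes (PTPRC), endothelial cells (PECAM1) and
#' leukocyte-contaminated clusters.
#'
#' On-gene sets follow the marker biology: middle-epithelial cells express
#' EPCAM, CLDN4 and keratins 8/18/19/20; high-epithelial cells add CLDN3 and
#' CLDN7 at higher levels; EMT cells express the mesenchymal panel led by
#' VIM, SPARC and ITGB1; intermediate-EMT cells express VIM/SPARC/ITGB1 more
#' weakly together with moderate CD44, KLF4 and MYC; stem-like clusters
#' strongly express CD44, ALDH2 and MYC (plus LGR5, PROM1) on a
#' high-epithelial background. Lineage contaminants carry a low dropout
#' probability because PTPRC and PECAM1 are abundant lineage markers that
#' are rarely lost to technical zeros.
#'
#' @param on_log_sd Log10-scale SD of on-gene expression (default 0.5).
#' @param dropout_prob Per-gene dropout probability for CTC archetypes
#'   (default 0.2). Contaminant archetypes use `contaminant_dropout`.
#' @param contaminant_dropout Dropout probability for leukocyte, endothelial
#'   and mixed-cluster archetypes (default 0.02).
#' @param background_rate Probability that any off-panel-program gene is
#'   expressed at background level (default 0.05).
#' @param background_log_mean Log10-TPM mean of background expression
#'   (default 0.5, i.e. ~3 TPM).
#' @return Named list of archetype specs, each a list with fields `name`,
#'   `on_genes`, `on_log_mean` (per-gene vector), `on_log_sd`,
#'   `dropout_prob`, `background_rate`, `background_log_mean`,
#'   `background_log_sd`, `is_cluster`.
#' @seealso [generate_cells()], [generate_cohort()], [expected_archetype_groups()]
#' @export
archetype_specs <- function(on_log_sd = 0.5, dropout_prob = 0.2,
                            contaminant_dropout = 0.02,
                            background_rate = 0.05,
                            background_log_mean = 0.5) {
  mk <- function(name, genes, means, dropout, cluster = FALSE) {
    list(name = name, on_genes = genes,
         on_log_mean = rep_len(means, length(genes)),
         on_log_sd = on_log_sd, dropout_prob = dropout,
         background_rate = background_rate,
         background_log_mean = background_log_mean,
         background_log_sd = 0.25, is_cluster = cluster)
  }
  epi_mid <- c("EPCAM", "CLDN4", "KRT8", "KRT18", "KRT19", "KRT20")
  epi_high <- c(epi_mid, "CLDN3", "CLDN7")
  list(
    epithelial_mid = mk("epithelial_mid", epi_mid, 2.0, dropout_prob),
    epithelial_high = mk("epithelial_high", epi_high, 2.5, dropout_prob),
    emt = mk("emt",
             c("VIM", "SPARC", "ITGB1", "TFAP4", "ZEB2", "SNAI1", "CDH2"),
             2.0, dropout_prob),
    emt_mid = mk("emt_mid",
                 c("VIM", "SPARC", "ITGB1", "CD44", "KLF4", "MYC"),
                 1.5, dropout_prob),
    stem_cluster = mk("stem_cluster",
                      c("CD44", "ALDH2", "MYC", "LGR5", "PROM1", epi_high),
                      c(rep(2.5, 5), rep(2.0, length(epi_high))),
                      dropout_prob, cluster = TRUE),
    leukocyte = mk("leukocyte", "PTPRC", 2.5, contaminant_dropout),
    endothelial = mk("endothelial", "PECAM1", 2.5, contaminant_dropout),
    mixed_cluster = mk("mixed_cluster",
                       c("PTPRC", "EPCAM", "KRT8", "KRT18"),
                       c(2.0, 1.5, 1.5, 1.5),
                       contaminant_dropout, cluster = TRUE)
  )
}

#' Phenotype groups each CTC archetype is built to land in
#'
#' The ground-truth map used to score classification recovery on synthetic
#' data: each CTC-class archetype against the (epithelial group,
#' EMT/stem group) pair implied by its expression program. Contaminant
#' archetypes are absent — they are expected to be removed by QC.
#'
#' @return Data frame with columns `archetype`, `epithelial_group`,
#'   `emt_stem_group`.
#' @export
expected_archetype_groups <- function() {
  data.frame(
    archetype = c("epithelial_mid", "epithelial_high", "emt", "emt_mid",
                  "stem_cluster"),
    epithelial_group = c("Middle", "High", "Low", "Low", "High"),
    emt_stem_group = c("LowStem_LowEMT", "LowStem_LowEMT", "LowStem_HighEMT",
                       "LowStem_MiddleEMT", "HighStem_LowEMT"),
    stringsAsFactors = FALSE
  )
}

#' Gene universe for simulation
#' @param n_background Number of background (non-panel) genes, default 468,
#'   giving a 500-gene universe over the 32 panel genes.
#' @return Character vector of gene symbols.
#' @export
gene_universe <- function(n_background = 468) {
  c(panel_genes(), sprintf("BG%04d", seq_len(n_background)))
}

#' Simulate single-cell TPM profiles from archetypes
#'
#' For each cell, on-genes are drawn log-normal on the log10 scale
#' (`10^rnorm(mean, sd)`) and then zeroed independently with the archetype's
#' dropout probability; every other gene in the universe is expressed with
#' probability `background_rate` at background level, zero otherwise.
#'
#' @param archetypes List of archetype specs ([archetype_specs()]).
#' @param counts Named integer vector: cells to draw per archetype (names
#'   must match archetype names; archetypes not named get zero cells).
#' @param universe Gene universe; must contain every on-gene.
#' @param seed Integer seed (all randomness flows through it).
#' @param patient_ids Optional character vector, one per generated cell;
#'   default assigns all cells to patient `"SIM"`.
#' @return List with `expr` (a [expression_matrix()]) and `labels`
#'   (data frame `cell_id`, `archetype`).
#' @export
generate_cells <- function(archetypes, counts, universe = gene_universe(),
                           seed = 1L, patient_ids = NULL) {
  stopifnot(length(counts) > 0, !is.null(names(counts)))
  unknown <- setdiff(names(counts), names(archetypes))
  if (length(unknown))
    stop("counts name unknown archetype(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (a in archetypes[names(counts)]) {
    absent <- setdiff(a$on_genes, universe)
    if (length(absent))
      stop(sprintf("archetype '%s' on-gene(s) absent from universe: %s",
                   a$name, paste(absent, collapse = ", ")), call. = FALSE)
  }
  set.seed(seed)
  n_total <- sum(counts)
  values <- matrix(0, nrow = length(universe), ncol = n_total,
                   dimnames = list(universe, if (n_total) sprintf("cell%04d", seq_len(n_total)) else NULL))
  lab <- character(n_total)
  is_cluster <- logical(n_total)
  j <- 0L
  for (aname in names(counts)) {
    a <- archetypes[[aname]]
    for (i in seq_len(counts[[aname]])) {
      j <- j + 1L
      lab[j] <- aname
      is_cluster[j] <- isTRUE(a$is_cluster)
      on <- 10^stats::rnorm(length(a$on_genes), a$on_log_mean, a$on_log_sd)
      on[stats::runif(length(on)) < a$dropout_prob] <- 0
      values[a$on_genes, j] <- on
      bg_genes <- setdiff(universe, a$on_genes)
      active <- stats::runif(length(bg_genes)) < a$background_rate
      if (any(active))
        values[bg_genes[active], j] <-
          10^stats::rnorm(sum(active), a$background_log_mean, a$background_log_sd)
    }
  }
  if (n_total == 0)
    return(list(expr = NULL,
                labels = data.frame(cell_id = character(0),
                                    archetype = character(0),
                                    stringsAsFactors = FALSE)))
  if (is.null(patient_ids)) patient_ids <- rep("SIM", n_total)
  meta <- data.frame(
    cell_id = colnames(values),
    patient_id = patient_ids,
    unique_reads = as.integer(round(stats::runif(n_total, 5e5, 5e6))),
    is_cluster = is_cluster,
    stringsAsFactors = FALSE
  )
  list(expr = expression_matrix(values, meta),
       labels = data.frame(cell_id = colnames(values), archetype = lab,
                           stringsAsFactors = FALSE))
}

#' Cohort-level simulation parameters
#'
#' @param n_patients Cohort size (default 27).
#' @param ctc_count_mean Mean of the Poisson per-patient CTC-candidate count
#'   (default 3; observed counts in small CTC cohorts are sparse, median ~2).
#' @param archetype_mixture Named probability vector over archetypes; must
#'   sum to 1. The default puts ~46% of candidates in contaminant classes.
#' @param baseline_hazard Daily PFS event hazard for the low-EMT-burden
#'   stratum (default log(2)/76, i.e. a 76-day median).
#' @param hazard_ratio_emt Hazard ratio applied to both endpoints when a
#'   patient's true EMT CTC count reaches `emt_threshold` (default 2).
#' @param emt_threshold EMT CTC count defining the high-burden stratum
#'   (default 2).
#' @param os_hazard_scale OS hazard as a fraction of the PFS hazard
#'   (default 0.25: overall survival runs ~4x longer than PFS).
#' @param censor_time_range Days over which independent uniform censoring
#'   is drawn (default c(100, 800)).
#' @param seed Integer seed.
#' @return Named list (class `cohort_spec`).
#' @export
cohort_spec <- function(n_patients = 27L,
                        ctc_count_mean = 3,
                        archetype_mixture = c(
                          leukocyte = 0.35, endothelial = 0.06,
                          mixed_cluster = 0.05, emt = 0.25, emt_mid = 0.09,
                          epithelial_mid = 0.08, epithelial_high = 0.05,
                          stem_cluster = 0.07),
                        baseline_hazard = log(2) / 76,
                        hazard_ratio_emt = 2,
                        emt_threshold = 2L,
                        os_hazard_scale = 0.25,
                        censor_time_range = c(100, 800),
                        seed = 1L) {
  stopifnot(n_patients >= 1, baseline_hazard > 0, hazard_ratio_emt > 0,
            emt_threshold >= 1, os_hazard_scale > 0,
            length(censor_time_range) == 2,
            censor_time_range[1] > 0,
            censor_time_range[2] >= censor_time_range[1])
  if (abs(sum(archetype_mixture) - 1) > 1e-8)
    stop("archetype_mixture must sum to 1", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 ctc_count_mean = ctc_count_mean,
                 archetype_mixture = archetype_mixture,
                 baseline_hazard = baseline_hazard,
                 hazard_ratio_emt = hazard_ratio_emt,
                 emt_threshold = as.integer(emt_threshold),
                 os_hazard_scale = os_hazard_scale,
                 censor_time_range = censor_time_range,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a patient cohort with CTC-burden-dependent survival
#'
#' Draws per-patient CTC-candidate counts (Poisson), assigns each candidate
#' an archetype from the mixture, simulates its expression profile, and
#' generates exponential PFS/OS times whose hazard is multiplied by
#' `hazard_ratio_emt` for patients whose true EMT CTC count (cells of the
#' `emt` or `emt_mid` archetype) reaches `emt_threshold`. Censoring is
#' independent uniform over `censor_time_range`.
#'
#' @param spec A [cohort_spec()].
#' @param archetypes Archetype list, default [archetype_specs()].
#' @param universe Gene universe, default [gene_universe()].
#' @return List with `expr` (`ctc_expr`; `NULL` when no candidate cells were
#'   drawn), `clinical` (patient table as in [read_clinical_table()]),
#'   `truth` (per-patient true archetype counts, EMT/epithelial CTC counts
#'   and the high-EMT stratum flag) and `cell_labels`.
#' @export
generate_cohort <- function(spec, archetypes = archetype_specs(),
                            universe = gene_universe()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  pids <- sprintf("P%03d", seq_len(n))
  n_cells <- stats::rpois(n, spec$ctc_count_mean)
  arche_names <- names(spec$archetype_mixture)
  cell_arche <- lapply(seq_len(n), function(i) {
    if (n_cells[i] == 0) character(0)
    else sample(arche_names, n_cells[i], replace = TRUE,
                prob = spec$archetype_mixture)
  })

  emt_classes <- c("emt", "emt_mid")
  epi_classes <- c("epithelial_mid", "epithelial_high", "stem_cluster")
  truth <- data.frame(
    patient_id = pids,
    n_candidates = n_cells,
    emt_ctc_count = vapply(cell_arche, function(a) sum(a %in% emt_classes), 0L),
    epithelial_ctc_count = vapply(cell_arche, function(a) sum(a %in% epi_classes), 0L),
    stringsAsFactors = FALSE
  )
  truth$emt_high <- truth$emt_ctc_count >= spec$emt_threshold

  treatment_line <- sample(1:4, n, replace = TRUE,
                           prob = c(0.2, 0.45, 0.25, 0.1))
  hr <- ifelse(truth$emt_high, spec$hazard_ratio_emt, 1)
  t_pfs <- stats::rexp(n, spec$baseline_hazard * hr)
  t_os <- stats::rexp(n, spec$baseline_hazard * spec$os_hazard_scale * hr)
  c_pfs <- stats::runif(n, spec$censor_time_range[1], spec$censor_time_range[2])
  c_os <- stats::runif(n, spec$censor_time_range[1], spec$censor_time_range[2])
  clinical <- data.frame(
    patient_id = pids,
    treatment_line = treatment_line,
    pfs_days = pmin(t_pfs, c_pfs),
    pfs_event = t_pfs <= c_pfs,
    os_days = pmin(t_os, c_os),
    os_event = t_os <= c_os,
    stringsAsFactors = FALSE
  )

  # expression for the pooled candidate cells (order: patient-major)
  all_arche <- unlist(cell_arche, use.names = FALSE)
  cells <- NULL
  if (length(all_arche)) {
    # generate_cells draws archetype-by-archetype; reorder back afterwards
    counts <- table(factor(all_arche, levels = arche_names))
    counts <- stats::setNames(as.integer(counts), names(counts))
    counts <- counts[counts > 0]
    pid_per_cell <- rep(pids, n_cells)
    ord <- order(match(all_arche, names(counts)))
    gen_seed <- (spec$seed * 1009L + 7L) %% .Machine$integer.max
    cells <- generate_cells(archetypes, counts, universe,
                            seed = gen_seed,
                            patient_ids = pid_per_cell[ord])
    # restore patient-major cell order
    back <- order(ord)
    expr <- subset_cells(cells$expr, colnames(cells$expr$values)[back])
    labels <- cells$labels[back, , drop = FALSE]
    rownames(labels) <- NULL
    cells <- list(expr = expr, labels = labels)
  }

  list(expr = if (is.null(cells)) NULL else cells$expr,
       clinical = validate_clinical(clinical),
       truth = truth,
       cell_labels = if (is.null(cells))
         data.frame(cell_id = character(0), archetype = character(0))
       else cells$labels)
}
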