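#' Kaplan-Meier estimate with median and confidence interval
#'
#' Product-limit estimator of the survival function. The median is the
#' smallest observed time at which the estimate drops to 0.5 or below
#' (undefined when the curve never reaches 0.5); its 95% confidence
#' interval is the Brookmeyer-Crowley interval reported by
#' [survival::survfit()]. Events precede censorings at tied times.
#'
#' @param time Positive times (days).
#' @param event Logical event indicators (`FALSE` = censored).
#' @return List `fit` (the `survfit` object), `time`, `surv` (step
#'   function values), `n_events`, `median`, `ci_low`, `ci_high` (the
#'   latter three `NA` when undefined).
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("no survival samples", call. = FALSE)
  stopifnot(length(time) == length(event), all(time > 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log")
  q <- stats::quantile(fit, probs = 0.5)
  # median: smallest observed time at which S(t) drops to 0.5 or below
  # (quantile.survfit midpoint-averages across an exact-0.5 plateau instead)
  hit <- fit$surv <= 0.5 + 1e-12
  med <- if (any(hit)) fit$time[which(hit)[1]] else NA_real_
  list(fit = fit,
       time = fit$time,
       surv = fit$surv,
       n_events = sum(event),
       median = med,
       ci_low = unname(q$lower),
       ci_high = unname(q$upper))
}

#' Gehan generalized Wilcoxon test for censored two-sample data
#'
#' Each observation i receives the Gehan score
#' `U_i = #(observations definitely later than i) - #(definitely earlier)`,
#' where "definitely" respects censoring: a censored time can never be
#' definitely later than anything, and an event at t is definitely earlier
#' than any observation (event or censoring) at a strictly greater time.
#' The statistic is `W = sum of U_i over group a`, with permutation
#' variance `Var(W) = n_a n_b sum(U_i^2) / (N (N - 1))` and a two-sided
#' normal p-value for `z = W / sqrt(Var)`. This weights early differences
#' more heavily than the log-rank test. A Peto-Peto variant (survey of
#' `survival::survdiff(rho = 1)`) is available for comparison.
#'
#' @param time_a,event_a Times and event flags for group a.
#' @param time_b,event_b Times and event flags for group b.
#' @param variant `"gehan"` (default) or `"peto"`.
#' @param exact Compute the p-value from the exact permutation distribution
#'   of W over all reassignments of the fixed Gehan scores. Default `NULL`
#'   enumerates when the total sample size is at most 20 and uses the
#'   normal approximation otherwise.
#' @return List `statistic` (W), `z`, `p_value`, `exact`, `n_a`, `n_b`.
#' @export
gehan_wilcoxon_test <- function(time_a, event_a, time_b, event_b,
                                variant = c("gehan", "peto"),
                                exact = NULL) {
  variant <- match.arg(variant)
  n_a <- length(time_a)
  n_b <- length(time_b)
  if (n_a == 0 || n_b == 0)
    stop("both strata must be nonempty", call. = FALSE)
  if (variant == "peto") {
    grp <- rep(c(0L, 1L), c(n_a, n_b))
    sd <- survival::survdiff(
      survival::Surv(c(time_a, time_b), c(event_a, event_b)) ~ grp,
      rho = 1)
    return(list(statistic = NA_real_, z = sqrt(sd$chisq),
                p_value = stats::pchisq(sd$chisq, df = 1,
                                        lower.tail = FALSE),
                exact = FALSE, n_a = n_a, n_b = n_b))
  }
  u <- gehan_scores(c(time_a, time_b), c(event_a, event_b))
  N <- n_a + n_b
  if (is.null(exact)) exact <- N <= 20
  w <- sum(u[seq_len(n_a)])
  v <- n_a * n_b * sum(u^2) / (N * (N - 1))
  z <- if (v == 0) 0 else w / sqrt(v)
  if (v == 0) {
    p <- 1
  } else if (exact) {
    splits <- utils::combn(N, n_a)
    w_perm <- colSums(matrix(u[splits], nrow = n_a))
    p <- mean(abs(w_perm) >= abs(w) - 1e-9)
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = w, z = z, p_value = p, exact = exact && v > 0,
       n_a = n_a, n_b = n_b)
}

# Gehan scores: U_i = #(definitely later than i) - #(definitely earlier).
# An observation with an observed event at time t is definitely earlier than
# anything at a strictly later time, and earlier than a censoring tied at t
# (events precede censorings at tied times).
gehan_scores <- function(time, event) {
  N <- length(time)
  ti <- matrix(time, N, N)
  tj <- t(ti)
  ei <- matrix(event, N, N)
  ej <- t(ei)
  before <- ei & (ti < tj | (ti == tj & !ej))
  rowSums(before) - colSums(before)
}

#' Stratify a cohort by a CTC-burden rule
#'
#' Restricts the cohort to patients with `treatment_line >= line_filter`,
#' then splits it by the rule: positive stratum = patients whose count of
#' the rule's CTC type reaches `min_count` and, if the rule is exclusive,
#' who have no cell of any other CTC type detectable.
#'
#' @param counts Per-patient CTC counts ([patient_ctc_counts()]).
#' @param clinical Clinical table.
#' @param ctc_type One of `"emt"`, `"epithelial"`, `"epithelial_or_emt"`.
#' @param min_count Count threshold (>= 1).
#' @param exclusive If `TRUE`, positives must have only that CTC type.
#' @param line_filter Minimum treatment line (default 2).
#' @return List `positive`, `negative`: character vectors of patient IDs.
#' @export
stratify <- function(counts, clinical,
                     ctc_type = c("emt", "epithelial", "epithelial_or_emt"),
                     min_count = 2L, exclusive = FALSE, line_filter = 2L) {
  ctc_type <- match.arg(ctc_type)
  stopifnot(min_count >= 1)
  unknown <- setdiff(counts$patient_id, clinical$patient_id)
  if (length(unknown))
    stop("counts reference unknown patient(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cohort <- clinical[clinical$treatment_line >= line_filter, , drop = FALSE]
  cc <- counts[match(cohort$patient_id, counts$patient_id), , drop = FALSE]
  cc[is.na(cc$total_ctc_count),
     c("epithelial_ctc_count", "emt_ctc_count", "total_ctc_count")] <- 0L
  type_count <- switch(ctc_type,
    emt = cc$emt_ctc_count,
    epithelial = cc$epithelial_ctc_count,
    epithelial_or_emt = pmax(cc$emt_ctc_count, cc$epithelial_ctc_count))
  other_count <- switch(ctc_type,
    emt = cc$epithelial_ctc_count,
    epithelial = cc$emt_ctc_count,
    epithelial_or_emt = 0L)
  pos <- type_count >= min_count
  if (exclusive) pos <- pos & other_count == 0
  list(positive = cohort$patient_id[pos],
       negative = cohort$patient_id[!pos])
}

#' Survival stratification report
#'
#' For each stratification rule, estimates per-stratum Kaplan-Meier medians
#' with confidence intervals and tests the strata with the Gehan
#' generalized Wilcoxon test, for both PFS and OS. Rules whose strata are
#' degenerate (an empty stratum, or no usable times) are emitted with the
#' test marked not computable (`p_value = NA`).
#'
#' @param counts Per-patient CTC counts ([patient_ctc_counts()]).
#' @param clinical Clinical table.
#' @param rules Data frame with columns `ctc_type`, `min_count`,
#'   `exclusive`; default mirrors the six standard rules (each type at
#'   thresholds 1 and 2, the EMT rules exclusive).
#' @param line_filter Minimum treatment line (default 2).
#' @param variant Test variant passed to [gehan_wilcoxon_test()].
#' @return Data frame with one row per rule x stratum x endpoint:
#'   `ctc_type`, `min_count`, `exclusive`, `endpoint`, `stratum`, `n`,
#'   `n_events`, `median`, `ci_low`, `ci_high`, `p_value` (the p-value is
#'   repeated on both stratum rows of a rule).
#' @export
survival_report <- function(counts, clinical, rules = default_rules(),
                            line_filter = 2L, variant = "gehan") {
  out <- list()
  for (r in seq_len(nrow(rules))) {
    rule <- rules[r, ]
    strata <- stratify(counts, clinical, rule$ctc_type, rule$min_count,
                       rule$exclusive, line_filter)
    for (endpoint in c("pfs", "os")) {
      tcol <- paste0(endpoint, "_days")
      ecol <- paste0(endpoint, "_event")
      grab <- function(pids) {
        cl <- clinical[match(pids, clinical$patient_id), , drop = FALSE]
        ok <- !is.na(cl[[tcol]])
        list(time = cl[[tcol]][ok], event = cl[[ecol]][ok])
      }
      pos <- grab(strata$positive)
      neg <- grab(strata$negative)
      p <- NA_real_
      if (length(pos$time) > 0 && length(neg$time) > 0) {
        p <- gehan_wilcoxon_test(pos$time, pos$event, neg$time, neg$event,
                                 variant)$p_value
      }
      row_for <- function(stratum, d) {
        km <- if (length(d$time)) km_estimate(d$time, d$event) else NULL
        data.frame(ctc_type = rule$ctc_type, min_count = rule$min_count,
                   exclusive = rule$exclusive, endpoint = endpoint,
                   stratum = stratum, n = length(d$time),
                   n_events = if (is.null(km)) 0L else km$n_events,
                   median = if (is.null(km)) NA_real_ else km$median,
                   ci_low = if (is.null(km)) NA_real_ else km$ci_low,
                   ci_high = if (is.null(km)) NA_real_ else km$ci_high,
                   p_value = p, stringsAsFactors = FALSE)
      }
      out[[length(out) + 1]] <- rbind(row_for("positive", pos),
                                      row_for("negative", neg))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default survival stratification rules
#'
#' The six standard rules: EMT, epithelial, and combined CTC presence at
#' count thresholds 1 and 2. The EMT rules are exclusive (positives must
#' have only EMT CTCs detectable).
#'
#' @return Data frame `ctc_type`, `min_count`, `exclusive`.
#' @export
default_rules <- function() {
  data.frame(
    ctc_type = rep(c("emt", "epithelial", "epithelial_or_emt"), each = 2),
    min_count = rep(c(1L, 2L), 3),
    exclusive = rep(c(TRUE, FALSE, FALSE), each = 2),
    stringsAsFactors = FALSE
  )
}
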