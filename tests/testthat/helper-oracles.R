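# Independent brute-force oracles used to validate the statistical routines.
# These are deliberately naive implementations kept separate from the package.

# tiny expression matrix builder: genes x cells from a named list of columns
tiny_expr <- function(cols, patient_id = NULL, unique_reads = 1e6,
                      is_cluster = FALSE) {
  values <- do.call(cbind, cols)
  colnames(values) <- names(cols)
  n <- length(cols)
  if (is.null(patient_id)) patient_id <- rep("P1", n)
  expression_matrix(values, data.frame(
    cell_id = names(cols),
    patient_id = patient_id,
    unique_reads = rep_len(unique_reads, n),
    is_cluster = rep_len(is_cluster, n)))
}

# Pearson chi-square by direct summation
chisq_oracle <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

# Fisher 2x2 two-sided p by exhaustive enumeration with fixed margins,
# table probabilities from products of binomial coefficients
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  prob_of <- function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- vapply(support, prob_of, numeric(1))
  p_obs <- prob_of(tab[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exhaustive two-sided permutation p for the Mann-Whitney U statistic
mw_perm_oracle <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  splits <- utils::combn(length(pool), n1)
  u_perm <- apply(splits, 2, function(idx) u_of(pool[idx], pool[-idx]))
  mu <- n1 * (length(pool) - n1) / 2
  mean(abs(u_perm - mu) >= abs(u_obs - mu) - 1e-9)
}

# Gehan scores by explicit double loop (independent of the package's
# vectorized computation), events before censorings at tied times
gehan_scores_oracle <- function(time, event) {
  N <- length(time)
  u <- numeric(N)
  for (i in seq_len(N)) {
    later <- 0; earlier <- 0
    for (j in seq_len(N)) {
      if (j == i) next
      if (event[i] && (time[i] < time[j] ||
                       (time[i] == time[j] && !event[j]))) later <- later + 1
      if (event[j] && (time[j] < time[i] ||
                       (time[j] == time[i] && !event[i]))) earlier <- earlier + 1
    }
    u[i] <- later - earlier
  }
  u
}

# Exhaustive permutation two-sided p for the Gehan statistic
gehan_perm_oracle <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b); event <- c(event_a, event_b)
  u <- gehan_scores_oracle(time, event)
  n1 <- length(time_a)
  w_obs <- sum(u[seq_len(n1)])
  splits <- utils::combn(length(time), n1)
  w_perm <- apply(splits, 2, function(idx) sum(u[idx]))
  mean(abs(w_perm) >= abs(w_obs) - 1e-9)
}

# hand product-limit estimator at event times
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event]))
  s <- 1
  surv <- numeric(length(ts))
  for (k in seq_along(ts)) {
    at_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  list(time = ts, surv = surv)
}

# the published 3x4 cross-classification counts used across tests
table1_counts <- function() {
  matrix(c(7L, 0L, 1L, 0L,
           0L, 0L, 7L, 3L,
           0L, 9L, 4L, 28L),
         nrow = 3, byrow = TRUE,
         dimnames = list(
           epithelial = c("High", "Middle", "Low"),
           emt_stem = c("HighStem_LowEMT", "LowStem_MiddleEMT",
                        "LowStem_LowEMT", "LowStem_HighEMT")))
}
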