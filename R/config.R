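#' Default pipeline configuration
#'
#' Every tunable threshold of the pipeline in one declarative list. Values
#' can be overridden individually via [read_config()] or by passing a
#' modified list to [run_pipeline()].
#'
#' \describe{
#'   \item{min_reads}{Read-count QC floor; a cell passes when its uniquely
#'     mapped read count is strictly greater. Default 100000.}
#'   \item{reported_reads_tier}{Secondary, reported-only read threshold
#'     (default 400000); does not gate retention.}
#'   \item{positivity_tpm}{TPM at or above which a marker gene is called
#'     positive (contaminant calls and CTC-type detection). Default 1.}
#'   \item{score_method}{Panel score aggregation: `"sum"` (default) or
#'     `"mean"` of log10(TPM+1) over panel genes.}
#'   \item{k_epithelial, k_emt_stem}{Cluster counts for the two marker-space
#'     clusterings (3 and 4).}
#'   \item{line_filter}{Minimum treatment line for the survival cohort
#'     (default 2: second- or later-line).}
#'   \item{min_ctc_count}{CTC-count threshold for survival stratification
#'     (default 2).}
#'   \item{gehan_variant}{`"gehan"` (default) or `"peto"` for the censored
#'     two-sample test.}
#'   \item{seed}{Seed recorded in the report; all pipeline randomness (none
#'     in the deterministic stages) and any simulation flows through it.}
#' }
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    min_reads = 100000L,
    reported_reads_tier = 400000L,
    positivity_tpm = 1.0,
    score_method = "sum",
    k_epithelial = 3L,
    k_emt_stem = 4L,
    line_filter = 2L,
    min_ctc_count = 2L,
    exclusive_emt_rule = TRUE,
    gehan_variant = "gehan",
    seed = 1L
  )
}

#' Read a YAML configuration, merged over the defaults
#' @param path YAML file; keys as in [default_config()]. Missing keys take
#'   their default values; unknown keys are rejected.
#' @return Full configuration list.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(user)] <- user
  cfg
}
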