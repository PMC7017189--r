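#' Run the full analysis pipeline on a cohort directory
#'
#' Convenience wrapper chaining the per-modality callers and the
#' integration layer: segment-mean copy-number calls, array beta-value
#' promoter methylation calls, paired RRBS change calls, normal-median
#' expression categorization, the integrated per-tumour state table with the
#' ESRP1-amplified/FGFR2-normal/IIIc-high axis flag, and (when survival
#' fields are present) the diffuse-histotype IIIc log-rank contrast.
#'
#' @param seg_file,manifest_file,beta_file,rrbs_file,expr_file,clinical_file
#'   Paths to the modality TSVs (formats of the module readers). `rrbs_file`
#'   may be `NULL`. A [simulate_cohort()] result can be passed as the first
#'   argument instead, supplying all paths.
#' @param cutoff Segment-mean cutoff (default 0.1).
#' @param normal_samples Normal sample ids used to derive expression
#'   thresholds; ignored when `thresholds` is given.
#' @param thresholds Optional named per-feature expression thresholds.
#' @param join Join mode for [assemble_cohort()].
#'
#' @return List with `cn_calls`, `methylation_calls`, `rrbs_calls`,
#'   `expression_categories`, `states`, and `survival` (log-rank result among
#'   diffuse tumours split by IIIc category, or `NULL` when not computable).
#' @export
run_pipeline <- function(seg_file, manifest_file = NULL, beta_file = NULL,
                         rrbs_file = NULL, expr_file = NULL,
                         clinical_file = NULL, cutoff = 0.1,
                         normal_samples = NULL, thresholds = NULL,
                         join = "inner") {
  if (inherits(seg_file, "synthetic_cohort")) {
    cohort <- seg_file
    manifest_file <- cohort$manifest_file
    beta_file <- cohort$beta_matrix
    rrbs_file <- cohort$rrbs_counts
    expr_file <- cohort$expression_file
    clinical_file <- cohort$clinical_file
    seg_file <- cohort$segment_file
    if (is.null(normal_samples) && is.null(thresholds))
      normal_samples <- cohort$truth$sample_id[cohort$truth$type == "normal"]
  }
  cn <- call_cn_from_seg(read_seg(seg_file), cutoff = cutoff)
  meth <- call_methylation_from_betas(read_beta_matrix(beta_file),
                                      read_manifest(manifest_file))
  rrbs <- if (!is.null(rrbs_file)) {
    r <- read_rrbs(rrbs_file)
    if (nrow(r) > 0) call_methylation_from_rrbs(r) else NULL
  } else NULL
  expr <- read_expression(expr_file)
  cats <- categorize_cohort_expression(expr, normal_samples = normal_samples,
                                       thresholds = thresholds)
  clinical <- utils::read.delim(clinical_file, stringsAsFactors = FALSE)
  states <- assemble_cohort(cn_calls = cn, methylation_calls = meth,
                            expression_categories = cats,
                            clinical = clinical, join = join)
  surv <- NULL
  if (all(c("lauren", "vital_status") %in% names(states))) {
    d <- states[!is.na(states$lauren) & states$lauren == "diffuse" &
                  states$iiic_cat %in% c("above", "below"), , drop = FALSE]
    if (nrow(d) > 1 && length(unique(d$iiic_cat)) == 2L) {
      time <- ifelse(d$vital_status == "dead", d$days_to_death,
                     d$days_to_last_follow_up)
      event <- as.integer(d$vital_status == "dead")
      if (sum(event) > 0)
        surv <- logrank(time, event, d$iiic_cat)
    }
  }
  list(cn_calls = cn, methylation_calls = meth, rrbs_calls = rrbs,
       expression_categories = cats, states = states, survival = surv)
}
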