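#' Exon-surrogate map for the FGFR2 splice isoforms
#'
#' The two mutually exclusive FGFR2 isoforms are quantified through their
#' isoform-specific exons: IIIb is exon 8 of transcript NM_022970 and IIIc is
#' exon 6 of transcript NM_001144916. The closest upstream and downstream
#' exons on the same transcript (shared between isoforms) serve as controls.
#'
#' @return Named list mapping feature names to `(transcript, exon)` pairs.
#' @export
exon_surrogate_map <- function() {
  list(
    iiib = list(transcript = "NM_022970", exon = 8L),
    iiic = list(transcript = "NM_001144916", exon = 6L),
    upstream = list(transcript = "NM_022970", exon = 7L),
    downstream = list(transcript = "NM_022970", exon = 9L))
}

#' Median of normal-sample expression values
#'
#' The normal-sample median is the threshold used to dichotomize tumour
#' expression when too few paired normals exist for direct comparison. For
#' reference, the published normal-stomach medians are IIIb 2.89, IIIc 1.53
#' and ESRP1 13.26 (RPKM/FPKM); recomputing them requires the original
#' cohort, so they are carried as documented constants, not recomputed.
#'
#' @param normal_values Non-empty numeric vector (non-negative expression).
#' @return Sample median (even n: mean of the two central order statistics).
#' @export
normal_median_threshold <- function(normal_values) {
  if (length(normal_values) == 0L)
    stop("normal expression collection must be non-empty", call. = FALSE)
  if (!is.numeric(normal_values) || any(!is.finite(normal_values)))
    stop("normal expression values must be finite numbers", call. = FALSE)
  stats::median(normal_values)
}

#' Published normal-stomach median thresholds
#'
#' @return Named numeric vector (`iiib`, `iiic`, `esrp1`), RPKM/FPKM units.
#' @export
published_normal_medians <- function() {
  c(iiib = 2.89, iiic = 1.53, esrp1 = 13.26)
}

#' Dichotomize an expression value against a threshold
#'
#' Strictly greater than the threshold is `"above"`; a tie at the threshold
#' is `"below"` ("above" means exceedance).
#'
#' @param value Non-negative expression; vectorised.
#' @param threshold Threshold (normal-sample median).
#' @param ties Category for a value equal to the threshold (default
#'   `"below"`).
#' @return Character vector in `{"above", "below"}`.
#' @export
categorize_expression <- function(value, threshold, ties = c("below", "above")) {
  ties <- match.arg(ties)
  if (!is.numeric(value) || any(!is.finite(value)) ||
      !is.numeric(threshold) || !is.finite(threshold))
    stop("value and threshold must be finite numbers", call. = FALSE)
  out <- ifelse(value > threshold, "above", "below")
  if (ties == "above") out[value == threshold] <- "above"
  out
}

#' Tumour/normal expression ratio category
#'
#' A T/N ratio equal or above 1.50 is `"up"`, strictly below 0.67 `"down"`,
#' and anything in `[0.67, 1.50)` is `"unchanged"`. Note the deliberate
#' asymmetry with the RRBS rule (0.67 here versus 0.66 there); each printed
#' rule is preserved per modality.
#'
#' @param tumor,normal Positive expression values; vectorised.
#' @return Character vector in `{"up", "down", "unchanged"}`.
#' @export
tn_ratio_category <- function(tumor, normal) {
  if (!is.numeric(tumor) || !is.numeric(normal) ||
      any(!is.finite(tumor)) || any(!is.finite(normal)) ||
      any(tumor <= 0) || any(normal <= 0))
    stop("tumor and normal expression must be positive finite numbers",
         call. = FALSE)
  ratio <- tumor / normal
  out <- rep("unchanged", length(ratio))
  out[ratio >= 1.50] <- "up"
  out[ratio < 0.67] <- "down"
  out
}

#' qRT-PCR relative quantification (2^-ddCt)
#'
#' Textbook comparative-Ct quantification: `ddCt = (Ct_target -
#' Ct_housekeeping) - (ref Ct_target - ref Ct_housekeeping)` and `RQ =
#' 2^-ddCt`, with an 18S-type housekeeping assay as the normalizer.
#'
#' @param ct_target,ct_housekeeping Sample Ct values.
#' @param ref_ct_target,ref_ct_housekeeping Reference-sample Ct values.
#' @return Positive relative quantity; `NA` propagated for missing Cts.
#' @export
relative_quantification <- function(ct_target, ct_housekeeping,
                                    ref_ct_target, ref_ct_housekeeping) {
  ddct <- (ct_target - ct_housekeeping) - (ref_ct_target - ref_ct_housekeeping)
  2^(-ddct)
}

#' Read a feature-by-sample expression table
#'
#' Feature keys are `gene:<symbol>` for gene-level FPKM and
#' `exon:<transcript>:<index>` for exon-level RPKM.
#'
#' @param path TSV with a `feature` column followed by one column per sample.
#' @return `data.frame` with `feature` first.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"feature" %in% names(d))
    stop("expression table must have a 'feature' column", call. = FALSE)
  d
}

#' Extract the isoform-surrogate and gene-level features for one sample
#'
#' @param expression `data.frame` from [read_expression()].
#' @param sample_id Sample column to extract.
#' @param map Exon-surrogate map (default [exon_surrogate_map()]).
#'
#' @return Named numeric vector with entries `iiib`, `iiic`, `upstream`,
#'   `downstream` (exon RPKM) and `fgfr2`, `esrp1` (gene FPKM).
#' @export
extract_surrogates <- function(expression, sample_id,
                               map = exon_surrogate_map()) {
  if (!sample_id %in% names(expression))
    stop("sample not present in expression table: ", sample_id, call. = FALSE)
  keys <- c(vapply(map, function(m)
    sprintf("exon:%s:%d", m$transcript, m$exon), character(1)),
    fgfr2 = "gene:FGFR2", esrp1 = "gene:ESRP1")
  idx <- match(keys, expression$feature)
  if (anyNA(idx))
    stop("missing expression feature(s): ",
         paste(keys[is.na(idx)], collapse = ", "), call. = FALSE)
  vals <- as.numeric(expression[[sample_id]][idx])
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("expression values must be finite and non-negative", call. = FALSE)
  stats::setNames(vals, names(keys))
}

#' Categorize tumour expression against normal-sample medians
#'
#' Computes the normal-median threshold per feature from the listed normal
#' samples (or uses supplied thresholds) and dichotomizes each tumour sample
#' as above/below per feature.
#'
#' @param expression `data.frame` from [read_expression()].
#' @param normal_samples Character vector of normal sample columns (used to
#'   derive thresholds); ignored when `thresholds` is supplied.
#' @param tumor_samples Tumour sample columns; default every non-feature
#'   column not in `normal_samples`.
#' @param features Feature names from [extract_surrogates()] to categorize
#'   (default `iiib`, `iiic`, `esrp1`, `upstream`, `downstream`).
#' @param thresholds Optional named numeric vector of per-feature thresholds.
#'
#' @return `data.frame` with `sample_id`, `feature`, `value`, `threshold`,
#'   `category`.
#' @export
categorize_cohort_expression <- function(expression, normal_samples = NULL,
                                         tumor_samples = NULL,
                                         features = c("iiib", "iiic", "esrp1",
                                                      "upstream", "downstream"),
                                         thresholds = NULL) {
  all_samples <- setdiff(names(expression), "feature")
  if (is.null(tumor_samples))
    tumor_samples <- setdiff(all_samples, normal_samples)
  prof <- vapply(c(normal_samples, tumor_samples),
                 function(s) extract_surrogates(expression, s),
                 numeric(6))
  if (is.null(thresholds)) {
    if (length(normal_samples) == 0L)
      stop("either normal_samples or thresholds must be supplied",
           call. = FALSE)
    thresholds <- apply(prof[features, normal_samples, drop = FALSE], 1,
                        normal_median_threshold)
  }
  miss <- setdiff(features, names(thresholds))
  if (length(miss))
    stop("no threshold for feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- expand.grid(sample_id = tumor_samples, feature = features,
                     stringsAsFactors = FALSE)
  out$value <- mapply(function(s, f) prof[f, s], out$sample_id, out$feature)
  out$threshold <- thresholds[out$feature]
  out$category <- mapply(function(v, th) categorize_expression(v, th),
                         out$value, out$threshold)
  rownames(out) <- NULL
  out
}

#' Read a qRT-PCR Ct table
#'
#' @param path TSV with header `sample_id`, `target_ct`, `housekeeping_ct`,
#'   `is_reference` (logical; at least one reference sample).
#' @return `data.frame`.
#' @export
read_qpcr <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "target_ct", "housekeeping_ct", "is_reference")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("qPCR table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d$is_reference <- as.logical(d$is_reference)
  d
}

#' Relative quantification for every sample of a qPCR table
#'
#' Applies the comparative-Ct model against the mean Ct values of the
#' reference sample(s); missing Cts propagate to `NA`.
#'
#' @param qpcr `data.frame` from [read_qpcr()].
#' @return Input with an `rq` column appended.
#' @export
qpcr_rq_table <- function(qpcr) {
  ref <- qpcr[qpcr$is_reference %in% TRUE, , drop = FALSE]
  if (nrow(ref) == 0L)
    stop("qPCR table has no reference sample", call. = FALSE)
  qpcr$rq <- relative_quantification(qpcr$target_ct, qpcr$housekeeping_ct,
                                     mean(ref$target_ct),
                                     mean(ref$housekeeping_ct))
  qpcr
}
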