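#' Flag the ESRP1-amplified / FGFR2-normal / FGFR2-IIIc-high axis
#'
#' The axis is true exactly when ESRP1 copy number is amplified, FGFR2 copy
#' number is normal, and the FGFR2-IIIc surrogate exon is above the
#' normal-median threshold. If any constituent is missing the flag is `NA`.
#'
#' @param esrp1_cn,fgfr2_cn Copy-number categories
#'   (`"amplified"/"normal"/"deleted"`, or `"missing"`/`NA`); vectorised.
#' @param iiic_cat IIIc expression category (`"above"/"below"`, or
#'   `"missing"`/`NA`).
#' @return Logical vector (`NA` on missing constituents).
#' @export
assign_axis <- function(esrp1_cn, fgfr2_cn, iiic_cat) {
  norm <- function(x) {
    x <- as.character(x)
    x[x %in% c("missing", "discordant")] <- NA_character_
    x
  }
  e <- norm(esrp1_cn); f <- norm(fgfr2_cn); i <- norm(iiic_cat)
  ifelse(is.na(e) | is.na(f) | is.na(i), NA,
         e == "amplified" & f == "normal" & i == "above")
}

#' Join per-sample CN, methylation and expression calls with clinical data
#'
#' Builds one integrated state per tumour sample. Discordant copy-number
#' calls are kept in the table but mapped to `"missing"` (they are excluded
#' wherever a CN category is required). With `join = "inner"` only samples
#' present in every supplied modality are kept; with `"outer"` samples
#' missing a modality carry `"missing"` in its fields.
#'
#' @param cn_calls `data.frame` with `sample_id`, `gene`, `status` (from
#'   [call_cn_from_seg()] or [call_cn_from_gistic()]), or `NULL`.
#' @param methylation_calls `data.frame` with `sample_id`, `gene`, `status`
#'   (from [call_methylation_from_betas()]), or `NULL`.
#' @param expression_categories `data.frame` with `sample_id`, `feature`,
#'   `category` (from [categorize_cohort_expression()]), or `NULL`.
#' @param clinical `data.frame` with a `sample_id` column, or `NULL`.
#' @param join `"inner"` or `"outer"`.
#'
#' @return `data.frame` with one row per sample: `sample_id`, `fgfr2_cn`,
#'   `esrp1_cn`, `fgfr2_meth`, `esrp1_meth`, `iiib_cat`, `iiic_cat`,
#'   `esrp1_expr_cat`, `axis_flag`, plus any clinical columns.
#' @export
assemble_cohort <- function(cn_calls = NULL, methylation_calls = NULL,
                            expression_categories = NULL, clinical = NULL,
                            join = c("inner", "outer")) {
  join <- match.arg(join)

  wide_status <- function(d, value_col, key_col, prefix, keys) {
    for (k in keys) {
      dk <- d[d[[key_col]] == k, , drop = FALSE]
      if (anyDuplicated(dk$sample_id))
        stop(sprintf("duplicate sample in modality '%s' for key '%s'",
                     prefix, k), call. = FALSE)
    }
    out <- data.frame(sample_id = unique(d$sample_id),
                      stringsAsFactors = FALSE)
    for (k in keys) {
      dk <- d[d[[key_col]] == k, , drop = FALSE]
      out[[paste0(prefix, "_", k)]] <-
        dk[[value_col]][match(out$sample_id, dk$sample_id)]
    }
    out
  }

  pieces <- list()
  if (!is.null(cn_calls)) {
    cn <- cn_calls
    cn$status[cn$status %in% c("discordant", "missing")] <- "missing"
    w <- wide_status(cn, "status", "gene", "cn", c("FGFR2", "ESRP1"))
    names(w) <- c("sample_id", "fgfr2_cn", "esrp1_cn")
    pieces$cn <- w
  }
  if (!is.null(methylation_calls)) {
    w <- wide_status(methylation_calls, "status", "gene", "meth",
                     c("FGFR2", "ESRP1"))
    names(w) <- c("sample_id", "fgfr2_meth", "esrp1_meth")
    pieces$meth <- w
  }
  if (!is.null(expression_categories)) {
    w <- wide_status(expression_categories, "category", "feature", "expr",
                     c("iiib", "iiic", "esrp1"))
    names(w) <- c("sample_id", "iiib_cat", "iiic_cat", "esrp1_expr_cat")
    pieces$expr <- w
  }
  if (length(pieces) == 0L)
    stop("at least one modality must be supplied", call. = FALSE)

  ids <- lapply(pieces, function(p) p$sample_id)
  samples <- if (join == "inner") Reduce(intersect, ids) else
    sort(unique(unlist(ids)))
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (p in pieces)
    out <- merge(out, p, by = "sample_id", all.x = TRUE, sort = FALSE)

  state_cols <- c("fgfr2_cn", "esrp1_cn", "fgfr2_meth", "esrp1_meth",
                  "iiib_cat", "iiic_cat", "esrp1_expr_cat")
  for (col in state_cols) {
    if (!col %in% names(out)) out[[col]] <- "missing"
    out[[col]][is.na(out[[col]])] <- "missing"
  }
  out$axis_flag <- assign_axis(out$esrp1_cn, out$fgfr2_cn, out$iiic_cat)

  if (!is.null(clinical)) {
    if (anyDuplicated(clinical$sample_id))
      stop("duplicate sample in clinical table", call. = FALSE)
    out <- merge(out, clinical, by = "sample_id", all.x = TRUE, sort = FALSE)
  }
  out <- out[order(out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Frequency table of integrated-state combinations
#'
#' Counts and proportions of each combination of the requested state fields,
#' computed among the samples non-missing on all of them.
#'
#' @param states `data.frame` from [assemble_cohort()].
#' @param keys Character vector of state column names.
#' @return `data.frame` with the key columns, `count`, `proportion`, and a
#'   `denominator` attribute (number of complete samples).
#' @export
state_frequencies <- function(states, keys) {
  miss <- setdiff(keys, names(states))
  if (length(miss))
    stop("unknown state field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sub <- states[, keys, drop = FALSE]
  complete <- rowSums(is.na(sub) | sub == "missing") == 0L
  sub <- sub[complete, , drop = FALSE]
  denom <- nrow(sub)
  if (denom == 0L) {
    out <- cbind(sub, count = integer(0), proportion = numeric(0))
    attr(out, "denominator") <- 0L
    return(out)
  }
  agg <- stats::aggregate(list(count = rep(1L, denom)),
                          by = lapply(sub, identity), FUN = sum)
  names(agg)[seq_along(keys)] <- keys
  agg <- agg[do.call(order, agg[keys]), , drop = FALSE]
  agg$proportion <- agg$count / denom
  attr(agg, "denominator") <- denom
  rownames(agg) <- NULL
  agg
}
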