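#' Classify a segment-mean value into a copy-number category
#'
#' A segment mean above the cutoff is called amplified, below the negative
#' cutoff deleted, and anything in the closed interval `[-cutoff, cutoff]`
#' (boundaries included) is normal copy number. The pipeline default cutoff
#' is 0.1, the value that separates normal mucosa from tumour segment means
#' at the FGFR2 and ESRP1 loci.
#'
#' @param value Segment mean (log2-ratio-like), finite numeric; vectorised.
#' @param cutoff Positive cutoff (default 0.1).
#'
#' @return Character vector in `{"amplified", "normal", "deleted"}`.
#' @export
classify_segment_mean <- function(value, cutoff = 0.1) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff) ||
      cutoff <= 0)
    stop("cutoff must be a single positive finite number", call. = FALSE)
  if (!is.numeric(value) || any(!is.finite(value)))
    stop("segment mean values must be finite numbers", call. = FALSE)
  out <- rep("normal", length(value))
  out[value > cutoff] <- "amplified"
  out[value < -cutoff] <- "deleted"
  out
}

#' Classify a gene-level GISTIC call
#'
#' GISTIC 2.0 gene-level values equal or above 1 are amplified, equal or
#' below -1 deleted, and 0 is normal copy number.
#'
#' @param value Integer call(s), expected in `{-2,-1,0,1,2}`; vectorised.
#' @param mode `"strict"` errors on non-integer or out-of-range input;
#'   `"lenient"` rounds to the nearest integer, clamps to the valid range and
#'   emits a warning.
#'
#' @return Character vector in `{"amplified", "normal", "deleted"}`.
#' @export
classify_gistic <- function(value, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (!is.numeric(value) || any(!is.finite(value)))
    stop("GISTIC values must be finite numbers", call. = FALSE)
  bad <- value != round(value) | value < -2 | value > 2
  if (any(bad)) {
    if (mode == "strict")
      stop(sprintf("GISTIC values outside {-2,...,2}: %s",
                   paste(utils::head(value[bad], 5), collapse = ", ")),
           call. = FALSE)
    warning(sprintf("%d GISTIC value(s) coerced to nearest in-range integer",
                    sum(bad)), call. = FALSE)
    value <- pmin(2, pmax(-2, round(value)))
  }
  out <- rep("normal", length(value))
  out[value >= 1] <- "amplified"
  out[value <= -1] <- "deleted"
  out
}

#' Derive a segment-mean cutoff separating normals from tumours
#'
#' Scans a candidate grid (default 0.01 to 0.50 in steps of 0.01) and returns
#' the smallest candidate `c` such that the `quantile` quantile of the
#' absolute normal segment means is strictly below `c`. If no candidate
#' satisfies the criterion the grid maximum is returned with a warning.
#' When derivation is skipped the pipeline default is 0.1.
#'
#' @param normal_values,tumor_values Non-empty numeric vectors of segment
#'   means. `tumor_values` is accepted for symmetry with the derivation on
#'   both distributions; only the normal distribution constrains the cutoff.
#' @param grid Candidate cutoffs, positive increasing.
#' @param quantile Target quantile of `|normal_values|` (default 0.99).
#'
#' @return A single positive cutoff.
#' @export
derive_segmean_cutoff <- function(normal_values, tumor_values,
                                  grid = seq(0.01, 0.50, by = 0.01),
                                  quantile = 0.99) {
  if (length(normal_values) == 0L || length(tumor_values) == 0L)
    stop("normal and tumor segment-mean collections must be non-empty",
         call. = FALSE)
  q <- stats::quantile(abs(normal_values), probs = quantile, names = FALSE,
                       type = 7)
  ok <- grid[q < grid]
  if (length(ok) == 0L) {
    warning("no grid candidate exceeds the normal quantile; returning grid maximum",
            call. = FALSE)
    return(max(grid))
  }
  min(ok)
}

#' Call gene-level copy-number status from overlapping segments
#'
#' Selects the segments of one sample that overlap the gene locus (1-based
#' inclusive overlap on the locus chromosome), classifies each segment mean,
#' and returns the common category when all overlapping segments agree.
#' Disagreeing segments yield status `"discordant"`, which downstream joins
#' exclude; this mirrors the rule that only samples with concordant probes
#' over the locus are considered.
#'
#' @param segments `data.frame` with columns `sample_id`, `chromosome`,
#'   `start`, `end`, `segment_mean` (a `num_probes` column is carried if
#'   present), all rows from one sample.
#' @param locus A [gene_locus()].
#' @param cutoff Segment-mean cutoff (default 0.1).
#'
#' @return One-row `data.frame`: `sample_id`, `gene`, `status`, `source`,
#'   `n_segments`, `evidence` (semicolon-joined segment means).
#' @export
call_gene_cn <- function(segments, locus, cutoff = 0.1) {
  stopifnot(inherits(locus, "gene_locus"), is.data.frame(segments))
  need <- c("sample_id", "chromosome", "start", "end", "segment_mean")
  miss <- setdiff(need, names(segments))
  if (length(miss))
    stop("segments missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sid <- unique(segments$sample_id)
  if (length(sid) != 1L)
    stop("call_gene_cn expects segments from exactly one sample", call. = FALSE)
  ov <- segments$chromosome == locus$chromosome &
    segments$start <= locus$end & segments$end >= locus$start
  if (!any(ov))
    stop(sprintf("no segment covers gene %s for sample %s", locus$name, sid),
         call. = FALSE)
  means <- segments$segment_mean[ov]
  cats <- classify_segment_mean(means, cutoff)
  status <- if (length(unique(cats)) == 1L) cats[[1L]] else "discordant"
  data.frame(sample_id = sid, gene = locus$name, status = status,
             source = "segment_mean", n_segments = sum(ov),
             evidence = paste(format(means, trim = TRUE), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Read a SEG-like segment file
#'
#' Tab-separated with header columns `Sample`, `Chromosome`, `Start`, `End`,
#' `Num_Probes`, `Segment_Mean` (GDC masked-seg dialect, 1-based inclusive
#' coordinates).
#'
#' @param path File path.
#' @return `data.frame` with columns `sample_id`, `chromosome`, `start`,
#'   `end`, `num_probes`, `segment_mean`.
#' @export
read_seg <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Sample", "Chromosome", "Start", "End", "Segment_Mean")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("SEG file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  data.frame(sample_id = as.character(d$Sample),
             chromosome = as.character(d$Chromosome),
             start = as.numeric(d$Start), end = as.numeric(d$End),
             num_probes = if ("Num_Probes" %in% names(d))
               as.numeric(d$Num_Probes) else NA_real_,
             segment_mean = as.numeric(d$Segment_Mean),
             stringsAsFactors = FALSE)
}

#' Read a gene-by-sample GISTIC integer call table
#'
#' @param path TSV with a `Gene` column followed by one integer column per
#'   sample.
#' @return `data.frame`, genes as rows, `Gene` column first.
#' @export
read_gistic <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"Gene" %in% names(d))
    stop("GISTIC table must have a 'Gene' column", call. = FALSE)
  d
}

#' Call copy-number status for every sample in a segment file
#'
#' @param segments `data.frame` as returned by [read_seg()].
#' @param loci List of [gene_locus()] (default [builtin_loci()]).
#' @param cutoff Segment-mean cutoff.
#' @param on_missing `"na"` records samples without locus coverage with
#'   status `"missing"`; `"error"` stops.
#'
#' @return `data.frame` of per-sample per-gene calls (see [call_gene_cn()]).
#' @export
call_cn_from_seg <- function(segments, loci = builtin_loci(), cutoff = 0.1,
                             on_missing = c("na", "error")) {
  on_missing <- match.arg(on_missing)
  out <- list()
  for (sid in unique(segments$sample_id)) {
    seg_s <- segments[segments$sample_id == sid, , drop = FALSE]
    for (locus in loci) {
      row <- tryCatch(call_gene_cn(seg_s, locus, cutoff), error = function(e) e)
      if (inherits(row, "error")) {
        if (on_missing == "error") stop(row)
        row <- data.frame(sample_id = sid, gene = locus$name,
                          status = "missing", source = "segment_mean",
                          n_segments = 0L, evidence = "",
                          stringsAsFactors = FALSE)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Call copy-number status from a GISTIC gene-level table
#'
#' @param gistic `data.frame` from [read_gistic()].
#' @param genes Genes to call (default the built-in two).
#' @param mode Passed to [classify_gistic()].
#'
#' @return `data.frame` with `sample_id`, `gene`, `status`, `source`,
#'   `evidence`.
#' @export
call_cn_from_gistic <- function(gistic, genes = c("FGFR2", "ESRP1"),
                                mode = "strict") {
  miss <- setdiff(genes, gistic$Gene)
  if (length(miss))
    stop("genes absent from GISTIC table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  samples <- setdiff(names(gistic), "Gene")
  out <- list()
  for (g in genes) {
    vals <- as.numeric(gistic[gistic$Gene == g, samples])
    out[[g]] <- data.frame(sample_id = samples, gene = g,
                           status = classify_gistic(vals, mode),
                           source = "gistic",
                           evidence = as.character(vals),
                           stringsAsFactors = FALSE)
  }
  ans <- do.call(rbind, out)
  rownames(ans) <- NULL
  ans
}
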