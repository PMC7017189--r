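#' Classify an average promoter beta-value
#'
#' Average beta-values run from 0 (fully demethylated) to 1 (fully
#' methylated). A promoter is called demethylated when the average is equal
#' or below 0.33, methylated when equal or above 0.66, and hemimethylated
#' strictly in between.
#'
#' @param mean_beta Numeric in \[0, 1\]; vectorised.
#' @return Character vector in
#'   `{"demethylated", "hemimethylated", "methylated"}`.
#' @export
classify_beta <- function(mean_beta) {
  if (!is.numeric(mean_beta) || any(!is.finite(mean_beta)) ||
      any(mean_beta < 0) || any(mean_beta > 1))
    stop("mean beta-values must lie in [0, 1]", call. = FALSE)
  out <- rep("hemimethylated", length(mean_beta))
  out[mean_beta <= 0.33] <- "demethylated"
  out[mean_beta >= 0.66] <- "methylated"
  out
}

#' Average beta-value of the probes inside a promoter region
#'
#' @param probes `data.frame` with columns `probe_id`, `chromosome`,
#'   `position`, `beta` (the beta of one sample; `NA` allowed).
#' @param region List with `chromosome`, `start`, `end` as returned by
#'   [promoter_region()].
#'
#' @return List with `mean_beta` (arithmetic mean over usable in-region
#'   probes) and `probes_used` (their ids).
#' @export
mean_promoter_beta <- function(probes, region) {
  stopifnot(is.data.frame(probes))
  need <- c("probe_id", "chromosome", "position", "beta")
  miss <- setdiff(need, names(probes))
  if (length(miss))
    stop("probes missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  inreg <- probes$chromosome == region$chromosome &
    probes$position >= region$start & probes$position <= region$end &
    !is.na(probes$beta)
  if (!any(inreg))
    stop("no usable probe with non-missing beta falls in the region",
         call. = FALSE)
  b <- probes$beta[inreg]
  if (any(b < 0 | b > 1))
    stop("beta-values must lie in [0, 1]", call. = FALSE)
  list(mean_beta = mean(b), probes_used = probes$probe_id[inreg])
}

#' Classify a paired tumour/normal RRBS methylation change
#'
#' The methylation level of a promoter is the count of methylated CpG sites;
#' the paired change is the tumour/normal ratio of these counts. A ratio
#' equal or above 1.5 is hypermethylated, equal or below 0.66 hypomethylated
#' (a two-fold decrease in the tumour), anything in between is normal. With
#' both counts zero the change is undefined; with a zero normal count and a
#' positive tumour count the ratio diverges and the pair is called
#' hypermethylated (flagged, since the ratio itself is undefined).
#'
#' @param tumor_methylated_cpg,normal_methylated_cpg Non-negative integer
#'   counts; vectorised.
#'
#' @return `data.frame` with `tumor_methylated_cpg`, `normal_methylated_cpg`,
#'   `ratio` (`NA` when undefined) and `change` in
#'   `{"hypermethylated", "hypomethylated", "normal", "undefined"}`.
#' @export
rrbs_change <- function(tumor_methylated_cpg, normal_methylated_cpg) {
  t <- tumor_methylated_cpg; n <- normal_methylated_cpg
  if (!is.numeric(t) || !is.numeric(n) || any(t < 0) || any(n < 0) ||
      any(t != round(t)) || any(n != round(n)))
    stop("methylated-CpG counts must be non-negative integers", call. = FALSE)
  if (length(t) != length(n))
    stop("count vectors must have equal length", call. = FALSE)
  ratio <- ifelse(n > 0, t / n, NA_real_)
  change <- rep("normal", length(t))
  change[!is.na(ratio) & ratio >= 1.5] <- "hypermethylated"
  change[!is.na(ratio) & ratio <= 0.66] <- "hypomethylated"
  change[n == 0 & t == 0] <- "undefined"
  change[n == 0 & t > 0] <- "hypermethylated"
  data.frame(tumor_methylated_cpg = t, normal_methylated_cpg = n,
             ratio = ratio, change = change, stringsAsFactors = FALSE)
}

#' Read a probe manifest (probe_id, chromosome, position)
#' @param path TSV path with header `probe_id`, `chromosome`, `position`.
#' @return `data.frame`.
#' @export
read_manifest <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chromosome", "position")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d$position <- as.numeric(d$position)
  d
}

#' Read a probe-by-sample beta-value matrix
#' @param path TSV with a `probe_id` column followed by one column per sample.
#' @return `data.frame` with `probe_id` first.
#' @export
read_beta_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"probe_id" %in% names(d))
    stop("beta matrix must have a 'probe_id' column", call. = FALSE)
  d
}

#' Read an RRBS methylated-CpG count table
#' @param path TSV with header `pair_id`, `gene`, `tumor_methylated_cpg`,
#'   `normal_methylated_cpg`.
#' @return `data.frame`.
#' @export
read_rrbs <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "gene", "tumor_methylated_cpg", "normal_methylated_cpg")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("RRBS table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d
}

#' Call promoter methylation status for every sample of a beta matrix
#'
#' For each sample and each locus, averages the manifest probes falling in
#' the promoter region and classifies the average. An optional explicit
#' probe set restricts the averaging to named probes (e.g. the 27k-overlap
#' pair for FGFR2 versus the full 9-probe 450k CpG-island set), supporting
#' both array averaging modes.
#'
#' @param betas `data.frame` from [read_beta_matrix()].
#' @param manifest `data.frame` from [read_manifest()].
#' @param loci List of [gene_locus()] (default [builtin_loci()]).
#' @param probe_sets Optional named list `gene -> character vector` of
#'   probe ids; when given it overrides the coordinate-based selection.
#'
#' @return `data.frame` with `sample_id`, `gene`, `mean_beta`, `status`,
#'   `probes_used`; samples with no usable probe get status `"missing"`.
#' @export
call_methylation_from_betas <- function(betas, manifest,
                                        loci = builtin_loci(),
                                        probe_sets = NULL) {
  samples <- setdiff(names(betas), "probe_id")
  out <- list()
  for (locus in loci) {
    region <- promoter_region(locus)
    keep <- if (!is.null(probe_sets) && locus$name %in% names(probe_sets)) {
      manifest$probe_id %in% probe_sets[[locus$name]]
    } else {
      manifest$chromosome == region$chromosome &
        manifest$position >= region$start & manifest$position <= region$end
    }
    man_g <- manifest[keep, , drop = FALSE]
    for (sid in samples) {
      b <- betas[[sid]][match(man_g$probe_id, betas$probe_id)]
      probes <- data.frame(probe_id = man_g$probe_id,
                           chromosome = man_g$chromosome,
                           position = man_g$position, beta = b,
                           stringsAsFactors = FALSE)
      res <- tryCatch(mean_promoter_beta(probes, region),
                      error = function(e) NULL)
      out[[length(out) + 1L]] <- if (is.null(res)) {
        data.frame(sample_id = sid, gene = locus$name, mean_beta = NA_real_,
                   status = "missing", probes_used = "",
                   stringsAsFactors = FALSE)
      } else {
        data.frame(sample_id = sid, gene = locus$name,
                   mean_beta = res$mean_beta,
                   status = classify_beta(res$mean_beta),
                   probes_used = paste(res$probes_used, collapse = ";"),
                   stringsAsFactors = FALSE)
      }
    }
  }
  ans <- do.call(rbind, out)
  rownames(ans) <- NULL
  ans
}

#' Call paired RRBS methylation changes for a count table
#'
#' @param rrbs `data.frame` from [read_rrbs()].
#' @return Input joined with `ratio` and `change` from [rrbs_change()].
#' @export
call_methylation_from_rrbs <- function(rrbs) {
  ch <- rrbs_change(rrbs$tumor_methylated_cpg, rrbs$normal_methylated_cpg)
  cbind(rrbs[, c("pair_id", "gene")], ch)
}

#' Built-in array probe sets for the FGFR2 and ESRP1 promoters
#'
#' `mode = "27k"` gives the probes with paired normal/tumour data on the
#' 27k-overlap analyses (2 for FGFR2, 1 for ESRP1); `mode = "450k"` gives the
#' full CpG-island sets (9 for FGFR2, 3 for ESRP1).
#'
#' @param mode `"27k"` or `"450k"`.
#' @return Named list of probe-id character vectors.
#' @export
builtin_probe_sets <- function(mode = c("450k", "27k")) {
  mode <- match.arg(mode)
  if (mode == "27k")
    list(FGFR2 = c("cg17028039", "cg09772154"),
         ESRP1 = "cg26350286")
  else
    list(FGFR2 = c("cg03471571", "cg05368033", "cg12835048", "cg17028039",
                   "cg06657142", "cg17794169", "cg22762615", "cg02179499",
                   "cg09772154"),
         ESRP1 = c("cg14154651", "cg26350286", "cg07473471"))
}
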