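#' Configuration of the synthetic paired tumour/normal cohort
#'
#' Defaults emulate the observed study conditions: 27 normal/tumour pairs
#' plus 348 unpaired tumours; FGFR2 amplified in 19% and deleted in 12% of
#' tumours, ESRP1 amplified in 62%; near-zero segment means in normals;
#' predominantly demethylated promoters (2% methylated per gene, so both
#' promoters demethylated plus ESRP1 amplification co-occur in about 60% of
#' tumours); expression log-normal around the
#' published normal medians (IIIb 2.89, IIIc 1.53, ESRP1 13.26 RPKM/FPKM)
#' with a multiplicative IIIc decrease and IIIb/ESRP1 increase under ESRP1
#' amplification; RRBS pair changes mostly unchanged or hypomethylated; and
#' survival whose hazard doubles for diffuse-histotype tumours with
#' IIIc above the normal median.
#'
#' @param n_pairs Number of normal/tumour pairs.
#' @param n_unpaired_tumors Number of additional unpaired tumours.
#' @param fgfr2_amp_freq,fgfr2_del_freq,esrp1_amp_freq,esrp1_del_freq
#'   Latent copy-number state frequencies among tumours.
#' @param normal_segmean_sd Segment-mean noise sd (log2-like units).
#' @param amp_shift,del_shift Segment-mean displacement of amplified
#'   (positive) and deleted (negative) loci.
#' @param promoter_meth_freq Probability that a tumour promoter is in the
#'   methylated latent state (per gene).
#' @param beta_demeth_params,beta_meth_params `c(shape1, shape2)` of the
#'   Beta distribution generating probe beta-values in the demethylated and
#'   methylated latent states.
#' @param expr_lognormal_params Named list `feature -> c(meanlog, sdlog)` for
#'   features `iiib`, `iiic`, `upstream`, `downstream`, `fgfr2`, `esrp1`.
#' @param esrp1_amp_iiic_effect Multiplicative factor (< 1) on the IIIc mean
#'   when ESRP1 is amplified.
#' @param esrp1_amp_iiib_effect,esrp1_amp_self_effect Multiplicative factors
#'   (> 1) on the IIIb and ESRP1 means when ESRP1 is amplified.
#' @param fgfr2_amp_expr_effect Multiplicative factor (> 1) on all FGFR2
#'   features when FGFR2 is amplified.
#' @param rrbs_change_freqs Named probabilities over
#'   `hypomethylated`/`normal`/`hypermethylated` pair changes (sum 1).
#' @param diffuse_freq,intestinal_freq,mixed_freq Lauren-histotype
#'   probabilities (sum 1).
#' @param subtype_freqs Named probabilities over `CIN`, `EBV`, `MSI`, `GS`
#'   (sum 1).
#' @param baseline_hazard Baseline death hazard (events per day).
#' @param hr_diffuse_iiic_high Hazard ratio (>= 1) for diffuse-histotype,
#'   IIIc-above-median tumours.
#' @param censoring_rate Exponential censoring rate (per day), independent
#'   of covariates.
#' @param seed Integer seed; one global stream split deterministically per
#'   modality, so adding a modality does not perturb the others.
#'
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 27L, n_unpaired_tumors = 348L,
                       fgfr2_amp_freq = 0.19, fgfr2_del_freq = 0.12,
                       esrp1_amp_freq = 0.62, esrp1_del_freq = 0.03,
                       normal_segmean_sd = 0.02,
                       amp_shift = 0.5, del_shift = -0.5,
                       promoter_meth_freq = 0.02,
                       beta_demeth_params = c(5, 45),
                       beta_meth_params = c(45, 5),
                       expr_lognormal_params = list(
                         iiib = c(log(2.89), 0.5),
                         iiic = c(log(1.53), 0.5),
                         upstream = c(log(5), 0.5),
                         downstream = c(log(5), 0.5),
                         fgfr2 = c(log(10), 0.5),
                         esrp1 = c(log(13.26), 0.5)),
                       esrp1_amp_iiic_effect = 0.4,
                       esrp1_amp_iiib_effect = 2,
                       esrp1_amp_self_effect = 2.5,
                       fgfr2_amp_expr_effect = 2,
                       rrbs_change_freqs = c(hypomethylated = 0.32,
                                             normal = 0.68,
                                             hypermethylated = 0),
                       diffuse_freq = 49 / 198,
                       intestinal_freq = 134 / 198,
                       mixed_freq = 15 / 198,
                       subtype_freqs = c(CIN = 101, EBV = 17, MSI = 37,
                                         GS = 43) / 198,
                       baseline_hazard = 1 / 1000,
                       hr_diffuse_iiic_high = 2,
                       censoring_rate = 1 / 1500,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!ok) stop(sprintf("invalid configuration: %s %s", field, what),
                  call. = FALSE)
  }
  chk(cfg$n_pairs >= 0 && cfg$n_pairs == round(cfg$n_pairs),
      "n_pairs", "must be a non-negative integer")
  chk(cfg$n_unpaired_tumors >= 0 &&
        cfg$n_unpaired_tumors == round(cfg$n_unpaired_tumors),
      "n_unpaired_tumors", "must be a non-negative integer")
  for (f in c("fgfr2_amp_freq", "fgfr2_del_freq", "esrp1_amp_freq",
              "esrp1_del_freq", "promoter_meth_freq"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must lie in [0, 1]")
  chk(cfg$fgfr2_amp_freq + cfg$fgfr2_del_freq <= 1, "fgfr2_amp_freq",
      "+ fgfr2_del_freq must not exceed 1")
  chk(cfg$esrp1_amp_freq + cfg$esrp1_del_freq <= 1, "esrp1_amp_freq",
      "+ esrp1_del_freq must not exceed 1")
  chk(cfg$normal_segmean_sd > 0, "normal_segmean_sd", "must be positive")
  chk(cfg$amp_shift > 0, "amp_shift", "must be positive")
  chk(cfg$del_shift < 0, "del_shift", "must be negative")
  chk(all(cfg$beta_demeth_params > 0) && all(cfg$beta_meth_params > 0),
      "beta params", "must be positive shape parameters")
  need <- c("iiib", "iiic", "upstream", "downstream", "fgfr2", "esrp1")
  chk(all(need %in% names(cfg$expr_lognormal_params)),
      "expr_lognormal_params", "must name all six features")
  chk(cfg$esrp1_amp_iiic_effect > 0 && cfg$esrp1_amp_iiic_effect < 1,
      "esrp1_amp_iiic_effect", "must lie in (0, 1)")
  for (f in c("esrp1_amp_iiib_effect", "esrp1_amp_self_effect",
              "fgfr2_amp_expr_effect"))
    chk(cfg[[f]] >= 1, f, "must be >= 1")
  chk(abs(sum(cfg$rrbs_change_freqs) - 1) < 1e-9 &&
        all(cfg$rrbs_change_freqs >= 0),
      "rrbs_change_freqs", "must be probabilities summing to 1")
  chk(abs(cfg$diffuse_freq + cfg$intestinal_freq + cfg$mixed_freq - 1) < 1e-9,
      "diffuse_freq", "+ intestinal_freq + mixed_freq must sum to 1")
  chk(abs(sum(cfg$subtype_freqs) - 1) < 1e-9 && all(cfg$subtype_freqs >= 0) &&
        all(c("CIN", "EBV", "MSI", "GS") %in% names(cfg$subtype_freqs)),
      "subtype_freqs", "must be CIN/EBV/MSI/GS probabilities summing to 1")
  chk(cfg$baseline_hazard > 0, "baseline_hazard", "must be positive")
  chk(cfg$hr_diffuse_iiic_high >= 1, "hr_diffuse_iiic_high", "must be >= 1")
  chk(cfg$censoring_rate > 0, "censoring_rate", "must be positive")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L && is.finite(cfg$seed),
      "seed", "must be a single integer")
  invisible(cfg)
}

#' Normal-median expression thresholds implied by a configuration
#'
#' The log-normal median of each feature in normal tissue,
#' `exp(meanlog)` — the thresholds against which the generator defines the
#' latent above/below expression regimes.
#'
#' @param config A [sim_config()].
#' @return Named numeric vector over the six expression features.
#' @export
config_normal_medians <- function(config) {
  vapply(config$expr_lognormal_params, function(p) exp(p[[1]]), numeric(1))
}

# deterministic per-modality sub-seed from the single global seed
modality_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(as.numeric(seed)) * 1009 + h * 10007) %% 2147483647)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Simulate a paired tumour/normal multi-omic cohort
#'
#' Draws per-tumour latent states (copy number per gene, promoter
#' methylation per gene, RRBS pair change per gene, expression regime,
#' histotype, molecular subtype, survival) at the configured frequencies and
#' writes every file the real-mode readers consume: a SEG-like segment file,
#' a gene-by-sample GISTIC table, a probe manifest and beta-value matrix, an
#' RRBS methylated-CpG count table, a feature-by-sample expression table, a
#' clinical table, and the latent truth table for recovery testing.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if absent).
#'
#' @return Object of class `synthetic_cohort`: file paths (`segment_file`,
#'   `gistic_file`, `manifest_file`, `beta_matrix`, `rrbs_counts`,
#'   `expression_file`, `clinical_file`, `truth_file`), the `truth`
#'   `data.frame`, and the `config`.
#' @export
simulate_cohort <- function(config, out_dir = tempfile("cohort")) {
  validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  loci <- builtin_loci()
  n_t <- config$n_pairs + config$n_unpaired_tumors
  tumor_ids <- sprintf("T%04d", seq_len(n_t))
  normal_ids <- sprintf("N%04d", seq_len(config$n_pairs))
  pair_ids <- sprintf("P%04d", seq_len(config$n_pairs))
  paired <- seq_len(config$n_pairs)

  draw_cn <- function(n, p_amp, p_del) {
    if (n == 0L) return(character(0))
    sample(c("amplified", "deleted", "normal"), n, replace = TRUE,
           prob = c(p_amp, p_del, 1 - p_amp - p_del))
  }
  draw_cat <- function(n, levels, probs) {
    if (n == 0L) return(character(0))
    sample(levels, n, replace = TRUE, prob = probs)
  }

  ## latent states: own stream so modality file layouts don't perturb them
  set.seed(modality_seed(config$seed, "latent"))
  tumor_pair <- rep(NA_character_, n_t)
  if (config$n_pairs > 0) tumor_pair[paired] <- pair_ids
  truth <- data.frame(
    sample_id = c(tumor_ids, normal_ids),
    type = c(rep("tumor", n_t), rep("normal", config$n_pairs)),
    pair_id = c(tumor_pair, pair_ids),
    stringsAsFactors = FALSE)

  tum <- data.frame(
    fgfr2_cn = draw_cn(n_t, config$fgfr2_amp_freq, config$fgfr2_del_freq),
    esrp1_cn = draw_cn(n_t, config$esrp1_amp_freq, config$esrp1_del_freq),
    fgfr2_meth = draw_cat(n_t, c("methylated", "demethylated"),
                          c(config$promoter_meth_freq,
                            1 - config$promoter_meth_freq)),
    esrp1_meth = draw_cat(n_t, c("methylated", "demethylated"),
                          c(config$promoter_meth_freq,
                            1 - config$promoter_meth_freq)),
    lauren = draw_cat(n_t, c("diffuse", "intestinal", "mixed"),
                      c(config$diffuse_freq, config$intestinal_freq,
                        config$mixed_freq)),
    subtype = draw_cat(n_t, names(config$subtype_freqs),
                       config$subtype_freqs),
    stringsAsFactors = FALSE)
  rrbs_truth <- data.frame(
    fgfr2_rrbs = draw_cat(config$n_pairs, names(config$rrbs_change_freqs),
                          config$rrbs_change_freqs),
    esrp1_rrbs = draw_cat(config$n_pairs, names(config$rrbs_change_freqs),
                          config$rrbs_change_freqs),
    stringsAsFactors = FALSE)

  ## expression values (latent regimes are defined from the drawn values)
  set.seed(modality_seed(config$seed, "expression"))
  feats <- c("iiib", "iiic", "upstream", "downstream", "fgfr2", "esrp1")
  medians <- config_normal_medians(config)
  expr <- matrix(NA_real_, nrow = length(feats),
                 ncol = n_t + config$n_pairs,
                 dimnames = list(feats, c(tumor_ids, normal_ids)))
  for (f in feats) {
    p <- config$expr_lognormal_params[[f]]
    shift <- rep(0, n_t)
    if (n_t > 0) {
      famp <- tum$fgfr2_cn == "amplified"
      eamp <- tum$esrp1_cn == "amplified"
      if (f %in% c("iiib", "iiic", "upstream", "downstream", "fgfr2"))
        shift <- shift + log(config$fgfr2_amp_expr_effect) * famp
      if (f == "iiib") shift <- shift + log(config$esrp1_amp_iiib_effect) * eamp
      if (f == "iiic") shift <- shift + log(config$esrp1_amp_iiic_effect) * eamp
      if (f == "esrp1") shift <- shift + log(config$esrp1_amp_self_effect) * eamp
    }
    expr[f, ] <- stats::rlnorm(n_t + config$n_pairs,
                               meanlog = p[[1]] + c(shift,
                                                    rep(0, config$n_pairs)),
                               sdlog = p[[2]])
  }
  regime <- function(f) {
    if (n_t == 0L) return(character(0))
    ifelse(expr[f, tumor_ids] > medians[[f]], "above", "below")
  }
  tum$iiib_regime <- regime("iiib")
  tum$iiic_regime <- regime("iiic")
  tum$esrp1_regime <- regime("esrp1")

  ## survival
  set.seed(modality_seed(config$seed, "survival"))
  highrisk <- if (n_t > 0)
    tum$lauren == "diffuse" & tum$iiic_regime == "above" else logical(0)
  hazard <- config$baseline_hazard *
    ifelse(highrisk, config$hr_diffuse_iiic_high, 1)
  t_death <- if (n_t > 0) stats::rexp(n_t, rate = hazard) else numeric(0)
  t_cens <- if (n_t > 0) stats::rexp(n_t, rate = config$censoring_rate)
  else numeric(0)
  time <- round(pmin(t_death, t_cens), 1)
  event <- as.integer(t_death <= t_cens)

  ## segment file (all samples, one segment per gene)
  set.seed(modality_seed(config$seed, "segments"))
  all_ids <- c(tumor_ids, normal_ids)
  seg_empty <- data.frame(Sample = character(0), Chromosome = character(0),
                          Start = numeric(0), End = numeric(0),
                          Num_Probes = integer(0), Segment_Mean = numeric(0))
  seg_rows <- list(seg_empty)
  for (g in if (length(all_ids)) names(loci) else character(0)) {
    locus <- loci[[g]]
    state <- c(if (n_t > 0) tum[[paste0(tolower(g), "_cn")]] else character(0),
               rep("normal", config$n_pairs))
    centre <- ifelse(state == "amplified", config$amp_shift,
                     ifelse(state == "deleted", config$del_shift, 0))
    mean_ <- stats::rnorm(length(all_ids), centre, config$normal_segmean_sd)
    seg_rows[[g]] <- data.frame(
      Sample = all_ids, Chromosome = locus$chromosome,
      Start = locus$start - 10000, End = locus$end + 10000,
      Num_Probes = 200L, Segment_Mean = round(mean_, 4),
      stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, seg_rows)
  seg <- seg[order(seg$Sample, seg$Chromosome, seg$Start), , drop = FALSE]
  segment_file <- write_tsv(seg, file.path(out_dir, "segments.seg.tsv"))

  ## GISTIC gene-level table (tumours; deterministic map from latent state)
  gmap <- c(amplified = 2L, normal = 0L, deleted = -2L)
  gistic <- if (n_t == 0L) data.frame(Gene = character(0)) else
    data.frame(Gene = c("FGFR2", "ESRP1"), stringsAsFactors = FALSE)
  for (i in seq_len(n_t)) {
    gistic[[tumor_ids[i]]] <- c(gmap[[tum$fgfr2_cn[i]]],
                                gmap[[tum$esrp1_cn[i]]])
  }
  gistic_file <- write_tsv(gistic, file.path(out_dir, "gistic_calls.tsv"))

  ## probe manifest + beta matrix
  set.seed(modality_seed(config$seed, "methylation"))
  sets <- builtin_probe_sets("450k")
  manifest <- do.call(rbind, lapply(names(loci), function(g) {
    region <- promoter_region(loci[[g]])
    k <- length(sets[[g]])
    data.frame(probe_id = sets[[g]], chromosome = region$chromosome,
               position = round(seq(region$start + 50, region$end - 50,
                                    length.out = k)),
               stringsAsFactors = FALSE)
  }))
  manifest_file <- write_tsv(manifest, file.path(out_dir, "probe_manifest.tsv"))
  betas <- if (length(all_ids) == 0L) data.frame(probe_id = character(0)) else
    data.frame(probe_id = manifest$probe_id, stringsAsFactors = FALSE)
  meth_state <- function(gene, i) {
    if (i <= n_t) tum[[paste0(tolower(gene), "_meth")]][i] else "demethylated"
  }
  for (i in seq_along(all_ids)) {
    col <- numeric(nrow(manifest))
    for (g in names(loci)) {
      sel <- manifest$probe_id %in% sets[[g]]
      par <- if (meth_state(g, i) == "methylated") config$beta_meth_params
      else config$beta_demeth_params
      col[sel] <- round(stats::rbeta(sum(sel), par[[1]], par[[2]]), 4)
    }
    betas[[all_ids[i]]] <- col
  }
  beta_matrix <- write_tsv(betas, file.path(out_dir, "beta_matrix.tsv"))

  ## RRBS methylated-CpG counts per pair
  set.seed(modality_seed(config$seed, "rrbs"))
  rrbs_rows <- list()
  ratio_range <- list(hypomethylated = c(0.20, 0.55),
                      normal = c(0.80, 1.40),
                      hypermethylated = c(1.60, 2.40))
  for (g in if (config$n_pairs > 0) c("FGFR2", "ESRP1") else character(0)) {
    states <- rrbs_truth[[paste0(tolower(g), "_rrbs")]]
    n_norm <- if (config$n_pairs > 0)
      10L + stats::rpois(config$n_pairs, 40) else integer(0)
    ratio <- vapply(seq_len(config$n_pairs), function(i) {
      r <- ratio_range[[states[i]]]
      stats::runif(1, r[1], r[2])
    }, numeric(1))
    rrbs_rows[[g]] <- data.frame(
      pair_id = pair_ids, gene = g,
      tumor_methylated_cpg = as.integer(round(n_norm * ratio)),
      normal_methylated_cpg = n_norm, stringsAsFactors = FALSE)
  }
  rrbs <- if (config$n_pairs == 0L)
    data.frame(pair_id = character(0), gene = character(0),
               tumor_methylated_cpg = integer(0),
               normal_methylated_cpg = integer(0))
  else {
    r <- do.call(rbind, rrbs_rows)
    r[order(r$pair_id, r$gene), , drop = FALSE]
  }
  rrbs_counts <- write_tsv(rrbs, file.path(out_dir, "rrbs_counts.tsv"))

  ## expression table
  emap <- exon_surrogate_map()
  feature_keys <- c(
    iiib = sprintf("exon:%s:%d", emap$iiib$transcript, emap$iiib$exon),
    iiic = sprintf("exon:%s:%d", emap$iiic$transcript, emap$iiic$exon),
    upstream = sprintf("exon:%s:%d", emap$upstream$transcript,
                       emap$upstream$exon),
    downstream = sprintf("exon:%s:%d", emap$downstream$transcript,
                         emap$downstream$exon),
    fgfr2 = "gene:FGFR2", esrp1 = "gene:ESRP1")
  expr_out <- if (length(all_ids) == 0L) data.frame(feature = character(0)) else
    data.frame(feature = unname(feature_keys[feats]),
               stringsAsFactors = FALSE)
  for (s in all_ids) expr_out[[s]] <- round(expr[, s], 4)
  expression_file <- write_tsv(expr_out,
                               file.path(out_dir, "expression.tsv"))

  ## clinical table (tumours)
  set.seed(modality_seed(config$seed, "clinical"))
  clinical <- data.frame(
    sample_id = tumor_ids,
    pair_id = truth$pair_id[seq_len(n_t)],
    gender = draw_cat(n_t, c("male", "female"), c(0.63, 0.37)),
    age = if (n_t > 0) round(stats::rnorm(n_t, 65, 10)) else numeric(0),
    vital_status = ifelse(event == 1, "dead", "alive"),
    days_to_death = ifelse(event == 1, time, NA_real_),
    days_to_last_follow_up = ifelse(event == 1, NA_real_, time),
    lauren = tum$lauren, stage = draw_cat(n_t, c("I/II", "III/IV", "NA"),
                                          c(0.48, 0.44, 0.08)),
    molecular_subtype = tum$subtype, stringsAsFactors = FALSE)
  clinical_file <- write_tsv(clinical, file.path(out_dir, "clinical.tsv"))

  ## truth table
  truth$fgfr2_cn_true <- c(tum$fgfr2_cn, rep("normal", config$n_pairs))
  truth$esrp1_cn_true <- c(tum$esrp1_cn, rep("normal", config$n_pairs))
  truth$fgfr2_meth_true <- c(tum$fgfr2_meth,
                             rep("demethylated", config$n_pairs))
  truth$esrp1_meth_true <- c(tum$esrp1_meth,
                             rep("demethylated", config$n_pairs))
  truth$fgfr2_rrbs_true <- rep(NA_character_, nrow(truth))
  truth$esrp1_rrbs_true <- rep(NA_character_, nrow(truth))
  if (config$n_pairs > 0) {
    idx <- match(pair_ids, truth$pair_id[truth$type == "tumor"])
    truth$fgfr2_rrbs_true[idx] <- rrbs_truth$fgfr2_rrbs
    truth$esrp1_rrbs_true[idx] <- rrbs_truth$esrp1_rrbs
  }
  truth$iiib_regime <- c(tum$iiib_regime, rep(NA_character_, config$n_pairs))
  truth$iiic_regime <- c(tum$iiic_regime, rep(NA_character_, config$n_pairs))
  truth$esrp1_regime <- c(tum$esrp1_regime,
                          rep(NA_character_, config$n_pairs))
  truth$lauren <- c(tum$lauren, rep(NA_character_, config$n_pairs))
  truth$subtype <- c(tum$subtype, rep(NA_character_, config$n_pairs))
  truth_file <- write_tsv(truth, file.path(out_dir, "truth_table.tsv"))

  structure(list(segment_file = segment_file, gistic_file = gistic_file,
                 manifest_file = manifest_file, beta_matrix = beta_matrix,
                 rrbs_counts = rrbs_counts,
                 expression_file = expression_file,
                 clinical_file = clinical_file, truth_file = truth_file,
                 truth = truth, config = config, dir = out_dir),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d pairs + %d unpaired tumours in %s\n",
              x$config$n_pairs, x$config$n_unpaired_tumors, x$dir))
  invisible(x)
}

confusion_and_accuracy <- function(truth_vec, call_vec) {
  keep <- !is.na(truth_vec)
  tv <- truth_vec[keep]; cv <- call_vec[keep]
  list(confusion = table(truth = tv, called = cv),
       accuracy = if (length(tv)) mean(tv == cv) else NA_real_)
}

#' Compare downstream calls against the latent truth of a synthetic cohort
#'
#' For each supplied modality, aligns the calls with the cohort's truth
#' table by sample (or pair) and gene, and reports the latent-state by
#' called-state confusion matrix and the accuracy. Calls on samples absent
#' from the truth table raise an alignment error.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param cn_calls Optional `data.frame` with `sample_id`, `gene`, `status`.
#' @param methylation_calls Optional `data.frame` with `sample_id`, `gene`,
#'   `status` (array beta calls).
#' @param rrbs_calls Optional `data.frame` with `pair_id`, `gene`, `change`.
#' @param expression_categories Optional `data.frame` with `sample_id`,
#'   `feature` (`iiib`/`iiic`/`esrp1`), `category`.
#'
#' @return Named list (one element per supplied modality), each with
#'   `confusion` and `accuracy`.
#' @export
recover_truth <- function(cohort, cn_calls = NULL, methylation_calls = NULL,
                          rrbs_calls = NULL, expression_categories = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  truth <- cohort$truth
  out <- list()
  by_gene <- function(calls, id_col, truth_cols, call_col, truth_ids) {
    if (!all(calls[[id_col]] %in% truth_ids))
      stop("alignment error: calls contain samples absent from the truth table",
           call. = FALSE)
    tv <- cv <- character(0)
    for (g in names(truth_cols)) {
      cg <- calls[calls$gene == g, , drop = FALSE]
      m <- match(cg[[id_col]], truth_ids)
      tvals <- truth[[truth_cols[[g]]]][m]
      tv <- c(tv, tvals); cv <- c(cv, cg[[call_col]])
    }
    confusion_and_accuracy(tv, cv)
  }
  if (!is.null(cn_calls))
    out$cn <- by_gene(cn_calls, "sample_id",
                      c(FGFR2 = "fgfr2_cn_true", ESRP1 = "esrp1_cn_true"),
                      "status", truth$sample_id)
  if (!is.null(methylation_calls))
    out$methylation <- by_gene(methylation_calls, "sample_id",
                               c(FGFR2 = "fgfr2_meth_true",
                                 ESRP1 = "esrp1_meth_true"),
                               "status", truth$sample_id)
  if (!is.null(rrbs_calls)) {
    tumor_truth <- truth[truth$type == "tumor" & !is.na(truth$pair_id), ,
                         drop = FALSE]
    if (!all(rrbs_calls$pair_id %in% tumor_truth$pair_id))
      stop("alignment error: RRBS calls contain pairs absent from the truth table",
           call. = FALSE)
    tv <- cv <- character(0)
    for (g in c("FGFR2", "ESRP1")) {
      cg <- rrbs_calls[rrbs_calls$gene == g, , drop = FALSE]
      m <- match(cg$pair_id, tumor_truth$pair_id)
      tv <- c(tv, tumor_truth[[paste0(tolower(g), "_rrbs_true")]][m])
      cv <- c(cv, cg$change)
    }
    out$rrbs <- confusion_and_accuracy(tv, cv)
  }
  if (!is.null(expression_categories)) {
    ec <- expression_categories
    if (!all(ec$sample_id %in% truth$sample_id))
      stop("alignment error: expression categories contain samples absent from the truth table",
           call. = FALSE)
    tcols <- c(iiib = "iiib_regime", iiic = "iiic_regime",
               esrp1 = "esrp1_regime")
    ec <- ec[ec$feature %in% names(tcols), , drop = FALSE]
    m <- match(ec$sample_id, truth$sample_id)
    tv <- mapply(function(i, f) truth[[tcols[[f]]]][i], m, ec$feature)
    out$expression <- confusion_and_accuracy(as.character(tv), ec$category)
  }
  if (length(out) == 0L)
    stop("no calls supplied to recover_truth", call. = FALSE)
  out
}
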