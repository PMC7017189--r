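test_that("configuration invariants are enforced with the offending field named", {
  expect_error(sim_config(n_pairs = -1), "n_pairs")
  expect_error(sim_config(fgfr2_amp_freq = 1.2), "fgfr2_amp_freq")
  expect_error(sim_config(amp_shift = -0.5), "amp_shift")
  expect_error(sim_config(del_shift = 0.5), "del_shift")
  expect_error(sim_config(normal_segmean_sd = 0), "normal_segmean_sd")
  expect_error(sim_config(esrp1_amp_iiic_effect = 1.5),
               "esrp1_amp_iiic_effect")
  expect_error(sim_config(diffuse_freq = 0.5, intestinal_freq = 0.5,
                          mixed_freq = 0.5), "sum to 1")
  expect_error(sim_config(hr_diffuse_iiic_high = 0.5),
               "hr_diffuse_iiic_high")
})

test_that("degenerate size yields valid header-only files", {
  co <- simulate_cohort(sim_config(n_pairs = 0, n_unpaired_tumors = 0),
                        tempfile("empty"))
  expect_equal(nrow(co$truth), 0L)
  expect_equal(nrow(read_seg(co$segment_file)), 0L)
  expect_equal(nrow(read_rrbs(co$rrbs_counts)), 0L)
  expect_equal(nrow(read_beta_matrix(co$beta_matrix)), 0L)
  expect_equal(nrow(read_expression(co$expression_file)), 0L)
})

test_that("identical configuration and seed give byte-identical outputs", {
  cfg <- sim_config(n_pairs = 4, n_unpaired_tumors = 10, seed = 7)
  a <- simulate_cohort(cfg, tempfile("a"))
  b <- simulate_cohort(cfg, tempfile("b"))
  expect_identical(a$truth, b$truth)
  for (f in c("segment_file", "gistic_file", "beta_matrix", "rrbs_counts",
              "expression_file", "clinical_file", "truth_file"))
    expect_identical(readLines(a[[f]]), readLines(b[[f]]))
})

test_that("latent amplification frequency converges to the configured probability", {
  cfg <- sim_config(n_pairs = 0, n_unpaired_tumors = 2000,
                    fgfr2_amp_freq = 0.19, seed = 7)
  co <- simulate_cohort(cfg, tempfile("freq"))
  p_hat <- mean(co$truth$fgfr2_cn_true == "amplified")
  expect_lt(abs(p_hat - 0.19), 3 * sqrt(0.19 * 0.81 / 2000))
})

test_that("every tumour in the modality files appears in the clinical file; truth covers all samples", {
  co <- small_cohort()
  clin <- read.delim(co$clinical_file, stringsAsFactors = FALSE)
  seg <- read_seg(co$segment_file)
  tum_in_seg <- grep("^T", unique(seg$sample_id), value = TRUE)
  expect_true(all(tum_in_seg %in% clin$sample_id))
  expr <- read_expression(co$expression_file)
  tum_in_expr <- grep("^T", setdiff(names(expr), "feature"), value = TRUE)
  expect_true(all(tum_in_expr %in% clin$sample_id))
  expect_setequal(co$truth$sample_id,
                  union(unique(seg$sample_id), setdiff(names(expr), "feature")))
})

test_that("file round-trip through the real-mode readers reproduces written values", {
  co <- small_cohort()
  seg <- read_seg(co$segment_file)
  expect_true(all(is.finite(seg$segment_mean)))
  raw <- read.delim(co$segment_file)
  expect_equal(seg$segment_mean, raw$Segment_Mean)
  betas <- read_beta_matrix(co$beta_matrix)
  expect_true(all(as.matrix(betas[, -1]) >= 0 & as.matrix(betas[, -1]) <= 1))
})

test_that("recover_truth: identity calls give accuracy 1, inverted 2-class calls give 0", {
  co <- small_cohort()
  tt <- co$truth
  id_calls <- data.frame(
    sample_id = rep(tt$sample_id, 2),
    gene = rep(c("FGFR2", "ESRP1"), each = nrow(tt)),
    status = c(tt$fgfr2_cn_true, tt$esrp1_cn_true),
    stringsAsFactors = FALSE)
  expect_equal(recover_truth(co, cn_calls = id_calls)$cn$accuracy, 1.0)
  tum <- tt[tt$type == "tumor", ]
  flip <- c(above = "below", below = "above")
  inv <- data.frame(sample_id = tum$sample_id, feature = "iiic",
                    category = unname(flip[tum$iiic_regime]),
                    stringsAsFactors = FALSE)
  expect_equal(recover_truth(co, expression_categories = inv)$expression$accuracy,
               0.0)
  bad <- id_calls; bad$sample_id[1] <- "NOT_A_SAMPLE"
  expect_error(recover_truth(co, cn_calls = bad), "alignment")
  expect_error(recover_truth(co), "no calls")
})

test_that("segment-mean recovery exceeds the Gaussian tail bound under well-separated shifts", {
  # default shifts sit 25 sd from zero and the 0.1 cutoff sits 5 sd from
  # every class centre: Gaussian tails bound misclassification near zero
  cfg <- sim_config(n_pairs = 0, n_unpaired_tumors = 500, seed = 13)
  co <- simulate_cohort(cfg, tempfile("sep"))
  calls <- call_cn_from_seg(read_seg(co$segment_file))
  acc <- recover_truth(co, cn_calls = calls)$cn$accuracy
  expect_gt(acc, 0.95)
})

test_that("with hazard ratio 1 the log-rank p-values are uniform across replicates", {
  ps <- vapply(1:200, function(i) {
    cfg <- sim_config(n_pairs = 0, n_unpaired_tumors = 60,
                      hr_diffuse_iiic_high = 1, seed = 1000 + i)
    co <- simulate_cohort(cfg, tempfile("null"))
    clin <- read.delim(co$clinical_file, stringsAsFactors = FALSE)
    time <- ifelse(clin$vital_status == "dead", clin$days_to_death,
                   clin$days_to_last_follow_up)
    event <- as.integer(clin$vital_status == "dead")
    grp <- ifelse(clin$lauren == "diffuse", "diffuse", "other")
    if (length(unique(grp)) < 2L || sum(event) == 0) return(NA_real_)
    logrank(time, event, grp)$p_value
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
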