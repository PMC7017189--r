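test_that("beta classification uses inclusive 0.33/0.66 boundaries", {
  expect_equal(classify_beta(0.33), "demethylated")
  expect_equal(classify_beta(0.50), "hemimethylated")
  expect_equal(classify_beta(0.66), "methylated")
  expect_equal(classify_beta(c(0, 1)), c("demethylated", "methylated"))
  expect_error(classify_beta(1.2), "\\[0, 1\\]")
})

test_that("beta classification is exhaustive, exclusive and monotone on [0,1]", {
  grid <- seq(0, 1, length.out = 10000)
  cats <- classify_beta(grid)
  expect_true(all(cats %in% c("demethylated", "hemimethylated", "methylated")))
  ord <- c(demethylated = 1L, hemimethylated = 2L, methylated = 3L)
  expect_true(all(diff(ord[cats]) >= 0))
})

test_that("promoter beta averaging uses in-region non-missing probes only", {
  region <- list(chromosome = "chr10", start = 100, end = 200)
  probes <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5"),
    chromosome = c("chr10", "chr10", "chr10", "chr10", "chr8"),
    position = c(110, 150, 190, 250, 150),
    beta = c(0.1, 0.2, 0.9, 0.99, 0.99))
  res <- mean_promoter_beta(probes, region)
  expect_equal(res$mean_beta, 0.4)  # mean of {0.1, 0.2, 0.9}
  expect_setequal(res$probes_used, c("p1", "p2", "p3"))
  # bounded by inputs, order-invariant
  expect_equal(mean_promoter_beta(probes[c(3, 1, 2), ], region)$mean_beta, 0.4)
  probes$beta[1:3] <- NA
  expect_error(mean_promoter_beta(probes, region), "no usable probe")
  p2 <- data.frame(probe_id = "p", chromosome = "chr10", position = 150,
                   beta = 0.9)
  expect_equal(mean_promoter_beta(p2, region)$mean_beta, 0.9)
})

test_that("promoter regions: built-in intervals override TSS arithmetic", {
  loci <- builtin_loci()
  r <- promoter_region(loci$ESRP1)
  expect_equal(r, list(chromosome = "chr8", start = 94639136, end = 94641136))
  r <- promoter_region(loci$FGFR2)
  expect_equal(r, list(chromosome = "chr10", start = 121598458,
                       end = 121600598))
  g <- gene_locus("G", "chr1", 10000, 50000, "+", tss = 10000)
  expect_equal(promoter_region(g, 2000),
               list(chromosome = "chr1", start = 8000, end = 10000))
  gm <- gene_locus("G", "chr1", 1000, 9000, "-", tss = 9000)
  expect_equal(promoter_region(gm, 2000),
               list(chromosome = "chr1", start = 9000, end = 11000))
  expect_error(promoter_region(g, 0), "positive")
  expect_error(gene_locus("G", "chr1", 10, 50, "+", tss = 50), "tss")
})

test_that("RRBS ratio rule: 1.5/0.66 cut-points, zero-count limits, scale invariance", {
  expect_equal(rrbs_change(10, 20)[, c("ratio", "change")],
               data.frame(ratio = 0.5, change = "hypomethylated"))
  expect_equal(rrbs_change(20, 20)$change, "normal")
  expect_equal(rrbs_change(30, 20)$change, "hypermethylated")  # ratio 1.5
  expect_equal(rrbs_change(132, 200)$change, "hypomethylated") # ratio 0.66
  expect_equal(rrbs_change(0, 0)$change, "undefined")
  hz <- rrbs_change(5, 0)
  expect_equal(hz$change, "hypermethylated")
  expect_true(is.na(hz$ratio))
  expect_error(rrbs_change(-1, 2), "non-negative")
  expect_error(rrbs_change(1.5, 2), "non-negative integers")
  # ratio invariance under integer scaling
  for (c_ in c(2L, 5L, 13L))
    expect_equal(rrbs_change(7L * c_, 11L * c_)$change,
                 rrbs_change(7L, 11L)$change)
})

test_that("array caller reproduces per-sample classes and supports probe-set modes", {
  co <- small_cohort()
  betas <- read_beta_matrix(co$beta_matrix)
  manifest <- read_manifest(co$manifest_file)
  calls <- call_methylation_from_betas(betas, manifest)
  expect_equal(nrow(calls), 2L * (ncol(betas) - 1L))
  expect_true(all(calls$status %in%
                    c("demethylated", "hemimethylated", "methylated")))
  # explicit 27k probe subset restricts the averaging
  calls27 <- call_methylation_from_betas(betas, manifest,
                                         probe_sets = builtin_probe_sets("27k"))
  s <- calls27$sample_id[1]
  used <- strsplit(calls27$probes_used[calls27$sample_id == s &
                                         calls27$gene == "FGFR2"], ";")[[1]]
  expect_setequal(used, c("cg17028039", "cg09772154"))
})

test_that("RRBS caller round-trips the generated count file", {
  co <- small_cohort()
  rr <- read_rrbs(co$rrbs_counts)
  calls <- call_methylation_from_rrbs(rr)
  expect_equal(nrow(calls), nrow(rr))
  expect_true(all(calls$change %in%
                    c("hypomethylated", "normal", "hypermethylated")))
})
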