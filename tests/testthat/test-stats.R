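# independent oracle: exact two-sided rank-sum p by enumerating rank splits
enumerate_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  splits <- utils::combn(n + m, n)
  w_all <- apply(splits, 2, function(idx)
    sum(rank(seq_len(n + m))[idx]) - n * (n + 1) / 2)
  mu <- n * m / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

test_that("contingency test: chi-square with Yates on 2x2, independence gives p 1", {
  # rows proportional to column margins -> statistic 0 (no correction at 3x2)
  tab <- matrix(c(10, 20, 20, 40, 5, 10), nrow = 3, byrow = TRUE)
  res <- contingency_test(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$correction, "none")
  expect_equal(res$df, 2L)
  r22 <- contingency_test(matrix(c(12, 8, 7, 13), 2))
  expect_equal(r22$correction, "yates")
  # invariant under row and column permutation
  tab2 <- matrix(c(28, 21, 24, 110, 4, 11), nrow = 3, byrow = TRUE)
  expect_equal(contingency_test(tab2)$p_value,
               contingency_test(tab2[c(3, 1, 2), c(2, 1)])$p_value)
  expect_error(contingency_test(matrix(c(0, 0, 1, 2), 2)), "degenerate")
  expect_error(contingency_test(matrix(c(1.5, 2, 3, 4), 2)), "integers")
  expect_error(contingency_test(matrix(1:3, ncol = 1)), "at least 2")
})

test_that("wilcoxon exact mode agrees with full rank-split enumeration (n+m <= 10)", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4), mode = "exact")$p_value,
               1 / 3)
  set.seed(42)
  for (i in 1:8) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    x <- round(rnorm(n), 2); y <- round(rnorm(m) + runif(1, -1, 1), 2)
    if (anyDuplicated(c(x, y))) next
    expect_equal(wilcoxon_rank_sum(x, y, mode = "exact")$p_value,
                 enumerate_ranksum_p(x, y), tolerance = 1e-12)
  }
  # identical samples: approximate mode gives p 1 by symmetry
  z <- c(1, 2, 3, 4)
  expect_equal(wilcoxon_rank_sum(z, z, mode = "normal-approx")$p_value, 1)
  # power sanity: strongly shifted Gaussians
  set.seed(1)
  big <- wilcoxon_rank_sum(rnorm(200), rnorm(200, 2), mode = "auto")
  expect_lt(big$p_value, 1e-6)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("student's t matches the closed form and flags degenerate variance", {
  res <- students_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$statistic, -sqrt(3 / 2))
  expect_equal(res$p_value, 2 * pt(-sqrt(3 / 2), df = 4))
  same <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  deg <- students_t(c(0, 0), c(1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0)
  degeq <- students_t(c(2, 2), c(2, 2))
  expect_true(degeq$degenerate)
  expect_equal(degeq$p_value, 1)
})

test_that("Kaplan-Meier estimate matches hand product-limit and 1 - ECDF oracles", {
  # 4 distinct event times, no censoring
  km <- km_estimate(1:4, rep(1, 4))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  # all censored: flat at 1 (no event steps)
  flat <- km_estimate(c(2, 5, 7), c(0, 0, 0))
  expect_equal(length(flat$time), 0L)
  # mixed worked set: S(1) = 2/3, then the last subject dies -> S(3) = 0
  mix <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(mix$survival, c(2 / 3, 0))
  # no censoring: survival equals 1 - empirical CDF at every event time
  set.seed(7)
  t <- round(rexp(40, 0.01), 1)
  km2 <- km_estimate(t, rep(1, 40))
  expect_equal(km2$survival,
               vapply(km2$time, function(u) mean(t > u), numeric(1)))
  expect_error(km_estimate(-1, 1), "non-negative")
  expect_error(km_estimate(1, 2), "event indicator")
})

test_that("log-rank: zero statistic for identical groups, label symmetry, power under HR 2", {
  t <- c(1, 2, 3, 4, 5); e <- c(1, 1, 0, 1, 1)
  same <- logrank(c(t, t), c(e, e), rep(c("a", "b"), each = 5))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  set.seed(3)
  tt <- rexp(60); ee <- rbinom(60, 1, 0.8); gg <- rep(c("a", "b"), 30)
  swapped <- ifelse(gg == "a", "b", "a")
  expect_equal(logrank(tt, ee, gg)$p_value, logrank(tt, ee, swapped)$p_value)
  expect_error(logrank(tt, rep(0, 60), gg), "no events")
  expect_error(logrank(tt, ee, rep("a", 60)), "2 groups")
  # pairwise table covers all group pairs
  g3 <- rep(c("a", "b", "c"), each = 20)
  pw <- logrank(rexp(60), rbinom(60, 1, 0.9), g3, pairwise = TRUE)
  expect_equal(nrow(pw$pairwise), 3L)
  # power: two exponential arms with hazard ratio 2, n = 200/arm
  set.seed(11)
  hits <- 0L
  for (i in 1:100) {
    times <- c(rexp(200, 1), rexp(200, 2))
    cens <- rexp(400, 0.2)
    obs <- pmin(times, cens); ev <- as.integer(times <= cens)
    p <- logrank(obs, ev, rep(c("lo", "hi"), each = 200))$p_value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 90L)
})

test_that("log-rank null p-values are uniform over replicates", {
  set.seed(19)
  ps <- replicate(500, {
    t <- rexp(40); e <- rbinom(40, 1, 0.85)
    logrank(t, e, rep(c("a", "b"), 20))$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("build_table1 cross-tabulates, drops NA rows from the test, keeps them in the layout", {
  cohort <- data.frame(
    sample_id = sprintf("S%02d", 1:40),
    iiic_cat = rep(c("above", "below"), 20),
    lauren = c(rep("diffuse", 14), rep("intestinal", 20), rep(NA, 6)),
    stringsAsFactors = FALSE)
  out <- build_table1(cohort, "lauren", "iiic_cat")
  expect_true("NA" %in% rownames(out$table))
  expect_false("NA" %in% rownames(out$tested_table))
  expect_equal(sum(out$tested_table), 34)
  expect_s3_class(out$test, "fgfr2axis_test")
  one <- data.frame(sample_id = "a", iiic_cat = "above", lauren = "diffuse")
  expect_error(build_table1(one, "lauren", "iiic_cat"), "degenerate")
  expect_error(build_table1(cohort, "missing_field", "iiic_cat"),
               "not present")
})
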