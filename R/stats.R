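#' Pearson chi-square test on a contingency table
#'
#' Categorical clinico-pathological factors versus expression or copy-number
#' categories are tested with Pearson's chi-square on the observed counts,
#' with the Yates continuity correction applied to 2x2 tables (the rule that
#' reproduces the published association p-values). Rows or columns whose
#' margin is zero are structural and rejected.
#'
#' @param table Matrix of non-negative integer counts, at least 2x2.
#' @return List of class `fgfr2axis_test`: `statistic`, `df`, `p_value`,
#'   `method`, `correction`.
#' @export
contingency_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("contingency counts must be non-negative integers", call. = FALSE)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("contingency table must have at least 2 rows and 2 columns",
         call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: a row or column margin is zero", call. = FALSE)
  yates <- nrow(table) == 2L && ncol(table) == 2L
  ct <- suppressWarnings(stats::chisq.test(table, correct = yates))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value,
                 method = "Pearson chi-square",
                 correction = if (yates) "yates" else "none"),
            class = "fgfr2axis_test")
}

#' @export
print.fgfr2axis_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, df = %s, p = %.3g%s\n", x$method,
              x$statistic, if (is.null(x$df) || is.na(x$df)) "NA" else x$df,
              x$p_value,
              if (identical(x$correction, "yates")) " (Yates)" else ""))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Continuous expression contrasts between groups use the nonparametric
#' rank-sum test. `mode = "auto"` uses the exact distribution when
#' `n + m <= 20` and there are no ties, otherwise the normal approximation
#' with tie and continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"normal-approx"`.
#' @return `fgfr2axis_test` list.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal-approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- switch(mode,
                  exact = TRUE,
                  `normal-approx` = FALSE,
                  auto = (length(x) + length(y)) <= 20L && !ties)
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  structure(list(statistic = unname(wt$statistic), df = NA_integer_,
                 p_value = wt$p.value,
                 method = if (exact) "Wilcoxon rank-sum (exact)" else
                   "Wilcoxon rank-sum (normal approximation)",
                 correction = if (exact) "none" else "continuity"),
            class = "fgfr2axis_test")
}

#' Two-sided two-sample Student's t-test
#'
#' Pooled-variance by default; `welch = TRUE` drops the equal-variance
#' assumption. When both groups are constant the test is degenerate: with
#' equal means `p = 1` is returned, with unequal means `p = 0`, both flagged.
#'
#' @param x,y Numeric vectors of length >= 2.
#' @param welch Use the Welch unequal-variance form.
#' @return `fgfr2axis_test` list with a logical `degenerate` element.
#' @export
students_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(structure(list(statistic = if (eq) 0 else Inf,
                          df = length(x) + length(y) - 2L,
                          p_value = if (eq) 1 else 0,
                          method = "Student's t (degenerate variance)",
                          correction = NA_character_, degenerate = TRUE),
                     class = "fgfr2axis_test"))
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 method = if (welch) "Welch t" else "Student's t (pooled)",
                 correction = NA_character_, degenerate = FALSE),
            class = "fgfr2axis_test")
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Non-negative follow-up times (days).
#' @param event Event indicator (1 = death, 0 = censored).
#' @return List of class `fgfr2axis_km`: `time` (ordered event times),
#'   `survival`, `n_risk`, `n_event`, and the underlying
#'   [survival::survfit] object as `fit`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L)
    stop("survival records must be non-empty", call. = FALSE)
  if (any(time < 0))
    stop("survival times must be non-negative", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("event indicator must be 0 (censored) or 1 (death)", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  structure(list(time = fit$time[keep], survival = fit$surv[keep],
                 n_risk = fit$n.risk[keep], n_event = fit$n.event[keep],
                 fit = fit),
            class = "fgfr2axis_km")
}

#' @export
print.fgfr2axis_km <- function(x, ...) {
  cat(sprintf("<Kaplan-Meier> %d event time(s); S(last) = %.3f\n",
              length(x$time),
              if (length(x$survival)) x$survival[length(x$survival)] else 1))
  invisible(x)
}

#' Plot Kaplan-Meier curves by group
#'
#' @param time,event As in [km_estimate()].
#' @param group Group labels.
#' @param ... Passed to `plot.survfit`.
#' @return The `survfit` object, invisibly.
#' @export
plot_km <- function(time, event, group = NULL, ...) {
  fit <- if (is.null(group))
    survival::survfit(survival::Surv(time, event) ~ 1)
  else
    survival::survfit(survival::Surv(time, event) ~ factor(group))
  graphics::plot(fit, xlab = "Days", ylab = "Overall survival",
                 col = seq_len(max(1L, length(unique(group)))), ...)
  invisible(fit)
}

#' Log-rank test between survival groups
#'
#' Standard log-rank chi-square with `groups - 1` degrees of freedom; the
#' overall k-group test by default, with optional pairwise tests between all
#' group pairs (uncorrected, as in the source analysis).
#'
#' @param time,event As in [km_estimate()].
#' @param group Group labels (>= 2 distinct).
#' @param pairwise Also compute all pairwise tests.
#' @return `fgfr2axis_test` list; with `pairwise = TRUE` a `pairwise`
#'   `data.frame` element (`group1`, `group2`, `p_value`) is attached.
#' @export
logrank <- function(time, event, group, pairwise = FALSE) {
  group <- as.character(group)
  if (length(unique(group)) < 2L)
    stop("log-rank requires at least 2 groups", call. = FALSE)
  if (sum(event) == 0)
    stop("degenerate: no events in any group", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ factor(group))
  df <- length(sd$n) - 1L
  res <- structure(list(statistic = sd$chisq, df = df,
                        p_value = stats::pchisq(sd$chisq, df,
                                                lower.tail = FALSE),
                        method = "log-rank", correction = NA_character_),
                   class = "fgfr2axis_test")
  if (pairwise) {
    gs <- sort(unique(group))
    pw <- list()
    for (i in seq_len(length(gs) - 1L)) for (j in seq((i + 1L), length(gs))) {
      keep <- group %in% gs[c(i, j)]
      p <- tryCatch(
        logrank(time[keep], event[keep], group[keep])$p_value,
        error = function(e) NA_real_)
      pw[[length(pw) + 1L]] <- data.frame(group1 = gs[i], group2 = gs[j],
                                          p_value = p,
                                          stringsAsFactors = FALSE)
    }
    res$pairwise <- do.call(rbind, pw)
  }
  res
}

#' Cross-tabulate a clinical factor against an expression/CN category
#'
#' Builds the association-layer table for one clinico-pathological factor:
#' factor levels as rows, categories (e.g. above/below) as columns. `NA` (or
#' literal `"NA"`) factor levels are reported as a row but dropped before
#' testing, matching the published table layout. Samples missing the
#' category are excluded.
#'
#' @param cohort `data.frame` from [assemble_cohort()] (with clinical
#'   columns).
#' @param factor_field Clinical column name (e.g. `"lauren"`).
#' @param category_field State column name (e.g. `"iiic_cat"`).
#' @return List: `table` (full counts incl. any NA row), `tested_table`,
#'   `test` (`fgfr2axis_test`).
#' @export
build_table1 <- function(cohort, factor_field, category_field) {
  for (f in c(factor_field, category_field))
    if (!f %in% names(cohort))
      stop("field not present in cohort: ", f, call. = FALSE)
  fac <- as.character(cohort[[factor_field]])
  cat_ <- as.character(cohort[[category_field]])
  keep <- !is.na(cat_) & cat_ != "missing"
  fac <- fac[keep]; cat_ <- cat_[keep]
  fac[is.na(fac)] <- "NA"
  tab <- table(factor = fac, category = cat_)
  tested <- tab[rownames(tab) != "NA", , drop = FALSE]
  if (nrow(tested) < 2L || ncol(tested) < 2L)
    stop("degenerate cross-tabulation: fewer than 2 usable levels",
         call. = FALSE)
  list(table = tab, tested_table = tested,
       test = contingency_test(unclass(tested)))
}
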