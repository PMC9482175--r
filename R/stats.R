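#' @title Statistical battery for immune-density scores
#' @description Association tests (chi-squared with Yates correction for
#'   2x2 tables, Fisher's exact test when expected counts fall below 5),
#'   log-density comparisons and correlations, and survival analysis
#'   (Kaplan-Meier, log-rank, Cox proportional hazards with Efron ties).
#'   All tests are two-sided; no multiple-testing correction is applied
#'   (single-hypothesis framing per table row, a documented caveat).
#' @name stats-battery
NULL

test_result <- function(method, statistic = NA_real_, df = NA_real_,
                        p_value, continuity_correction = NA, ...) {
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 continuity_correction = continuity_correction, ...),
            class = "periscore_test")
}

#' @export
print.periscore_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, df = %s, p = %.4g\n", x$method,
              format(x$statistic), format(x$df), x$p_value))
  invisible(x)
}

check_table <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("contingency table must hold non-negative integer counts")
  tab
}

#' Pearson chi-squared test of independence
#'
#' Applies the Yates continuity correction for 2x2 tables (the convention
#' under which the published association p-values of this analysis type
#' reproduce), no correction for larger tables. Degenerate tables with a
#' zero margin return p = 1 with a warning.
#'
#' @param tab r x c matrix of counts.
#' @return a `periscore_test` result.
#' @export
chi_square_test <- function(tab) {
  tab <- check_table(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: chi-squared test is degenerate, p = 1")
    return(test_result("chi_square", 0, NA_real_, 1, FALSE))
  }
  two_by_two <- all(dim(tab) == 2L)
  ct <- suppressWarnings(chisq.test(tab, correct = two_by_two))
  test_result("chi_square", ct$statistic, ct$parameter, ct$p.value,
              two_by_two, expected = ct$expected)
}

#' Fisher's exact test
#'
#' Two-sided exact test summing hypergeometric probabilities not larger
#' than that of the observed table; for tables larger than 2x2 with a
#' grand total above `mc_threshold` the p-value is estimated by Monte
#' Carlo with the simulation flagged in the result.
#'
#' @param tab r x c matrix of counts.
#' @param mc_threshold grand-total guard above which r x c tables fall
#'   back to Monte Carlo.
#' @param B Monte Carlo replicates for the fallback.
#' @return a `periscore_test` result (`simulated` reports the fallback).
#' @export
fisher_exact_test <- function(tab, mc_threshold = 10000, B = 1e5) {
  tab <- check_table(tab)
  simulate <- !all(dim(tab) == 2L) && sum(tab) > mc_threshold
  ft <- fisher.test(tab, simulate.p.value = simulate, B = B)
  test_result("fisher_exact", NA_real_, NA_real_, ft$p.value, NA,
              simulated = simulate)
}

#' Choose chi-squared or Fisher by the expected-count rule
#'
#' Fisher's exact test is used when any expected cell count is below 5,
#' otherwise the chi-squared test; the choice is recorded in the result.
#'
#' @param tab r x c matrix of counts.
#' @return a `periscore_test` with an extra `test_chosen` field.
#' @export
select_association_test <- function(tab) {
  tab <- check_table(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("need at least 2 rows and 2 columns")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: association test degenerate, p = 1")
    return(test_result("chi_square", 0, NA_real_, 1, FALSE,
                       test_chosen = "chi_square", min_expected = 0))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    res <- fisher_exact_test(tab)
    res$test_chosen <- "fisher_exact"
  } else {
    res <- chi_square_test(tab)
    res$test_chosen <- "chi_square"
  }
  res$min_expected <- min(expected)
  res
}

#' Log transform of densities with +1 offset
#'
#' `log(x + 1)` (natural log); the offset keeps zero densities finite.
#'
#' @param density non-negative densities (1/mm^2).
#' @return transformed values.
#' @export
log_offset_transform <- function(density) {
  if (any(density < 0, na.rm = TRUE)) stop("densities must be >= 0")
  log(density + 1)
}

#' Paired t-test on log-transformed densities
#'
#' Compares log(density + 1) close to versus distant from the tumour in
#' the same patients. All-identical pairs give p = 1; zero variance of
#' the differences with a non-zero mean is flagged as degenerate.
#'
#' @param log_close,log_distant equal-length paired vectors (already
#'   log-transformed, see [log_offset_transform()]).
#' @return a `periscore_test` (`degenerate` flags zero-variance shifts).
#' @export
paired_t_test <- function(log_close, log_distant) {
  stopifnot(length(log_close) == length(log_distant))
  ok <- complete.cases(log_close, log_distant)
  d <- log_close[ok] - log_distant[ok]
  if (length(d) < 2L) stop("need at least 2 complete pairs")
  if (sd(d) == 0) {
    if (mean(d) == 0)
      return(test_result("paired_t", 0, length(d) - 1, 1, NA,
                         degenerate = FALSE))
    return(test_result("paired_t", Inf, length(d) - 1, 0, NA,
                       degenerate = TRUE))
  }
  tt <- t.test(log_close[ok], log_distant[ok], paired = TRUE)
  test_result("paired_t", tt$statistic, tt$parameter, tt$p.value, NA,
              degenerate = FALSE, mean_difference = unname(tt$estimate))
}

#' Pearson correlation of log-transformed densities
#'
#' Correlates `log(a + 1)` with `log(b + 1)`; two-sided p from the t
#' transform of r.
#'
#' @param a,b paired non-negative density vectors.
#' @return list `r`, `p_value`, `n`; zero-variance input gives `NA` with
#'   a warning.
#' @export
pearson_log_correlation <- function(a, b) {
  ok <- complete.cases(a, b)
  x <- log_offset_transform(a[ok])
  y <- log_offset_transform(b[ok])
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Student t-test for two groups (pooled variance)
#'
#' @param values numeric vector.
#' @param group two-level grouping.
#' @return a `periscore_test`.
#' @export
two_sample_t_test <- function(values, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("need exactly 2 non-empty groups")
  sp <- split(values, group)
  if (sd(unlist(sp)) == 0)
    return(test_result("t", 0, length(values) - 2, 1, NA))
  tt <- t.test(sp[[1]], sp[[2]], var.equal = TRUE)
  test_result("t", tt$statistic, tt$parameter, tt$p.value, NA)
}

#' Kruskal-Wallis rank test
#'
#' @param values numeric vector.
#' @param group grouping with >= 2 non-empty levels.
#' @return a `periscore_test`.
#' @export
kruskal_wallis <- function(values, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("need at least 2 non-empty groups")
  kt <- kruskal.test(values, group)
  test_result("kruskal_wallis", kt$statistic, kt$parameter, kt$p.value, NA)
}

#' Kaplan-Meier estimate and median follow-up
#'
#' Product-limit survival estimate plus the median follow-up time by the
#' reverse Kaplan-Meier method (censoring and event roles swapped).
#'
#' @param time positive event/censoring times.
#' @param event 1 = event, 0 = censored.
#' @return list with the `survfit` object (`fit`), `median_follow_up`
#'   and `n_events`.
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) == 0L) stop("empty survival input")
  if (any(time <= 0)) stop("times must be > 0")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  rev <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  mfu <- unname(summary(rev)$table["median"])
  list(fit = fit, median_follow_up = mfu, n_events = sum(event))
}

#' Two-group log-rank test
#'
#' @param time,event survival data as in [kaplan_meier()].
#' @param group two-level grouping.
#' @return a `periscore_test` (chi-squared statistic, 1 df); no events
#'   at all gives a flagged undefined result.
#' @export
log_rank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("need exactly 2 groups")
  if (sum(event) == 0L) {
    warning("no events: log-rank undefined")
    return(test_result("log_rank", NA_real_, 1, NA_real_, NA))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  test_result("log_rank", sd_$chisq, 1, p, NA,
              observed = sd_$obs, expected = sd_$exp)
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood fit with the Efron tie approximation (Breslow
#' available), Wald confidence intervals and p-values per covariate.
#' Non-convergence or monotone likelihood (complete separation) is
#' flagged rather than raised.
#'
#' @param time,event survival data.
#' @param covariates data frame of covariates (numeric or factor).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_fit`: data frame `coefficients` (term,
#'   coef, hr, ci_lower, ci_upper, se, p_value), `loglik`, `converged`,
#'   `ties`, `n`, `n_events`, and the underlying `coxph` fit.
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(event) < 1L) stop("need at least one event")
  df <- data.frame(covariates)
  df$.time <- time
  df$.event <- event
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(fml, data = df, ties = ties,
                        control = survival::coxph.control(eps = 1e-9,
                                                          iter.max = 50)))
      attr(f, "flagged") <- conditionMessage(w)
      f
    })
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  res <- data.frame(term = rownames(co), coef = co[, "coef"],
                    hr = co[, "exp(coef)"],
                    ci_lower = ci[, "lower .95"],
                    ci_upper = ci[, "upper .95"],
                    se = co[, "se(coef)"], p_value = co[, "Pr(>|z|)"])
  rownames(res) <- NULL
  structure(list(coefficients = res, loglik = fit$loglik,
                 converged = is.null(attr(fit, "flagged")),
                 flag = attr(fit, "flagged"), ties = ties,
                 n = s$n, n_events = s$nevent, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties), n = %d, events = %d%s\n", x$ties, x$n,
              x$n_events, if (x$converged) "" else " [flagged]"))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Run the association battery of marker groups vs clinical variables
#'
#' For every combination of a marker group column and a clinical
#' variable, builds the contingency table (categorical variables, with
#' the chi-squared/Fisher selection rule) or compares group values
#' (scale variables: Student t for parametric, Kruskal-Wallis for
#' non-parametric), and returns a tidy results table. Complete cases per
#' test; variables collapsing to a single level are skipped with a
#' warning.
#'
#' @param scores data frame with `patient_id` and group columns (values
#'   `low`/`high`).
#' @param clinical data frame with `patient_id` and clinical variables.
#' @param group_cols names of marker group columns in `scores`.
#' @param variable_types named character vector mapping clinical variable
#'   names to `"categorical"`, `"t"` or `"kruskal"`.
#' @return data frame: `variable`, `marker`, `method`, `statistic`,
#'   `p_value`, `n`, `test_chosen`.
#' @export
run_association_battery <- function(scores, clinical,
                                    group_cols = c("cd8_group", "gzmb_group",
                                                   "cd68_group"),
                                    variable_types) {
  if (any(!variable_types %in% c("categorical", "t", "kruskal")))
    stop("unknown variable type")
  merged <- merge(scores, clinical, by = "patient_id")
  out <- list()
  for (v in names(variable_types)) {
    for (g in group_cols) {
      ok <- !is.na(merged[[v]]) & !is.na(merged[[g]])
      x <- merged[[v]][ok]
      grp <- droplevels(as.factor(merged[[g]][ok]))
      if (length(unique(x)) < 2L || nlevels(grp) < 2L) {
        warning("skipping ", v, " x ", g, ": single level")
        next
      }
      res <- switch(variable_types[[v]],
                    categorical = select_association_test(table(x, grp)),
                    t = two_sample_t_test(x, grp),
                    kruskal = kruskal_wallis(x, grp))
      out[[length(out) + 1L]] <-
        data.frame(variable = v, marker = g, method = res$method,
                   statistic = res$statistic, p_value = res$p_value,
                   n = sum(ok),
                   test_chosen = if (!is.null(res$test_chosen))
                     res$test_chosen else res$method)
    }
  }
  do.call(rbind, out)
}
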