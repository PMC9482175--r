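test_that("chi-squared test uses Yates for 2x2 and handles degeneracy", {
  r <- chi_square_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_true(r$continuity_correction)
  r3 <- chi_square_test(matrix(c(10, 5, 3, 8, 12, 4), 3))
  expect_false(r3$continuity_correction)
  expect_warning(z <- chi_square_test(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_equal(z$p_value, 1)
  expect_error(chi_square_test(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("Yates chi-squared matches the textbook corrected statistic", {
  tab <- matrix(c(19, 26, 32, 11), 2)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  by_hand <- sum((abs(tab - e) - 0.5)^2 / e)
  expect_equal(chi_square_test(tab)$statistic, by_hand, tolerance = 1e-12)
})

test_that("Fisher 2x2 equals full hypergeometric enumeration", {
  expect_equal(fisher_exact_test(matrix(c(3, 1, 1, 3), 2))$p_value, 34 / 70,
               tolerance = 1e-12)
  # an all-zero row leaves a single attainable table
  expect_equal(fisher_exact_test(matrix(c(0, 4, 0, 6), 2))$p_value, 1)
  set.seed(10)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(c(2, 5, 12), 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_test(tab)$p_value, fisher_p_oracle(tab),
                 tolerance = 1e-10)
  }
})

test_that("the expected-count rule selects the right test", {
  r1 <- select_association_test(matrix(c(52, 16, 62, 6), 2))
  expect_equal(r1$test_chosen, "chi_square")
  expect_gt(r1$min_expected, 5)
  r2 <- select_association_test(matrix(c(2, 9, 8, 1), 2))
  expect_equal(r2$test_chosen, "fisher_exact")
  expect_lt(r2$min_expected, 5)
  expect_error(select_association_test(matrix(1:3, 3)), "2 rows")
})

test_that("log offset transform is log(x+1) and monotone", {
  expect_equal(log_offset_transform(0), 0)
  expect_equal(log_offset_transform(exp(1) - 1), 1)
  x <- sort(runif(20, 0, 50))
  expect_true(all(diff(log_offset_transform(x)) > 0))
  expect_error(log_offset_transform(-1), ">= 0")
})

test_that("paired t-test handles identity, degeneracy and real shifts", {
  v <- log_offset_transform(c(3, 8, 20))
  same <- paired_t_test(v, v)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  deg <- paired_t_test(c(1, 2, 3), c(0, 1, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0)
  # power: shift of 1 sd at n = 50 rejects essentially always
  set.seed(4)
  rej <- mean(vapply(1:200, function(i) {
    x <- rnorm(50); y <- x + 1 + rnorm(50, 0, 0.5)
    paired_t_test(y, x)$p_value < 0.05
  }, logical(1)))
  expect_gt(rej, 0.99)
})

test_that("Pearson log correlation behaves at the extremes and the null", {
  a <- c(0, 10, 100, 1000)
  expect_equal(pearson_log_correlation(a, a)$r, 1)
  # b chosen so log(b+1) = C - log(a+1): exact negative correlation
  b <- exp(log(1001) - log(a + 1)) - 1
  expect_equal(pearson_log_correlation(a, b)$r, -1)
  set.seed(12)
  x <- runif(1000, 0, 100); y <- runif(1000, 0, 100)
  expect_lt(abs(pearson_log_correlation(x, y)$r), 0.1)
  expect_warning(pearson_log_correlation(c(1, 1, 1), c(1, 2, 3)),
                 "variance")
})

test_that("two-sample t and Kruskal-Wallis match their definitions", {
  expect_equal(two_sample_t_test(c(1, 2, 3, 1, 2, 3),
                                 rep(c("a", "b"), each = 3))$statistic, 0)
  expect_error(two_sample_t_test(1:4, rep("a", 4)), "2 non-empty groups")
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # H from rank sums: 12/(6*7) * (6^2/3 + 15^2/3) - 3*7
  expect_equal(kw$statistic, 12 / 42 * (36 / 3 + 225 / 3) - 21,
               tolerance = 1e-12)
  # exact permutation p over all 20 splits is 2/20; the chi-squared
  # approximation must sit near it
  splits <- combn(6, 3)
  H <- apply(splits, 2, function(s) {
    g <- rep("b", 6); g[s] <- "a"
    kruskal_wallis(1:6, g)$statistic
  })
  p_perm <- mean(H >= kw$statistic - 1e-12)
  expect_equal(p_perm, 0.1)
  expect_lt(abs(kw$p_value - p_perm), 0.06)
})

test_that("Kaplan-Meier matches hand-computed product limits", {
  km <- kaplan_meier(c(1, 2), c(1, 1))
  s <- summary(km$fit, times = c(1, 2))
  expect_equal(s$surv, c(0.5, 0))
  none <- kaplan_meier(c(3, 5, 7), c(0, 0, 0))
  expect_true(all(summary(none$fit)$surv == 1))
  # censoring before the first event leaves S unchanged
  km2 <- kaplan_meier(c(1, 2, 3), c(0, 1, 1))
  s2 <- summary(km2$fit, times = c(2, 3))
  expect_equal(s2$surv, c(0.5, 0))
  # survival curve is non-increasing and starts at 1
  sv <- draw_survival(60, 0.5, seed = 91)
  km3 <- kaplan_meier(sv$time, sv$event)
  expect_true(all(diff(km3$fit$surv) <= 1e-12))
  expect_lte(max(km3$fit$surv), 1)
  expect_true(is.finite(km3$median_follow_up))
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
})

test_that("log-rank matches hand-computed O-E sums and symmetries", {
  time <- c(1, 2, 3, 4); event <- rep(1, 4)
  grp <- c("A", "A", "B", "B")
  lr <- log_rank_test(time, event, grp)
  # hand computation: at t=1 (4 at risk, 2 in A) E_A=0.5 V=0.25;
  # t=2 (3 at risk, 1 in A) E_A=1/3 V=2/9; t=3 (2 at risk, 0 in A) E=0;
  # t=4 E=0.  O_A=2, E_A=5/6, V=0.25+2/9
  stat <- (2 - 5 / 6)^2 / (0.25 + 2 / 9)
  expect_equal(lr$statistic, stat, tolerance = 1e-10)
  # invariant to relabeling
  lr2 <- log_rank_test(time, event, rev(grp))
  expect_equal(lr$statistic, lr2$statistic, tolerance = 1e-12)
  # equal groups: statistic 0, p 1
  eq <- log_rank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(eq$statistic, 0, tolerance = 1e-12)
  expect_equal(eq$p_value, 1)
  expect_warning(log_rank_test(c(1, 2), c(0, 0), c("A", "B")), "no events")
})

test_that("log-rank equals the Cox score test at beta = 0 without ties", {
  set.seed(14)
  sv <- draw_survival(120, 0.5, seed = 14)
  sv$time <- sv$time + runif(nrow(sv), 0, 1e-6)   # break ties
  lr <- log_rank_test(sv$time, sv$event, sv$group_true)
  cx <- cox_fit(sv$time, sv$event,
                data.frame(g = as.integer(sv$group_true == "high")))
  sct <- summary(cx$fit)$sctest[["test"]]
  expect_lt(abs(lr$statistic - sct), 1e-6)
})

test_that("Cox regression recovers simulated hazard ratios", {
  sv <- draw_survival(500, 0.25, seed = 77)
  cx <- cox_fit(sv$time, sv$event,
                data.frame(group = as.integer(sv$group_true == "high")))
  expect_true(cx$converged)
  hr <- cx$coefficients$hr[1]
  expect_gt(hr, 0.18); expect_lt(hr, 0.34)
  ci <- cx$coefficients
  expect_lte(ci$ci_lower[1], hr); expect_gte(ci$ci_upper[1], hr)
  # null covariate: |beta| < 2 se most of the time; here one fixed seed
  sv0 <- draw_survival(500, 1, seed = 78)
  cx0 <- cox_fit(sv0$time, sv0$event,
                 data.frame(group = as.integer(sv0$group_true == "high")))
  expect_lt(abs(cx0$coefficients$coef[1]), 2 * cx0$coefficients$se[1])
  # ties method is configurable
  cxb <- cox_fit(sv$time, sv$event,
                 data.frame(group = as.integer(sv$group_true == "high")),
                 ties = "breslow")
  expect_equal(cxb$ties, "breslow")
  expect_error(cox_fit(5, 0, data.frame(g = 1)), "event")
})

test_that("complete separation is flagged, not raised", {
  df <- data.frame(g = c(1, 1, 0, 0))
  cx <- suppressWarnings(cox_fit(c(1, 2, 10, 12), c(1, 1, 1, 1), df))
  expect_false(cx$converged)
  expect_true(is.character(cx$flag))
})

test_that("the association battery reproduces a printed cross-table", {
  # GZMB low/high vs pT 3/4 in the validation cohort: counts 52/62, 16/6
  scores <- data.frame(patient_id = 1:136,
                       gzmb_group = rep(c("low", "high"),
                                        times = c(68, 68)))
  clinical <- data.frame(patient_id = 1:136,
                         pT = c(rep(3, 52), rep(4, 16),
                                rep(3, 62), rep(4, 6)))
  out <- run_association_battery(scores, clinical,
                                 group_cols = "gzmb_group",
                                 variable_types = c(pT = "categorical"))
  expect_equal(round(out$p_value, 3), 0.036)
  expect_equal(out$test_chosen, "chi_square")
  expect_equal(out$n, 136)
  # single-level variables are skipped with a warning
  clinical$flat <- 1
  expect_warning(
    out2 <- run_association_battery(scores, clinical,
                                    group_cols = "gzmb_group",
                                    variable_types = c(pT = "categorical",
                                                       flat = "categorical")),
    "single level")
  expect_equal(nrow(out2), 1)
  expect_error(run_association_battery(scores, clinical, "gzmb_group",
                                       c(pT = "wilcoxon")), "unknown")
})
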