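test_that("normality flagging is a deterministic Shapiro-Wilk surrogate", {
  flags <- vapply(1:20, function(s) {
    withr::with_seed(s, assess_normality(rnorm(200)))
  }, character(1))
  expect_gt(mean(flags == "parametric"), 0.5)
  expect_identical(assess_normality(c(1, 1, 1, 1000, 10000, 100000)),
                   "nonparametric")
  expect_error(assess_normality(c(1, 2)), "at least 3")
  expect_error(assess_normality(rep(2, 10)), "degenerate")
})

test_that("case-control comparisons pick the right test and match hand arithmetic", {
  # printed male/female contingency is non-significant by chi-square
  sex <- c(rep(1, 19), rep(0, 17), rep(1, 48), rep(0, 35))
  tab <- tibble::tibble(group = rep(c("healthy", "t2d"), c(36, 83)), sex_male = sex)
  res <- compare_case_control(tab, "sex_male", m = 1)
  expect_identical(res$test, "chi-square")
  expect_gt(res$p_raw, 0.05)

  # identical groups: t statistic 0, p = 1
  same <- tibble::tibble(group = rep(c("a", "b"), each = 5),
                         y = rep(c(1, 2, 3, 4, 5), 2))
  res2 <- compare_case_control(same, "y", m = 1,
                               test_override = c(y = "parametric"))
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_raw, 1)

  # pooled-variance t on a 4-subject toy vs the textbook formula
  toy <- tibble::tibble(group = c("a", "a", "b", "b"), y = c(1, 3, 6, 10))
  res3 <- compare_case_control(toy, "y", m = 1, welch = FALSE,
                               test_override = c(y = "parametric"))
  sp2 <- ((2 - 1) * var(c(1, 3)) + (2 - 1) * var(c(6, 10))) / (2 + 2 - 2)
  t_hand <- (mean(c(1, 3)) - mean(c(6, 10))) / sqrt(sp2 * (1 / 2 + 1 / 2))
  expect_equal(res3$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res3$p_raw, 2 * pt(abs(t_hand), 2, lower.tail = FALSE),
               tolerance = 1e-12)

  # a group with < 2 observations is skipped with a warning
  tiny <- tibble::tibble(group = c("a", "b", "b", "b"), y = c(1, 4, 5, 6))
  expect_warning(out <- compare_case_control(tiny, "y", m = 1), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("Bonferroni adjustment is monotone, capped, and never below raw p", {
  withr::with_seed(5, {
    p <- runif(50)
    for (m in c(1, 5, 23)) {
      adj <- bonferroni(p, m)
      expect_true(all(adj >= p))
      expect_true(all(adj <= 1))
      expect_equal(adj[p * m < 1], (p * m)[p * m < 1])
    }
  })
})

test_that("correlation matrices agree with the direct covariance formula", {
  withr::with_seed(8, {
    tab <- tibble::tibble(group = rep("g", 10), x = rnorm(10), y = rnorm(10))
    tab$z <- -tab$x
    cm <- correlation_matrix(tab, c("x", "y"), c("x", "y", "z"))
    expect_equal(cm$r["x", "x"], 1)
    expect_equal(cm$r["x", "z"], -1)
    r_hand <- sum((tab$x - mean(tab$x)) * (tab$y - mean(tab$y))) /
      sqrt(sum((tab$x - mean(tab$x))^2) * sum((tab$y - mean(tab$y))^2))
    expect_equal(cm$r["x", "y"], r_hand, tolerance = 1e-12)
    t_hand <- r_hand * sqrt(8 / (1 - r_hand^2))
    expect_equal(cm$p["x", "y"], 2 * pt(abs(t_hand), 8, lower.tail = FALSE),
                 tolerance = 1e-12)
    # degenerate variance flagged undefined
    tab$c <- 1
    cm2 <- correlation_matrix(tab, "x", "c")
    expect_true(is.na(cm2$r["x", "c"]))
  })
})

test_that("change-score Model 1 is the paired t-test and Model 2 matches normal equations", {
  rct <- generate_rct(default_variable_specs(), cohort_config(seed = 13))
  rct$leptin <- log10_transform(rct$leptin)
  for (a in unique(rct$arm)) {
    m1 <- prepost_change_model(rct, "leptin", 1, arm = a)
    bl <- rct[rct$arm == a & rct$timepoint == "baseline", ]
    fu <- rct[rct$arm == a & rct$timepoint == "followup", ]
    fu <- fu[match(bl$subject_id, fu$subject_id), ]
    tt <- t.test(fu$leptin, bl$leptin, paired = TRUE)
    expect_equal(m1$statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(m1$p_raw, tt$p.value, tolerance = 1e-10)
  }

  # all changes zero: statistic 0, p 1
  flat <- tibble::tibble(subject_id = rep(sprintf("s%d", 1:6), each = 2),
                         arm = "mrp",
                         timepoint = rep(c("baseline", "followup"), 6),
                         y = rep(c(3, 3), 6))
  m0 <- prepost_change_model(flat, "y", 1)
  expect_equal(m0$statistic, 0)
  expect_equal(m0$p_raw, 1)

  # Model 2 on an 8-pair toy vs an independently coded least-squares fit
  withr::with_seed(21, {
    n <- 8
    bl_w <- rnorm(n, 100, 10); d_w <- rnorm(n, -5, 2)
    dy <- rnorm(n, -0.2, 0.1)
    toy <- tibble::tibble(
      subject_id = rep(sprintf("s%d", 1:n), 2),
      arm = "mrp",
      timepoint = rep(c("baseline", "followup"), each = n),
      weight = c(bl_w, bl_w + d_w),
      y = c(rep(0, n), dy))
    m2 <- prepost_change_model(toy, "y", 2, weight_var = "weight")
    X <- cbind(1, d_w, bl_w)
    beta <- solve(t(X) %*% X, t(X) %*% dy)
    resid <- dy - X %*% beta
    s2 <- sum(resid^2) / (n - 3)
    se <- sqrt(s2 * solve(t(X) %*% X)[1, 1])
    expect_equal(m2$estimate, as.numeric(beta[1, 1]), tolerance = 1e-10)
    expect_equal(m2$statistic, as.numeric(beta[1, 1] / se), tolerance = 1e-10)
    expect_equal(m2$p_raw, as.numeric(2 * pt(abs(beta[1, 1] / se), n - 3, lower.tail = FALSE)),
                 tolerance = 1e-10)
  })

  expect_error(prepost_change_model(flat[1:2, ], "y", 2, weight_var = "y"),
               "not enough pairs")
})

test_that("the remission rule and HbA1c unit conversion are exact", {
  expect_true(classify_remission(6.0, 7.0, FALSE))
  expect_false(classify_remission(8.0, 6.0, TRUE))
  expect_true(classify_remission(8.0, 6.0, FALSE))   # HbA1c branch
  expect_false(classify_remission(7.0, 6.5, FALSE))  # strict inequalities
  expect_true(is.na(classify_remission(NA, NA, FALSE)))
  expect_true(classify_remission(NA, 6.0, FALSE))

  expect_equal(convert_hba1c(55.9, digits = 1), 7.3)
  expect_equal(convert_hba1c(35.3, digits = 1), 5.4)
  expect_equal(convert_hba1c(48.0, digits = 1), 6.5)
  expect_error(convert_hba1c(-1))
})
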