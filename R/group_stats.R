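#' Flag a variable as parametric or non-parametric
#'
#' Deterministic surrogate for the visual normality assessment used when
#' choosing between the t-test and the Mann-Whitney test: Shapiro-Wilk at
#' `alpha` (default 0.05). Overridable per variable in
#' [compare_case_control()].
#'
#' @param values Numeric vector with >= 3 non-missing, non-constant values.
#' @param alpha Significance level of the Shapiro-Wilk test.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
assess_normality <- function(values, alpha = 0.05) {
  v <- values[!is.na(values)]
  if (length(v) < 3L) stop("need at least 3 non-missing values", call. = FALSE)
  if (sd(v) == 0) stop("degenerate (constant) values", call. = FALSE)
  if (length(v) > 4999L) v <- v[seq_len(4999L)]  # shapiro.test n limit
  p <- stats::shapiro.test(v)$p.value
  if (p >= alpha) "parametric" else "nonparametric"
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` for a declared comparison count `m`; monotone in `p`
#' and never below the raw p-value.
#'
#' @param p Raw p-values.
#' @param m Number of comparisons.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m) pmin(1, p * m)

fmt_mean_sd <- function(x) sprintf("%.2f ± %.2f", mean(x, na.rm = TRUE), sd(x, na.rm = TRUE))
fmt_median_iqr <- function(x) sprintf("%.2f (%.2f)", stats::median(x, na.rm = TRUE),
                                      stats::IQR(x, na.rm = TRUE))
fmt_count_pct <- function(x) {
  n1 <- sum(x == 1, na.rm = TRUE)
  sprintf("%d (%.0f)", n1, 100 * n1 / sum(!is.na(x)))
}

#' Case-control comparisons across a variable panel
#'
#' For each variable applies the test matching its type: Welch (or
#' pooled) t-test for parametric continuous variables, Mann-Whitney for
#' non-parametric ones, Pearson chi-square on the 2 x c contingency table
#' for categorical ones. Normality is assessed on within-group-centred
#' residuals via [assess_normality()] unless overridden. P-values are
#' Bonferroni-adjusted with declared comparison count `m`.
#'
#' @param table Cohort tibble with a `group` column (exactly two groups).
#' @param variables Variables to test (default: all schema variables).
#' @param m Comparison count for the Bonferroni correction (default:
#'   number of variables actually tested).
#' @param test_override Named character vector forcing
#'   `"parametric"`/`"nonparametric"`/`"categorical"` per variable.
#' @param welch Use Welch's unequal-variance t-test (default `TRUE`).
#' @return A tibble, one row per variable: test used, per-group formatted
#'   summaries and numeric locations, statistic, `p_raw`, `p_adj`, `m`.
#'   Variables with fewer than 2 observations in a group are skipped with
#'   a warning.
#' @export
compare_case_control <- function(table, variables = NULL, m = NULL,
                                 test_override = NULL, welch = TRUE) {
  groups <- unique(table$group)
  if (length(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  if (is.null(variables)) {
    schema <- attr(table, "schema")
    variables <- if (!is.null(schema))
      vapply(schema$columns, `[[`, character(1), "name")
    else setdiff(names(table), c("subject_id", "group", "arm", "timepoint"))
  }
  schema <- attr(table, "schema")
  fam_of <- function(v) {
    if (!is.null(schema)) {
      for (c in schema$columns) if (c$name == v) return(c$family)
    }
    vals <- stats::na.omit(table[[v]])
    if (length(unique(vals)) <= 2L) "bernoulli" else "normal"
  }
  rows <- list()
  for (v in variables) {
    x1 <- table[[v]][table$group == groups[1L]]
    x2 <- table[[v]][table$group == groups[2L]]
    categorical <- identical(fam_of(v), "bernoulli")
    if (!categorical && (sum(!is.na(x1)) < 2L || sum(!is.na(x2)) < 2L)) {
      warning(sprintf("variable '%s' skipped: a group has < 2 observations", v))
      next
    }
    flag <- if (!is.null(test_override) && v %in% names(test_override))
      test_override[[v]]
    else if (categorical) "categorical"
    else {
      resid <- c(x1 - mean(x1, na.rm = TRUE), x2 - mean(x2, na.rm = TRUE))
      tryCatch(assess_normality(resid), error = function(e) "nonparametric")
    }
    if (flag == "categorical") {
      tab <- base::table(factor(table$group, levels = groups), table[[v]])
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      res <- tibble(variable = v, test = "chi-square",
                    summary_1 = fmt_count_pct(x1), summary_2 = fmt_count_pct(x2),
                    location_1 = mean(x1, na.rm = TRUE), location_2 = mean(x2, na.rm = TRUE),
                    statistic = unname(ht$statistic), p_raw = ht$p.value)
    } else if (flag == "parametric") {
      ht <- stats::t.test(x1, x2, var.equal = !welch)
      res <- tibble(variable = v, test = if (welch) "t (Welch)" else "t (pooled)",
                    summary_1 = fmt_mean_sd(x1), summary_2 = fmt_mean_sd(x2),
                    location_1 = mean(x1, na.rm = TRUE), location_2 = mean(x2, na.rm = TRUE),
                    statistic = unname(ht$statistic), p_raw = ht$p.value)
    } else {
      ht <- suppressWarnings(stats::wilcox.test(x1, x2, exact = FALSE))
      res <- tibble(variable = v, test = "Mann-Whitney",
                    summary_1 = fmt_median_iqr(x1), summary_2 = fmt_median_iqr(x2),
                    location_1 = stats::median(x1, na.rm = TRUE),
                    location_2 = stats::median(x2, na.rm = TRUE),
                    statistic = unname(ht$statistic), p_raw = ht$p.value)
    }
    rows[[v]] <- res
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L)
    return(tibble(variable = character(0), test = character(0),
                  statistic = numeric(0), p_raw = numeric(0),
                  p_adj = numeric(0), m = numeric(0)))
  if (is.null(m)) m <- nrow(out)
  out$p_adj <- bonferroni(out$p_raw, m)
  out$m <- m
  names(out)[names(out) == "summary_1"] <- paste0("summary_", groups[1L])
  names(out)[names(out) == "summary_2"] <- paste0("summary_", groups[2L])
  names(out)[names(out) == "location_1"] <- paste0("location_", groups[1L])
  names(out)[names(out) == "location_2"] <- paste0("location_", groups[2L])
  out
}

#' Pearson correlation matrix between two variable sets
#'
#' Pairwise-complete Pearson r with two-sided p for every (A, B) pair,
#' optionally within one group. Degenerate pairs (variance zero or fewer
#' than 3 complete pairs) are flagged `NA`.
#'
#' @param table Cohort tibble.
#' @param set_a,set_b Character vectors of column names.
#' @param group Optional group label to restrict to.
#' @return List of matrices `r`, `p`, `n` (complete-pair counts), rows =
#'   `set_a`, columns = `set_b`.
#' @export
correlation_matrix <- function(table, set_a, set_b, group = NULL) {
  if (!is.null(group)) table <- table[table$group == group, , drop = FALSE]
  r <- p <- n <- matrix(NA_real_, length(set_a), length(set_b),
                        dimnames = list(set_a, set_b))
  for (a in set_a) for (b in set_b) {
    x <- table[[a]]; y <- table[[b]]
    ok <- !is.na(x) & !is.na(y)
    n[a, b] <- sum(ok)
    if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    r[a, b] <- unname(ct$estimate)
    p[a, b] <- ct$p.value
  }
  list(r = r, p = p, n = n)
}

#' Within-arm pre/post change-score model
#'
#' Regresses the per-subject change `followup - baseline` of `variable`
#' on an intercept plus the model's covariates and reports the
#' intercept's two-sided test against zero:
#' * Model 1: intercept only (algebraically identical to the paired
#'   t-test);
#' * Model 2: adjusted for change in weight and baseline weight;
#' * Model 3: adjusted for change in HbA1c and baseline HbA1c.
#'
#' Values are modelled on the scale present in `table` (log10-transform
#' biomarkers first).
#'
#' @param table Trial tibble from [generate_rct()] (long format).
#' @param variable Outcome variable name.
#' @param model_id 1, 2 or 3.
#' @param arm Optional arm label to restrict to.
#' @param weight_var,hba1c_var Covariate column names for Models 2 and 3.
#' @param m Bonferroni comparison count (default 1).
#' @return One-row tibble: `variable`, `model`, `arm`, `n`, `estimate`
#'   (adjusted mean change), `statistic` (t), `df`, `p_raw`, `p_adj`,
#'   `covariates`.
#' @export
prepost_change_model <- function(table, variable, model_id = 1L, arm = NULL,
                                 weight_var = "weight", hba1c_var = "hba1c_mmol_mol",
                                 m = 1L) {
  stopifnot(model_id %in% 1:3)
  if (!is.null(arm)) table <- table[table$arm == arm, , drop = FALSE]
  bl <- table[table$timepoint == "baseline", , drop = FALSE]
  fu <- table[table$timepoint == "followup", , drop = FALSE]
  fu <- fu[match(bl$subject_id, fu$subject_id), , drop = FALSE]
  dy <- fu[[variable]] - bl[[variable]]
  covs <- switch(model_id,
                 `1` = NULL,
                 `2` = data.frame(delta_weight = fu[[weight_var]] - bl[[weight_var]],
                                  baseline_weight = bl[[weight_var]]),
                 `3` = data.frame(delta_hba1c = fu[[hba1c_var]] - bl[[hba1c_var]],
                                  baseline_hba1c = bl[[hba1c_var]]))
  dat <- data.frame(dy = dy)
  if (!is.null(covs)) dat <- cbind(dat, covs)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  p_cov <- ncol(dat) - 1L
  if (nrow(dat) - p_cov - 1L < 1L)
    stop("not enough pairs for the requested model", call. = FALSE)
  fit <- stats::lm(dy ~ ., data = dat)
  cf <- summary(fit)$coefficients["(Intercept)", ]
  if (!is.finite(cf["t value"])) {
    # degenerate fit (zero residual variance): report the sign of the
    # intercept directly rather than NaN
    est <- cf["Estimate"]
    cf["t value"] <- if (abs(est) < 1e-12) 0 else sign(est) * Inf
    cf["Pr(>|t|)"] <- if (abs(est) < 1e-12) 1 else 0
  }
  tibble(variable = variable, model = paste0("model", model_id),
         arm = if (is.null(arm)) NA_character_ else arm,
         n = nrow(dat), estimate = unname(cf["Estimate"]),
         statistic = unname(cf["t value"]), df = fit$df.residual,
         p_raw = unname(cf["Pr(>|t|)"]), p_adj = bonferroni(unname(cf["Pr(>|t|)"]), m),
         covariates = if (is.null(covs)) "" else paste(names(covs), collapse = " + "))
}

#' Run a change model over a biomarker panel
#'
#' Applies [prepost_change_model()] to each variable with a shared
#' Bonferroni count (default: panel size).
#'
#' @inheritParams prepost_change_model
#' @param variables Panel of outcome variables.
#' @return Tibble with one row per variable.
#' @export
prepost_panel <- function(table, variables, model_id = 1L, arm = NULL,
                          m = length(variables), ...) {
  dplyr::bind_rows(lapply(variables, function(v)
    prepost_change_model(table, v, model_id = model_id, arm = arm, m = m, ...)))
}

#' Classify type 2 diabetes remission
#'
#' Remission: fasting glucose < 7.0 mmol/L *or* HbA1c < 6.5%, without
#' glucose-lowering medication post-intervention. Vectorised; if both
#' measures are missing for a subject the result is `NA` (undetermined).
#'
#' @param fasting_glucose mmol/L.
#' @param hba1c_percent NGSP %.
#' @param on_glucose_lowering_meds Logical.
#' @return Logical vector.
#' @export
classify_remission <- function(fasting_glucose, hba1c_percent, on_glucose_lowering_meds) {
  n <- max(length(fasting_glucose), length(hba1c_percent), length(on_glucose_lowering_meds))
  g <- rep_len(fasting_glucose, n)
  h <- rep_len(hba1c_percent, n)
  med <- rep_len(as.logical(on_glucose_lowering_meds), n)
  crit <- ifelse(is.na(g) & is.na(h), NA,
                 (!is.na(g) & g < 7.0) | (!is.na(h) & h < 6.5))
  crit & !med
}

#' Convert HbA1c from IFCC to NGSP units
#'
#' Master equation: NGSP% = 0.09148 x IFCC(mmol/mol) + 2.152.
#'
#' @param ifcc_mmol_per_mol HbA1c in mmol/mol (> 0).
#' @param digits Optional rounding.
#' @return HbA1c in NGSP %.
#' @examples
#' convert_hba1c(55.9, digits = 1) # 7.3
#' @export
convert_hba1c <- function(ifcc_mmol_per_mol, digits = NULL) {
  stopifnot(all(ifcc_mmol_per_mol > 0))
  out <- 0.09148 * ifcc_mmol_per_mol + 2.152
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Biomarker panel summary on both scales
#'
#' Per-group log10 mean +/- SD with the corresponding back-transformed
#' geometric mean and geometric SD, plus the (Bonferroni-adjustable)
#' between-group t-test — the two-scale panel layout used for reporting
#' fibro-inflammatory markers.
#'
#' @param table Case-control tibble (natural-scale biomarker values).
#' @param biomarkers Biomarker column names.
#' @param m Bonferroni count (default panel size).
#' @return Tibble, one row per biomarker.
#' @export
summarize_biomarker_panel <- function(table, biomarkers, m = length(biomarkers)) {
  groups <- unique(table$group)
  stopifnot(length(groups) == 2L)
  rows <- lapply(biomarkers, function(v) {
    l1 <- log10_transform(table[[v]][table$group == groups[1L]])
    l2 <- log10_transform(table[[v]][table$group == groups[2L]])
    ht <- stats::t.test(l1, l2)
    b1 <- back_transform(mean(l1, na.rm = TRUE), sd(l1, na.rm = TRUE))
    b2 <- back_transform(mean(l2, na.rm = TRUE), sd(l2, na.rm = TRUE))
    tibble(biomarker = v,
           log10_1 = sprintf("%.2f ± %.2f", mean(l1, na.rm = TRUE), sd(l1, na.rm = TRUE)),
           back_1 = sprintf("%.2f ± %.2f", b1[1L], b1[2L]),
           log10_2 = sprintf("%.2f ± %.2f", mean(l2, na.rm = TRUE), sd(l2, na.rm = TRUE)),
           back_2 = sprintf("%.2f ± %.2f", b2[1L], b2[2L]),
           p_raw = ht$p.value, p_adj = bonferroni(ht$p.value, m))
  })
  out <- dplyr::bind_rows(rows)
  names(out) <- sub("_1$", paste0("_", groups[1L]), names(out))
  names(out) <- sub("_2$", paste0("_", groups[2L]), names(out))
  out
}
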