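#' Declarative description of one cohort variable
#'
#' A `variable_spec` states how a single subject-level variable is
#' distributed in each group of a cohort: its role in the analysis, its
#' distribution family, and per-group parameters on the *modelled* scale
#' (the log10 scale for `"log10normal"` variables, the natural scale for
#' `"normal"`, a success probability for `"bernoulli"`).
#'
#' @param name Variable name (syntactic identifier).
#' @param role One of `"demographic"`, `"clinical"`, `"anthropometric"`,
#'   `"mri"`, `"glycaemic"`, `"biomarker"`, `"categorical"`. Used to select
#'   variable subsets (e.g. biomarkers + demographics only).
#' @param family `"normal"`, `"log10normal"` or `"bernoulli"`.
#' @param params Named list, one entry per group label. For continuous
#'   families each entry is `c(location, scale)` on the modelled scale
#'   (`scale > 0`, or 0 for a degenerate point mass); for `"bernoulli"` a
#'   single probability in `[0, 1]`.
#' @param unit Free-text unit, e.g. `"pg/ml"`.
#'
#' @return An object of class `"variable_spec"`.
#' @seealso [default_variable_specs()], [generate_case_control()]
#' @export
variable_spec <- function(name, role, family, params, unit = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  role <- match.arg(role, c("demographic", "clinical", "anthropometric",
                            "mri", "glycaemic", "biomarker", "categorical"))
  family <- match.arg(family, c("normal", "log10normal", "bernoulli"))
  if (!is.list(params) || is.null(names(params)) || any(!nzchar(names(params))))
    stop("`params` must be a named list with one entry per group label", call. = FALSE)
  params <- lapply(params, function(p) {
    p <- as.numeric(p)
    if (family == "bernoulli") {
      if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
        stop(sprintf("bernoulli parameter for variable '%s' must be a probability in [0, 1]", name),
             call. = FALSE)
      c(prob = p)
    } else {
      if (length(p) != 2L || anyNA(p))
        stop(sprintf("continuous parameters for variable '%s' must be c(location, scale)", name),
             call. = FALSE)
      if (p[2L] < 0)
        stop(sprintf("negative scale for variable '%s'", name), call. = FALSE)
      c(location = p[1L], scale = p[2L])
    }
  })
  structure(list(name = name, role = role, family = family,
                 params = params, unit = unit),
            class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s [%s, %s]%s\n", x$name, x$role, x$family,
              if (nzchar(x$unit)) paste0(" (", x$unit, ")") else ""))
  for (g in names(x$params))
    cat(sprintf("  %-12s %s\n", g, paste(signif(x$params[[g]], 6), collapse = ", ")))
  invisible(x)
}

spec_names <- function(specs) vapply(specs, `[[`, character(1), "name")

spec_by_name <- function(specs, name) {
  i <- match(name, spec_names(specs))
  if (is.na(i)) stop(sprintf("no variable spec named '%s'", name), call. = FALSE)
  specs[[i]]
}

is_continuous <- function(spec) spec$family %in% c("normal", "log10normal")

#' Solve log10-normal parameters from a printed median and IQR
#'
#' Skewed clinical variables are often reported as median (IQR). Under a
#' base-10 log-normal model the median `m` fixes the location
#' `mu = log10(m)` and the IQR fixes the scale through
#' `IQR = m * (10^(z*sigma) - 10^(-z*sigma))` with `z = qnorm(0.75)`,
#' which has the closed-form solution `sigma = log10((r + sqrt(r^2 + 4)) / 2) / z`
#' for `r = IQR / m`.
#'
#' @param median Printed median (natural scale, > 0).
#' @param iqr Printed interquartile range (> 0).
#' @return `c(location, scale)` on the log10 scale.
#' @export
solve_log10normal_quartiles <- function(median, iqr) {
  stopifnot(median > 0, iqr > 0)
  z <- stats::qnorm(0.75)
  r <- iqr / median
  t <- (r + sqrt(r^2 + 4)) / 2
  c(location = log10(median), scale = log10(t) / z)
}

# Printed per-group log10 mean +/- SD for the 23 differentially reported
# plasma biomarkers (units pg/ml; healthy controls then T2D).
biomarker_param_table <- function() {
  tibble::tribble(
    ~name,         ~h_loc, ~h_scale, ~t_loc, ~t_scale,
    "galectin3",     3.79,   0.17,     3.74,   0.13,
    "mmp2",          5.49,   0.13,     5.40,   0.10,
    "mmp3",          4.09,   0.23,     3.93,   0.22,
    "mmp7",          3.33,   0.26,     3.52,   0.27,
    "mmp8",          2.09,   0.35,     2.28,   0.33,
    "pai1",          4.87,   0.26,     5.00,   0.17,
    "tenascin_c",    4.20,   0.19,     4.04,   0.17,
    "troponin_t",    1.75,   0.23,     1.64,   0.21,
    "ntproanp",      3.69,   0.39,     3.46,   0.31,
    "renin",         2.97,   0.50,     3.15,   0.43,
    "pentraxin3",    2.13,   0.42,     1.94,   0.46,
    "gdf15",         2.68,   0.33,     2.97,   0.25,
    "adiponectin",   3.91,   0.31,     3.58,   0.24,
    "leptin",        3.65,   0.42,     4.29,   0.35,
    "fabp4",         4.56,   0.36,     4.88,   0.22,
    "il6",           0.05,   0.05,     0.12,   0.12,
    "tnfr1",         3.40,   0.118,    3.49,   0.16,
    "tnfr2",         5.04,   0.25,     4.92,   0.24,
    "tnf_alpha",     0.40,   0.21,     0.52,   0.21,
    "ngal",          5.50,   0.16,     5.40,   0.16,
    "cystatin_c",    6.62,   0.23,     6.48,   0.23,
    "vegfr1",        1.25,   0.27,     1.11,   0.20,
    "vegfa",         1.42,   0.18,     1.53,   0.15
  )
}

#' Default variable specifications for the case-control cohort
#'
#' Returns the library of `variable_spec`s that defines the default
#' simulated study: demographics, anthropometrics, glycaemic indices,
#' cardiovascular MRI measures and a 23-marker fibro-inflammatory plasma
#' panel, with per-group parameters equal to the published per-group
#' summaries (mean +/- SD for approximately normal variables, median (IQR)
#' back-solved to log10-normal parameters for skewed ones, group
#' proportions for binary ones). Group labels are `"healthy"` and `"t2d"`.
#'
#' @param groups Character vector of the two group labels, in
#'   (control, case) order.
#' @return A list of [variable_spec()] objects.
#' @export
default_variable_specs <- function(groups = c("healthy", "t2d")) {
  stopifnot(length(groups) == 2L)
  h <- groups[1L]; t <- groups[2L]
  cont <- function(name, role, hm, hs, tm, ts, unit = "", family = "normal") {
    p <- stats::setNames(list(c(hm, hs), c(tm, ts)), c(h, t))
    variable_spec(name, role, family, p, unit)
  }
  skew <- function(name, role, h_med, h_iqr, t_med, t_iqr, unit = "") {
    p <- stats::setNames(list(solve_log10normal_quartiles(h_med, h_iqr),
                              solve_log10normal_quartiles(t_med, t_iqr)), c(h, t))
    variable_spec(name, role, "log10normal", p, unit)
  }
  bin <- function(name, hp, tp) {
    variable_spec(name, "categorical", "bernoulli",
                  stats::setNames(list(hp, tp), c(h, t)))
  }

  specs <- list(
    cont("age", "demographic", 48.6, 6.2, 50.5, 6.4, "years"),
    bin("sex_male", 19 / 36, 48 / 83),
    bin("ethnicity_white", 24 / 36, 50 / 83),
    bin("smoking_history", 9 / 36, 39 / 83),
    bin("hypertension", 0 / 36, 43 / 83),
    cont("hba1c_mmol_mol", "glycaemic", 35.3, 2.6, 55.9, 11.2, "mmol/mol"),
    cont("hba1c_percent", "glycaemic", 5.4, 0.2, 7.3, 1.0, "%"),
    cont("fasting_glucose", "glycaemic", 5.0, 0.5, 8.4, 2.4, "mmol/L"),
    skew("egfr", "clinical", 85.0, 13.4, 83.9, 9.6, "mL/min/1.73m2"),
    cont("urea", "clinical", 5.3, 1.4, 5.4, 1.2, "mmol/L"),
    cont("creatinine", "clinical", 78.6, 11.8, 75.5, 15.3, "umol/L"),
    cont("weight", "anthropometric", 70.4, 10.8, 102.4, 16.0, "kg"),
    cont("bmi", "anthropometric", 24.5, 2.4, 36.4, 5.4, "kg/m2"),
    cont("sbp", "clinical", 120.9, 13.2, 139.9, 15.6, "mmHg"),
    cont("dbp", "clinical", 76.4, 7.2, 87.6, 8.0, "mmHg"),
    cont("lvedv_indexed", "mri", 83.1, 18.6, 67.4, 10.6, "mL/m2"),
    cont("lv_ef", "mri", 65.2, 4.9, 68.2, 6.9, "%"),
    cont("lv_mass_indexed", "mri", 58.1, 13.6, 55.2, 9.0, "g/m2"),
    skew("lv_mass_volume", "mri", 0.70, 0.1, 0.83, 0.2, "g/mL"),
    cont("gls", "mri", 17.6, 1.5, 16.9, 2.6, "%"),
    cont("gcs", "mri", 19.7, 1.9, 20.3, 2.5, "%"),
    cont("pedsr_long", "mri", 0.86, 0.15, 0.83, 0.13, "1/s"),
    cont("pedsr_circ", "mri", 1.01, 0.19, 1.09, 0.16, "1/s"),
    skew("la_volume_indexed", "mri", 50.2, 18.1, 30.9, 9.4, "mL/m2"),
    cont("la_ef", "mri", 59.0, 7.2, 57.1, 8.4, "%"),
    skew("aortic_distensibility", "mri", 6.6, 2.0, 4.2, 2.1, "1/mmHg x 10-3"),
    cont("mpr", "mri", 4.0, 1.0, 3.1, 1.0, ""),
    skew("e_over_eprime", "mri", 6.2, 2.6, 8.0, 3.3, "")
  )

  bm <- biomarker_param_table()
  bm_specs <- lapply(seq_len(nrow(bm)), function(i) {
    p <- stats::setNames(list(c(bm$h_loc[i], bm$h_scale[i]),
                              c(bm$t_loc[i], bm$t_scale[i])), c(h, t))
    variable_spec(bm$name[i], "biomarker", "log10normal", p, "pg/ml")
  })
  c(specs, bm_specs)
}

#' Select variables by role
#'
#' @param specs List of [variable_spec()] objects.
#' @param roles Character vector of roles to keep.
#' @return The subset of `specs` with matching roles.
#' @export
select_specs <- function(specs, roles) {
  specs[vapply(specs, function(s) s$role %in% roles, logical(1))]
}
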