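#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm rbinom runif setNames sd
NULL

validate_specs_cover <- function(specs, groups) {
  for (s in specs) {
    missing <- setdiff(groups, names(s$params))
    if (length(missing))
      stop(sprintf("variable '%s' has no parameters for group(s): %s",
                   s$name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

schema_from_specs <- function(specs) {
  list(
    label_columns = c("subject_id", "group", "arm", "timepoint"),
    columns = lapply(specs, function(s)
      list(name = s$name, role = s$role, family = s$family, unit = s$unit))
  )
}

# Draw one column on the *natural* scale for group indices `idx`, given the
# modelled-scale parameters; `z` optionally supplies pre-correlated
# standard-normal deviates (correlation hook).
draw_column <- function(spec, group, n, z = NULL) {
  out <- numeric(n)
  for (g in unique(group)) {
    idx <- which(group == g)
    p <- spec$params[[g]]
    if (spec$family == "bernoulli") {
      out[idx] <- rbinom(length(idx), 1L, p[["prob"]])
    } else {
      dev <- if (is.null(z)) rnorm(length(idx)) else z[idx]
      val <- p[["location"]] + p[["scale"]] * dev
      out[idx] <- if (spec$family == "log10normal") 10^val else val
    }
  }
  out
}

# Pre-correlated standard normals for the variables named in cor_matrix,
# drawn per group so that the correlation holds within group.
correlated_deviates <- function(cor_matrix, group) {
  vars <- rownames(cor_matrix)
  L <- chol(cor_matrix)
  z <- matrix(NA_real_, length(group), length(vars), dimnames = list(NULL, vars))
  for (g in unique(group)) {
    idx <- which(group == g)
    raw <- matrix(rnorm(length(idx) * length(vars)), length(idx), length(vars))
    z[idx, ] <- raw %*% L
  }
  z
}

#' Generate a synthetic case-control cohort
#'
#' Draws one row per subject with each variable sampled independently (or
#' via the optional correlation hook) from its declared per-group
#' distribution. Log10-normal variables are emitted on the natural
#' (back-transformed) scale; the modelled parameters refer to the log10
#' scale.
#'
#' @param specs List of [variable_spec()]s covering every group label.
#' @param config A [cohort_config()] (or list coercible to one).
#' @return A tibble with columns `subject_id`, `group`, then one column
#'   per variable, carrying the generating schema as attribute
#'   `"schema"`. Deterministic given `(specs, config)`.
#' @examples
#' cohort <- generate_case_control(default_variable_specs(), cohort_config(seed = 7))
#' table(cohort$group)
#' @export
generate_case_control <- function(specs, config = cohort_config()) {
  config <- as_cohort_config(config)
  groups <- names(config$group_sizes)
  validate_specs_cover(specs, groups)
  n <- sum(config$group_sizes)
  group <- rep(groups, times = config$group_sizes)
  withr::with_seed(config$seed, {
    z <- if (!is.null(config$cor_matrix)) correlated_deviates(config$cor_matrix, group)
    cols <- lapply(specs, function(s) {
      zi <- if (!is.null(z) && s$name %in% colnames(z) && is_continuous(s)) z[, s$name]
      draw_column(s, group, n, zi)
    })
  })
  tbl <- tibble(subject_id = sprintf("S%03d", seq_len(n)), group = group)
  tbl[spec_names(specs)] <- cols
  attr(tbl, "schema") <- schema_from_specs(specs)
  tbl
}

#' Generate a synthetic three-arm pre/post trial cohort
#'
#' Each subject gets a baseline row drawn from the baseline group's
#' parameters and a follow-up row correlated with baseline (correlation
#' `within_subject_corr` per variable on the modelled scale) plus the
#' arm-specific additive effect. Binary variables are drawn at baseline
#' and carried forward. With `rho = 1` and zero effects the follow-up
#' equals the baseline exactly.
#'
#' @inheritParams generate_case_control
#' @return A tibble with columns `subject_id`, `group`, `arm`,
#'   `timepoint` (`"baseline"`/`"followup"`), then one column per
#'   variable; two rows per subject, schema attached as for
#'   [generate_case_control()].
#' @examples
#' rct <- generate_rct(default_variable_specs(), cohort_config(seed = 7))
#' nrow(rct) # 2 x (30 + 24 + 22)
#' @export
generate_rct <- function(specs, config = cohort_config()) {
  config <- as_cohort_config(config)
  bg <- config$baseline_group
  validate_specs_cover(specs, bg)
  effects <- config$arm_effects
  if (is.null(effects)) {
    effects <- default_arm_effects(specs)
    effects <- effects[intersect(names(effects), names(config$arm_sizes))]
  }
  bad_arms <- setdiff(names(effects), names(config$arm_sizes))
  if (length(bad_arms))
    stop("unknown arm label(s) in arm effects: ", paste(bad_arms, collapse = ", "),
         call. = FALSE)
  for (a in names(effects)) {
    bad <- setdiff(names(effects[[a]]), spec_names(specs))
    if (length(bad))
      stop(sprintf("arm '%s' effect names not in specs: %s", a,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  arms <- names(config$arm_sizes)
  n <- sum(config$arm_sizes)
  arm <- rep(arms, times = config$arm_sizes)
  rho <- config$within_subject_corr
  withr::with_seed(config$seed, {
    base_cols <- list(); fu_cols <- list()
    for (s in specs) {
      p <- s$params[[bg]]
      shift <- unname(vapply(arm, function(a) {
        e <- effects[[a]]
        if (!is.null(e) && s$name %in% names(e)) e[[s$name]] else 0
      }, numeric(1)))
      if (s$family == "bernoulli") {
        b <- rbinom(n, 1L, p[["prob"]])
        base_cols[[s$name]] <- b
        fu_cols[[s$name]] <- b
      } else {
        y1 <- p[["location"]] + p[["scale"]] * rnorm(n)
        eps <- rnorm(n)
        y2 <- p[["location"]] + rho * (y1 - p[["location"]]) +
          sqrt(1 - rho^2) * p[["scale"]] * eps + shift
        if (s$family == "log10normal") { y1 <- 10^y1; y2 <- 10^y2 }
        base_cols[[s$name]] <- y1
        fu_cols[[s$name]] <- y2
      }
    }
  })
  ids <- sprintf("R%03d", seq_len(n))
  half <- function(cols, tp) {
    tbl <- tibble(subject_id = ids, group = bg, arm = arm, timepoint = tp)
    tbl[names(cols)] <- cols
    tbl
  }
  out <- dplyr::bind_rows(half(base_cols, "baseline"), half(fu_cols, "followup"))
  out <- dplyr::arrange(out, .data$subject_id, .data$timepoint)
  attr(out, "schema") <- schema_from_specs(specs)
  out
}

continuous_columns <- function(table) {
  schema <- attr(table, "schema")
  labels <- c("subject_id", "group", "arm", "timepoint")
  if (!is.null(schema)) {
    keep <- vapply(schema$columns, function(c)
      c$family %in% c("normal", "log10normal"), logical(1))
    cols <- vapply(schema$columns, `[[`, character(1), "name")[keep]
    return(intersect(cols, names(table)))
  }
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  num <- setdiff(num, labels)
  # without a schema, treat 0/1 columns as categorical
  num[vapply(table[num], function(x) length(unique(stats::na.omit(x))) > 2, logical(1))]
}

#' Inject missing-completely-at-random values
#'
#' Masks each eligible cell independently with probability `rate`, and
#' returns the masked table together with a mask recording the original
#' values so imputation error can be scored ([restore_masked()] undoes the
#' masking exactly). Label columns (`subject_id`, `group`, `arm`,
#' `timepoint`) and non-continuous variables are never masked.
#'
#' @param table A cohort tibble from the generators (or any tibble).
#' @param rate Masking probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param columns Columns eligible for masking; default: all continuous
#'   variables per the table's schema.
#' @return A list with elements `data` (the masked tibble) and `mask`
#'   (tibble of `row`, `column`, `value` for each masked cell).
#' @export
inject_missingness <- function(table, rate, seed = 1L, columns = NULL) {
  if (rate < 0 || rate >= 1) stop("`rate` must lie in [0, 1)", call. = FALSE)
  if (is.null(columns)) columns <- continuous_columns(table)
  labels <- intersect(c("subject_id", "group", "arm", "timepoint"), names(table))
  if (length(intersect(columns, labels)))
    stop("label columns cannot be masked", call. = FALSE)
  bad <- setdiff(columns, names(table))
  if (length(bad)) stop("unknown column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  masked <- list()
  withr::with_seed(seed, {
    for (col in columns) {
      hit <- which(runif(nrow(table)) < rate & !is.na(table[[col]]))
      if (length(hit)) {
        masked[[col]] <- tibble(row = hit, column = col, value = table[[col]][hit])
        table[[col]][hit] <- NA_real_
      }
    }
  })
  mask <- if (length(masked)) dplyr::bind_rows(masked) else
    tibble(row = integer(0), column = character(0), value = numeric(0))
  list(data = table, mask = mask)
}

#' Restore masked cells from an injection mask
#'
#' @param table Masked tibble from [inject_missingness()].
#' @param mask The companion mask tibble.
#' @return The tibble with every masked cell restored to its original value.
#' @export
restore_masked <- function(table, mask) {
  for (i in seq_len(nrow(mask)))
    table[[mask$column[i]]][mask$row[i]] <- mask$value[i]
  table
}
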