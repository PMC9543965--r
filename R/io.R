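#' Write a cohort table with a sidecar schema
#'
#' The CSV dialect is UTF-8, comma-separated, with missing values encoded
#' as empty fields; the JSON sidecar names role, family and unit per
#' column so the table can be re-typed on read.
#'
#' @param table Cohort tibble carrying a `"schema"` attribute (as
#'   produced by the generators), or provide `specs`.
#' @param csv_path,schema_path Output paths.
#' @param specs Optional list of [variable_spec()]s overriding the
#'   attached schema.
#' @return Invisibly, the paths.
#' @export
write_cohort <- function(table, csv_path, schema_path, specs = NULL) {
  schema <- if (!is.null(specs)) schema_from_specs(specs) else attr(table, "schema")
  if (is.null(schema)) stop("no schema: supply `specs`", call. = FALSE)
  utils::write.csv(table, csv_path, row.names = FALSE, na = "")
  jsonlite::write_json(schema, schema_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv = csv_path, schema = schema_path))
}

#' Read a cohort table against its schema
#'
#' Validates that the CSV header matches the schema's variable list plus
#' the label columns, types each column per its family (empty fields
#' become `NA`), and errors with the offending location on any
#' non-numeric cell in a numeric column.
#'
#' @param csv_path,schema_path Paths written by [write_cohort()].
#' @return A typed tibble with the schema attached.
#' @export
read_cohort <- function(csv_path, schema_path) {
  schema <- jsonlite::read_json(schema_path, simplifyVector = FALSE)
  raw <- utils::read.csv(csv_path, colClasses = "character", check.names = FALSE,
                         na.strings = "")
  vars <- vapply(schema$columns, function(c) c$name, character(1))
  labels <- intersect(unlist(schema$label_columns), names(raw))
  expected <- c(labels, vars)
  extra <- setdiff(names(raw), expected)
  missing <- setdiff(expected, names(raw))
  if (length(extra) || length(missing))
    stop("header/schema mismatch; ",
         if (length(missing)) paste0("missing: ", paste(missing, collapse = ", "), "; "),
         if (length(extra)) paste0("unexpected: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  out <- tibble::as_tibble(raw[expected])
  for (c in schema$columns) {
    x <- out[[c$name]]
    num <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell in column '%s', row %d: '%s'",
                   c$name, bad[1L], x[bad[1L]]), call. = FALSE)
    out[[c$name]] <- if (identical(c$family, "bernoulli")) as.integer(num) else num
  }
  attr(out, "schema") <- schema
  out
}

config_hash <- function(obj) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

# Assemble the standardized analysis matrix used by both embeddings:
# log10 the log10normal-family variables, keep the rest as-is, and select
# the variable set.
analysis_matrix <- function(table, specs,
                            variable_set = c("full", "biomarkers_demographics"),
                            include_binary = TRUE) {
  variable_set <- match.arg(variable_set)
  if (variable_set == "biomarkers_demographics")
    specs <- select_specs(specs, c("biomarker", "demographic", "categorical",
                                   "anthropometric", "glycaemic"))
  if (!include_binary)
    specs <- specs[vapply(specs, is_continuous, logical(1))]
  x <- as.matrix(table[spec_names(specs)])
  for (s in specs)
    if (s$family == "log10normal") x[, s$name] <- log10_transform(x[, s$name])
  x
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Orchestrates the stages in order — simulate (or read), log10-transform
#' biomarkers, standardise, optionally inject and impute missingness,
#' case-control comparisons, 3-D PCA with best-fit plane, and per-arm
#' Fisher planes against the healthy-control centre — and writes a
#' deterministic bundle: `comparisons.csv`, `biomarker_panel.csv`,
#' `pca.json`, `fisher_<arm>.json`, an `imputation.json` report when
#' missingness was injected, optional figures, and `run_log.json`
#' capturing the seed, configuration hash, k, lambda and variable set.
#'
#' @param config List of options: `seed` (default 1), `specs`,
#'   `cohort` / `rct` (optional pre-built tibbles; otherwise simulated),
#'   `missing_rate` (default 0), `k` (kNN neighbours, default 5),
#'   `lambda` (Fisher ridge, `NULL` = default ridge), `variable_set`
#'   (`"full"` or `"biomarkers_demographics"`), `make_figures`
#'   (default `FALSE`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`comparisons`,
#'   `panel`, `pca`, `plane` fit, `fisher` per arm, `imputation`,
#'   `log`).
#' @export
run_report <- function(config = list(), out_dir) {
  cfg <- utils::modifyList(list(seed = 1L, missing_rate = 0, k = 5L,
                                lambda = NULL, variable_set = "full",
                                make_figures = FALSE), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  specs <- cfg$specs
  if (is.null(specs)) specs <- default_variable_specs()
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))

  cohort <- if (!is.null(cfg$cohort)) cfg$cohort else
    stage("simulate", generate_case_control(specs, cohort_config(seed = cfg$seed)))
  rct <- if (!is.null(cfg$rct)) cfg$rct else
    stage("simulate", generate_rct(specs, cohort_config(seed = cfg$seed + 1L)))

  comparisons <- stage("compare", compare_case_control(cohort))
  bm <- spec_names(select_specs(specs, "biomarker"))
  panel <- stage("compare", summarize_biomarker_panel(cohort, bm))

  x <- stage("prep", analysis_matrix(cohort, specs, cfg$variable_set))
  imputation <- NULL
  if (cfg$missing_rate > 0) {
    inj <- stage("prep", inject_missingness(tibble::as_tibble(x), cfg$missing_rate,
                                            seed = cfg$seed + 2L,
                                            columns = colnames(x)))
    std <- stage("prep", fit_standardizer(inj$data))
    z <- stage("prep", apply_standardizer(std, inj$data))
    imp <- stage("impute", knn_impute(z, k = cfg$k))
    z <- imp$data
    imputation <- imp$report
  } else {
    std <- stage("prep", fit_standardizer(x))
    z <- stage("prep", apply_standardizer(std, x))
  }

  pca <- stage("embed", pca_svd(z, 3L, groups = cohort$group))
  plane <- stage("embed", best_fit_plane(pca$scores))

  groups <- unique(cohort$group)
  healthy_label <- groups[1L]
  xr <- stage("prep", analysis_matrix(rct, specs, cfg$variable_set))
  zr <- stage("prep", apply_standardizer(std, xr))
  zh <- z[cohort$group == healthy_label, , drop = FALSE]
  center_healthy <- colMeans(zh)
  fisher <- list()
  for (a in unique(rct$arm)) {
    pre <- zr[rct$arm == a & rct$timepoint == "baseline", , drop = FALSE]
    post <- zr[rct$arm == a & rct$timepoint == "followup", , drop = FALSE]
    fisher[[a]] <- stage("embed", fisher_plane(pre, post, center_healthy, cfg$lambda))
  }

  utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"), row.names = FALSE)
  utils::write.csv(panel, file.path(out_dir, "biomarker_panel.csv"), row.names = FALSE)
  log <- list(seed = cfg$seed,
              config_hash = config_hash(cfg[setdiff(names(cfg), c("specs", "cohort", "rct"))]),
              k = cfg$k,
              lambda = if (is.null(cfg$lambda)) "default" else cfg$lambda,
              variable_set = cfg$variable_set,
              missing_rate = cfg$missing_rate,
              n_case_control = nrow(cohort), n_rct_rows = nrow(rct),
              package_version = as.character(utils::packageVersion("fibrolens")))
  jsonlite::write_json(c(log["seed"], log["config_hash"], list(
    pca = list(var_explained = pca$var_explained[1:3],
               eigenvalues = pca$eigenvalues[1:3],
               centers = pca$centers,
               plane_normal = plane$normal,
               plane_point = plane$point)
  )), file.path(out_dir, "pca.json"), auto_unbox = TRUE, digits = NA)
  for (a in names(fisher)) {
    fp <- fisher[[a]]
    jsonlite::write_json(c(log["seed"], log["config_hash"], list(
      u = fp$u, v = fp$v, centers = fp$centers, threshold = fp$threshold,
      accuracy = fp$accuracy, lambda = fp$lambda
    )), file.path(out_dir, paste0("fisher_", a, ".json")),
    auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(imputation))
    jsonlite::write_json(c(log["seed"], log["config_hash"], list(
      k = imputation$k, metric = imputation$metric,
      n_imputed = nrow(imputation$imputed),
      fallback_count = imputation$fallback_count,
      cells = imputation$imputed[c("row", "column", "value", "n_neighbors")]
    )), file.path(out_dir, "imputation.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  if (isTRUE(cfg$make_figures)) {
    ggplot2::ggsave(file.path(out_dir, "pca_scores.png"),
                    plot_embedding(pca, cohort$group), width = 7, height = 4, dpi = 120)
    for (a in names(fisher))
      ggplot2::ggsave(file.path(out_dir, paste0("fisher_", a, ".png")),
                      plot_fisher_plane(fisher[[a]]), width = 5, height = 4, dpi = 120)
  }
  invisible(list(comparisons = comparisons, panel = panel, pca = pca,
                 plane = plane, fisher = fisher, imputation = imputation,
                 standardizer = std, log = log))
}

#' Plot PCA score projections
#'
#' PC1-PC2 and PC1-PC3 panels of the 3-D embedding, coloured by group.
#'
#' @param pca A `"pca_embedding"`.
#' @param groups Group labels, one per score row.
#' @return A ggplot object.
#' @export
plot_embedding <- function(pca, groups) {
  s <- tibble::as_tibble(pca$scores)
  df <- dplyr::bind_rows(
    tibble::tibble(h = s$PC1, v = s$PC2, panel = "PC1 vs PC2", group = groups),
    tibble::tibble(h = s$PC1, v = s$PC3, panel = "PC1 vs PC3", group = groups))
  pct <- 100 * pca$var_explained[1:3]
  ggplot2::ggplot(df, ggplot2::aes(.data$h, .data$v, colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pct[1L]),
                  y = sprintf("PC2 / PC3 (%.1f%% / %.1f%%)", pct[2L], pct[3L]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Fisher-discriminant plane
#'
#' Pre/post subject projections with the three group centres and the
#' classification threshold.
#'
#' @param fp A `"fisher_plane"`.
#' @return A ggplot object.
#' @export
plot_fisher_plane <- function(fp) {
  ctr <- tibble::tibble(x = fp$centers[, "x"], y = fp$centers[, "y"],
                        group = rownames(fp$centers))
  ggplot2::ggplot(fp$coords, ggplot2::aes(.data$x, .data$y, colour = .data$phase)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = fp$threshold, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(data = ctr, ggplot2::aes(shape = .data$group),
                        colour = "black", size = 3, inherit.aes = FALSE,
                        mapping = ggplot2::aes(.data$x, .data$y, shape = .data$group)) +
    ggplot2::labs(x = "Fisher axis u", y = "healthy-anchor axis v",
                  subtitle = sprintf("resubstitution accuracy %.0f%%", 100 * fp$accuracy)) +
    ggplot2::theme_minimal()
}
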