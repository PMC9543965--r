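#' Log10-transform a biomarker block
#'
#' Plasma biomarker concentrations are analysed on the log10 scale.
#' Missing values stay missing; any non-positive value is an error naming
#' its position.
#'
#' @param values Numeric vector, matrix or data frame of positive values.
#' @return The same shape, log10-transformed.
#' @export
log10_transform <- function(values) {
  check_block <- function(x, label = NULL) {
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad)) {
      where <- if (is.matrix(x)) {
        rc <- arrayInd(bad[1L], dim(x))
        sprintf("row %d, column %s", rc[1L],
                if (!is.null(colnames(x))) colnames(x)[rc[2L]] else rc[2L])
      } else if (!is.null(label)) {
        sprintf("column %s, row %d", label, bad[1L])
      } else sprintf("position %d", bad[1L])
      stop("non-positive value at ", where, call. = FALSE)
    }
  }
  if (is.data.frame(values)) {
    for (nm in names(values)) {
      if (!is.numeric(values[[nm]])) next
      check_block(values[[nm]], nm)
      values[[nm]] <- log10(values[[nm]])
    }
    return(values)
  }
  check_block(values)
  log10(values)
}

#' Back-transform log10 summaries to geometric mean and geometric SD
#'
#' A mean +/- SD computed on the log10 scale corresponds on the natural
#' scale to a geometric mean `10^mean` with multiplicative (geometric)
#' spread `10^sd`.
#'
#' @param log10_mean Mean on the log10 scale.
#' @param log10_sd SD on the log10 scale.
#' @return Named numeric `c(geometric_mean, geometric_sd)` (vectorised).
#' @examples
#' back_transform(3.79, 0.17) # c(6165.95, 1.48) at 2 dp
#' @export
back_transform <- function(log10_mean, log10_sd) {
  stopifnot(is.finite(log10_mean), is.finite(log10_sd))
  if (length(log10_mean) == 1L && length(log10_sd) == 1L)
    c(geometric_mean = 10^log10_mean, geometric_sd = 10^log10_sd)
  else
    cbind(geometric_mean = 10^log10_mean, geometric_sd = 10^log10_sd)
}

#' Fit a z-standardisation model
#'
#' Computes per-column means and sample (n-1) SDs on a fit set, ignoring
#' missing entries. Zero-variance columns are reported in the model and
#' dropped from the retained column set rather than silently divided by
#' zero.
#'
#' @param x Numeric matrix or all-numeric data frame with >= 2 rows.
#' @return An object of class `"standardizer"` with elements `center`,
#'   `scale`, `columns` (retained) and `dropped`.
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2L, is.numeric(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  center <- colMeans(x, na.rm = TRUE)
  scale <- apply(x, 2L, sd, na.rm = TRUE)
  ok <- is.finite(scale) & scale > 0
  structure(list(center = center[ok], scale = scale[ok],
                 columns = colnames(x)[ok], dropped = colnames(x)[!ok]),
            class = "standardizer")
}

#' Apply a standardisation model
#'
#' @param model A `"standardizer"` from [fit_standardizer()].
#' @param x Matrix or data frame containing at least the model's retained
#'   columns.
#' @return Matrix of z-scores over the retained columns, in model column
#'   order.
#' @export
apply_standardizer <- function(model, x) {
  stopifnot(inherits(model, "standardizer"))
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) == length(model$columns))
    colnames(x) <- model$columns
  missing <- setdiff(model$columns, colnames(x))
  if (length(missing))
    stop("columns absent from data: ", paste(missing, collapse = ", "), call. = FALSE)
  x <- x[, model$columns, drop = FALSE]
  sweep(sweep(x, 2L, model$center), 2L, model$scale, `/`)
}

#' @export
print.standardizer <- function(x, ...) {
  cat(sprintf("<standardizer> %d column(s) retained", length(x$columns)))
  if (length(x$dropped))
    cat(sprintf(", %d zero-variance dropped (%s)", length(x$dropped),
                paste(x$dropped, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' k-nearest-neighbour imputation
#'
#' Fills each missing cell with the unweighted mean of the target column
#' among the `k` nearest rows. Distance between two rows is the mean
#' squared difference over the columns observed in *both* rows, which
#' keeps rows with different missingness patterns comparable; eligible
#' neighbours must have the target column observed. Ties are broken by
#' the lower row index. If fewer than `k` eligible neighbours exist all
#' available ones are used; if none, the observed column mean is used and
#' the fallback is counted. The matrix should be standardised (or at
#' least scale-homogeneous) first, since the distance is Euclidean in
#' nature.
#'
#' @param x Numeric matrix (z-scores), possibly with `NA`s.
#' @param k Number of neighbours (default 5).
#' @return A list with the completed `data` matrix and a `report` (class
#'   `"imputation_report"`) listing each imputed position, the neighbour
#'   rows used, `k`, the distance metric name, and the fallback count.
#'   Observed entries are never altered.
#' @export
knn_impute <- function(x, k = 5L) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x), k >= 1L)
  obs <- !is.na(x)
  if (any(colSums(obs) == 0L)) {
    bad <- which(colSums(obs) == 0L)
    nm <- if (!is.null(colnames(x))) colnames(x)[bad] else bad
    stop("fully-missing column(s): ", paste(nm, collapse = ", "), call. = FALSE)
  }
  col_means <- colMeans(x, na.rm = TRUE)
  need <- which(rowSums(!obs) > 0L)
  entries <- list(); fallback_count <- 0L
  x0 <- x
  for (i in need) {
    d <- rep(Inf, nrow(x0))
    for (j in seq_len(nrow(x0))) {
      if (j == i) next
      shared <- obs[i, ] & obs[j, ]
      ns <- sum(shared)
      if (ns > 0L) d[j] <- sum((x0[i, shared] - x0[j, shared])^2) / ns
    }
    for (cc in which(!obs[i, ])) {
      elig <- which(obs[, cc] & is.finite(d))
      if (length(elig)) {
        elig <- elig[order(d[elig], elig)]
        nb <- elig[seq_len(min(k, length(elig)))]
        val <- mean(x0[nb, cc])
        fb <- FALSE
      } else {
        nb <- integer(0)
        val <- col_means[cc]
        fb <- TRUE
        fallback_count <- fallback_count + 1L
      }
      x[i, cc] <- val
      entries[[length(entries) + 1L]] <- tibble(
        row = i, col = cc,
        column = if (!is.null(colnames(x))) colnames(x)[cc] else as.character(cc),
        value = val, n_neighbors = length(nb),
        neighbors = list(nb), fallback = fb)
    }
  }
  report <- structure(list(
    imputed = if (length(entries)) dplyr::bind_rows(entries) else
      tibble(row = integer(0), col = integer(0), column = character(0),
             value = numeric(0), n_neighbors = integer(0),
             neighbors = list(), fallback = logical(0)),
    k = as.integer(k),
    metric = "mean squared difference over shared observed columns",
    fallback_count = fallback_count), class = "imputation_report")
  list(data = x, report = report)
}

#' @export
print.imputation_report <- function(x, ...) {
  cat(sprintf("<imputation_report> %d cell(s) imputed, k = %d, %d fallback(s)\n",
              nrow(x$imputed), x$k, x$fallback_count))
  invisible(x)
}
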