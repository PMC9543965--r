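#' Principal component analysis via singular value decomposition
#'
#' Columns are mean-centred, the SVD taken, and the covariance
#' eigenvalues recovered as squared singular values divided by `n - 1`.
#' Scores are the projections of the centred rows onto the right singular
#' vectors; variance-explained fractions are eigenvalue / trace. Axis
#' signs are fixed (largest-magnitude loading positive) so results are
#' reproducible across runs.
#'
#' @param x Complete numeric matrix of standardised variables (impute
#'   first; missing entries are an error), rows >= `n_components + 1`.
#' @param n_components Number of leading components to keep (default 3).
#' @param groups Optional group labels (length `nrow(x)`) for which score
#'   centres are returned.
#' @return Object of class `"pca_embedding"`: `axes` (p x k, orthonormal
#'   columns), `eigenvalues` (all, non-increasing), `var_explained`
#'   (all), `scores` (n x k), `centers` (per-group score means, or
#'   `NULL`), `column_means`.
#' @export
pca_svd <- function(x, n_components = 3L, groups = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing entries: impute before PCA", call. = FALSE)
  n <- nrow(x)
  stopifnot(n >= n_components + 1L)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  s <- svd(xc)
  eig <- s$d^2 / (n - 1L)
  rank <- sum(s$d > max(s$d) * 1e-10)
  if (n_components > rank)
    stop(sprintf("n_components (%d) exceeds matrix rank (%d)", n_components, rank),
         call. = FALSE)
  v <- s$v[, seq_len(n_components), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  scores <- xc %*% v
  colnames(scores) <- colnames(v) <- paste0("PC", seq_len(n_components))
  rownames(v) <- colnames(x)
  centers <- NULL
  if (!is.null(groups)) {
    stopifnot(length(groups) == n)
    centers <- do.call(rbind, lapply(split(seq_len(n), groups), function(idx)
      colMeans(scores[idx, , drop = FALSE])))
  }
  structure(list(axes = v, eigenvalues = eig, var_explained = eig / sum(eig),
                 scores = scores, centers = centers, column_means = mu,
                 n_components = as.integer(n_components)),
            class = "pca_embedding")
}

#' @export
print.pca_embedding <- function(x, ...) {
  k <- x$n_components
  cat(sprintf("<pca_embedding> %d component(s); variance explained: %s\n", k,
              paste(sprintf("%.2f%%", 100 * x$var_explained[seq_len(k)]), collapse = ", ")))
  invisible(x)
}

#' Least-squares best-fit plane through 3-D points
#'
#' The plane passes through the centroid and is spanned by the top two
#' principal directions of the points; the normal is the third. Points
#' that are (numerically) collinear give a degenerate flag instead of an
#' arbitrary plane.
#'
#' @param scores n x 3 matrix of 3-D coordinates, n >= 3.
#' @return List: `point` (centroid), `normal` (unit), `basis` (3 x 2
#'   in-plane directions), `degenerate` (logical).
#' @export
best_fit_plane <- function(scores) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 3L, nrow(scores) >= 3L)
  ctr <- colMeans(scores)
  s <- svd(sweep(scores, 2L, ctr))
  degenerate <- s$d[2L] <= max(s$d[1L], 1) * 1e-10
  normal <- s$v[, 3L]
  i <- which.max(abs(normal))
  if (normal[i] < 0) normal <- -normal
  list(point = ctr, normal = normal, basis = s$v[, 1:2, drop = FALSE],
       degenerate = degenerate)
}

within_class_scatter <- function(x, labels) {
  Sw <- matrix(0, ncol(x), ncol(x))
  for (g in unique(labels)) {
    xg <- x[labels == g, , drop = FALSE]
    xg <- sweep(xg, 2L, colMeans(xg))
    Sw <- Sw + crossprod(xg)
  }
  Sw
}

default_ridge <- function(Sw) 1e-3 * sum(diag(Sw)) / ncol(Sw)

#' Fisher's linear discriminant direction
#'
#' Maximises the between-class to within-class variance ratio:
#' `w` proportional to `solve(Sw + lambda * I, m2 - m1)` where `Sw` is the pooled
#' within-class scatter and `lambda >= 0` ridges the small-n /
#' high-dimension case. The returned vector has unit length with the sign
#' fixed so that the *second* class (second factor level of `labels`)
#' projects to the larger mean.
#'
#' @param x Numeric matrix of standardised variables.
#' @param labels Two-class labels (each class >= 2 rows).
#' @param lambda Ridge; `NULL` (default) uses `1e-3 * trace(Sw) / p`.
#'   `lambda = 0` with a singular scatter is an error instructing
#'   regularisation.
#' @return Unit vector with attributes `lambda` and `classes`.
#' @export
fisher_direction <- function(x, labels, lambda = NULL) {
  x <- as.matrix(x)
  labels <- factor(labels)
  cls <- levels(labels)
  if (length(cls) != 2L) stop("exactly two classes required", call. = FALSE)
  if (any(table(labels) < 2L)) stop("each class needs >= 2 rows", call. = FALSE)
  m1 <- colMeans(x[labels == cls[1L], , drop = FALSE])
  m2 <- colMeans(x[labels == cls[2L], , drop = FALSE])
  Sw <- within_class_scatter(x, labels)
  if (is.null(lambda)) lambda <- default_ridge(Sw)
  A <- Sw + diag(lambda, ncol(x))
  w <- tryCatch(solve(A, m2 - m1), error = function(e)
    stop("within-class scatter is singular; use lambda > 0 to regularize",
         call. = FALSE))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-300) stop("degenerate discriminant: identical class means", call. = FALSE)
  w <- w / nw
  if (sum(m2 * w) < sum(m1 * w)) w <- -w
  attr(w, "lambda") <- lambda
  attr(w, "classes") <- cls
  w
}

#' Resubstitution classification accuracy of thresholded scores
#'
#' Fraction of rows on the correct side of `threshold`, with the class
#' whose mean score is larger assigned to scores above the threshold.
#' Ties (scores exactly at the threshold) go to the class whose mean is
#' nearer the threshold (deterministic).
#'
#' @param scores Numeric vector of discriminant scores.
#' @param labels Two-class labels.
#' @param threshold Decision threshold (default: midpoint of the class
#'   mean scores).
#' @return Accuracy in `[0, 1]`.
#' @export
classification_accuracy <- function(scores, labels, threshold = NULL) {
  labels <- factor(labels)
  cls <- levels(labels)
  if (length(cls) != 2L) stop("exactly two classes required", call. = FALSE)
  mu <- vapply(cls, function(g) mean(scores[labels == g]), numeric(1))
  hi <- cls[which.max(mu)]; lo <- cls[which.min(mu)]
  if (is.null(threshold)) threshold <- mean(mu)
  pred <- ifelse(scores > threshold, hi, lo)
  tie <- scores == threshold
  if (any(tie)) {
    nearer <- if (abs(mu[hi] - threshold) < abs(mu[lo] - threshold)) hi else lo
    pred[tie] <- nearer
  }
  mean(pred == as.character(labels))
}

#' Fisher-discriminant plane with an orthogonalised healthy-anchor axis
#'
#' Builds the 2-D view used to compare a treated group pre- vs
#' post-intervention against a healthy reference: the horizontal unit
#' axis `u` is the Fisher direction separating pre from post (post
#' projecting larger); the vertical unit axis `v` is the vector from the
#' healthy-group centre to the pre-intervention centre minus its
#' projection onto `u`, normalised. All subjects and the three group
#' centres are projected onto `(u, v)`; classification thresholds the
#' `u`-coordinate at the midpoint of the two projected class means and
#' reports resubstitution accuracy.
#'
#' @param x_pre,x_post Matrices of standardised variables (same columns).
#' @param center_healthy Healthy-group centre in the same standardised
#'   space.
#' @param lambda Ridge for the Fisher direction (`NULL` = default ridge).
#' @return Object of class `"fisher_plane"`: unit axes `u`, `v`
#'   (orthogonal), `coords` (tibble with `phase` pre/post and in-plane
#'   `x`, `y`), `centers` (3 x 2: healthy, pre, post), `threshold`,
#'   `accuracy`, `lambda`.
#' @export
fisher_plane <- function(x_pre, x_post, center_healthy, lambda = NULL) {
  x_pre <- as.matrix(x_pre); x_post <- as.matrix(x_post)
  stopifnot(ncol(x_pre) == ncol(x_post),
            length(center_healthy) == ncol(x_pre))
  X <- rbind(x_pre, x_post)
  phase <- factor(rep(c("pre", "post"), c(nrow(x_pre), nrow(x_post))),
                  levels = c("pre", "post"))
  u <- fisher_direction(X, phase, lambda)
  c_pre <- colMeans(x_pre)
  a <- c_pre - center_healthy
  a_perp <- a - as.numeric(crossprod(a, u)) * u
  na <- sqrt(sum(a_perp^2))
  if (na < 1e-12)
    stop("healthy-to-pre vector is parallel to the Fisher axis; vertical axis degenerate",
         call. = FALSE)
  v <- a_perp / na
  proj <- function(m) cbind(x = as.numeric(m %*% u), y = as.numeric(m %*% v))
  coords <- tibble::as_tibble(proj(X))
  coords$phase <- phase
  centers <- proj(rbind(healthy = center_healthy, pre = c_pre,
                        post = colMeans(x_post)))
  rownames(centers) <- c("healthy", "pre", "post")
  su <- as.numeric(X %*% u)
  threshold <- mean(c(mean(su[phase == "pre"]), mean(su[phase == "post"])))
  acc <- classification_accuracy(su, phase, threshold)
  structure(list(u = as.numeric(u), v = v, coords = coords, centers = centers,
                 threshold = threshold, accuracy = acc,
                 lambda = attr(u, "lambda")),
            class = "fisher_plane")
}

#' @export
print.fisher_plane <- function(x, ...) {
  cat(sprintf("<fisher_plane> %d pre + %d post subjects; accuracy %.1f%% (lambda = %.4g)\n",
              sum(x$coords$phase == "pre"), sum(x$coords$phase == "post"),
              100 * x$accuracy, x$lambda))
  invisible(x)
}
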