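# Independent oracles and small fixture builders used across the suite.

# Exhaustive kNN-imputation oracle: sorts all pairwise distances directly
# and averages neighbour values, mirroring the documented contract but
# implemented independently of knn_impute()'s loop structure.
brute_knn_oracle <- function(x, k) {
  out <- x
  n <- nrow(x)
  for (i in seq_len(n)) {
    miss <- which(is.na(x[i, ]))
    if (!length(miss)) next
    d <- vapply(seq_len(n), function(j) {
      if (j == i) return(Inf)
      sh <- !is.na(x[i, ]) & !is.na(x[j, ])
      if (!any(sh)) return(Inf)
      mean((x[i, sh] - x[j, sh])^2)
    }, numeric(1))
    for (cc in miss) {
      elig <- setdiff(which(!is.na(x[, cc]) & is.finite(d)), i)
      if (!length(elig)) {
        out[i, cc] <- mean(x[, cc], na.rm = TRUE)
      } else {
        elig <- elig[order(d[elig], elig)]
        out[i, cc] <- mean(x[elig[seq_len(min(k, length(elig)))], cc])
      }
    }
  }
  out
}

# Brute-force maximiser of the 2-D Fisher criterion
# J(theta) = (w.(m2-m1))^2 / (w' Sw w) over a grid of angles.
fisher_grid_oracle <- function(x, labels, n_angles = 1e4) {
  labels <- factor(labels)
  cls <- levels(labels)
  m1 <- colMeans(x[labels == cls[1], , drop = FALSE])
  m2 <- colMeans(x[labels == cls[2], , drop = FALSE])
  Sw <- matrix(0, 2, 2)
  for (g in cls) {
    xg <- scale(x[labels == g, , drop = FALSE], scale = FALSE)
    Sw <- Sw + crossprod(xg)
  }
  thetas <- seq(0, pi, length.out = n_angles)
  J <- vapply(thetas, function(th) {
    w <- c(cos(th), sin(th))
    (sum(w * (m2 - m1)))^2 / drop(t(w) %*% Sw %*% w)
  }, numeric(1))
  th <- thetas[which.max(J)]
  c(cos(th), sin(th))
}

# Angle (degrees) between two directions, ignoring sign.
axis_angle_deg <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, ca)) * 180 / pi
}

# Two-group toy specs for generator tests.
toy_specs <- function(groups = c("healthy", "t2d")) {
  list(
    variable_spec("marker", "biomarker", "log10normal",
                  stats::setNames(list(c(3.0, 0.2), c(3.5, 0.3)), groups), "pg/ml"),
    variable_spec("size", "mri", "normal",
                  stats::setNames(list(c(80, 10), c(65, 8)), groups), "mL"),
    variable_spec("flag", "categorical", "bernoulli",
                  stats::setNames(list(0.5, 0.6), groups))
  )
}

# The printed two-scale biomarker panel: log10 mean/SD per group and the
# corresponding printed back-transformed geometric mean/SD cells (with
# their printed decimal count, for printed-precision comparisons).
printed_panel <- function() {
  tb <- fibrolens:::biomarker_param_table()
  tb$h_geo <- c(6165.95, 309029.54, 12302.69, 2137.96, 123.03, 74131.02,
                15848.93, 56.23, 4897.79, 933.25, 134.90, 478.63, 8128.31,
                4466.84, 36307.81, 1.12, 2511.89, 109647.82, 2.51,
                316227.77, 4168693.84, 17.78, 26.30)
  tb$h_geo_dp <- rep(2L, 23)
  tb$h_gsd <- c(1.48, 1.35, 1.70, 1.82, 2.24, 1.82, 1.55, 1.70, 2.46, 3.16,
                2.63, 2.14, 2.04, 2.63, 2.29, 1.12, 1.31, 1.78, 1.62, 1.45,
                1.70, 1.86, 1.51)
  tb$t_geo <- c(5495.41, 251189, 8511.38, 3311.31, 190.55, 100000.00,
                10964.80, 43.65, 2884.03, 1412.54, 87.10, 933.25, 3801.89,
                19498.4, 75857.80, 1.32, 3090.30, 83176.4, 3.31, 251189,
                3019952.00, 12.88, 33.88)
  tb$t_geo_dp <- c(2L, 0L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L,
                   1L, 2L, 2L, 2L, 1L, 2L, 0L, 2L, 2L, 2L)
  tb$t_gsd <- c(1.35, 1.26, 1.66, 1.86, 2.14, 1.48, 1.48, 1.62, 2.04, 2.69,
                2.88, 1.78, 1.74, 2.24, 1.66, 1.32, 1.45, 1.74, 1.62, 1.45,
                1.70, 1.58, 1.41)
  tb
}

# Printed-precision agreement: within half a unit of the printed last
# digit, a small relative slack absorbing rounding artifacts in wide
# columns, or the consistency band implied by the log10 input itself
# being printed at `input_dp` decimals (a log10 value rounded to 2 dp
# pins its back-transform only to within a factor 10^0.005).
expect_printed <- function(computed, printed, dp, rel = 5e-6, input_dp = 2L) {
  band <- 10^(0.5 * 10^(-input_dp)) - 1
  expect_true(abs(computed - printed) <= 0.5 * 10^(-dp) + 1e-12 ||
                abs(computed - printed) / abs(printed) <= max(rel, band),
              label = sprintf("computed %.6g vs printed %.6g", computed, printed))
}
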