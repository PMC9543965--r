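test_that("PCA via SVD satisfies its exact algebraic contracts", {
  withr::with_seed(2, {
    # rank-1 data on a line in 5-D: first component explains everything
    t_par <- rnorm(20)
    line <- outer(t_par, c(1, -2, 0.5, 3, 1))
    p1 <- pca_svd(line, 1)
    expect_equal(p1$var_explained[1], 1, tolerance = 1e-10)
    expect_error(pca_svd(line, 3), "rank")

    # duplicated column pair matches the closed-form 2x2 eigendecomposition
    x1 <- rnorm(30)
    dup <- cbind(x1, x1)
    p2 <- pca_svd(dup, 1)
    expect_equal(p2$eigenvalues[1], 2 * var(x1), tolerance = 1e-10)
    expect_equal(abs(p2$axes[1, 1]), abs(p2$axes[2, 1]), tolerance = 1e-10)
    expect_equal(abs(p2$axes[1, 1]), 1 / sqrt(2), tolerance = 1e-10)

    x <- matrix(rnorm(40 * 6), 40, 6)
    p <- pca_svd(x, 3)
    # orthonormal axes, ordered non-negative eigenvalues, fractions sum to 1
    expect_equal(unname(crossprod(p$axes)), diag(3), tolerance = 1e-8)
    expect_true(all(diff(p$eigenvalues) <= 1e-10))
    expect_true(all(p$eigenvalues >= -1e-10))
    expect_equal(sum(p$var_explained), 1, tolerance = 1e-8)
    # scores' covariance is diagonal with the eigenvalues
    expect_equal(unname(cov(p$scores)), diag(p$eigenvalues[1:3]), tolerance = 1e-8)
    # rotation invariance of the spectrum
    q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
    pr <- pca_svd(x %*% q, 3)
    expect_equal(pr$eigenvalues, p$eigenvalues, tolerance = 1e-8)
    expect_error(pca_svd(rbind(x[1, ], NA * x[2, ]), 1), "impute")
  })
})

test_that("the best-fit plane passes through the centroid with the least-squares normal", {
  withr::with_seed(3, {
    flat <- cbind(rnorm(15), rnorm(15), 0)
    pl <- best_fit_plane(flat)
    expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-10)
    expect_false(pl$degenerate)

    pts <- cbind(rnorm(30), rnorm(30), rnorm(30))
    pl2 <- best_fit_plane(pts)
    expect_equal(sum((colMeans(pts) - pl2$point)^2), 0, tolerance = 1e-12)

    # noisy points around a known plane: normal recovered within 5 degrees
    true_n <- c(1, 2, -1) / sqrt(6)
    basis <- svd(diag(3) - tcrossprod(true_n))$u[, 1:2]
    noisy <- cbind(rnorm(30, sd = 3), rnorm(30, sd = 2)) %*% t(basis) +
      outer(rnorm(30, sd = 0.1), true_n)
    expect_lt(axis_angle_deg(best_fit_plane(noisy)$normal, true_n), 5)

    line <- outer(1:10, c(1, 1, 1))
    expect_true(best_fit_plane(line)$degenerate)
  })
})

test_that("the Fisher direction maximises the Fisher criterion (grid-search oracle)", {
  # exactly isotropic within-class scatter: direction is the mean
  # difference (identity-scatter identity)
  square <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  x <- rbind(square, sweep(square, 2, c(3, 1), `+`))
  lab <- rep(c("a", "b"), each = 4)
  w <- fisher_direction(x, lab, lambda = 0)
  md <- c(3, 1)
  expect_lt(axis_angle_deg(w, md), 1e-6)
  withr::with_seed(4, {

    # anisotropic toys vs brute-force grid search over 1e4 angles
    for (s in 1:4) {
      withr::with_seed(100 + s, {
        A <- matrix(rnorm(4), 2, 2)
        x1 <- matrix(rnorm(160), 80, 2) %*% A
        x2 <- sweep(matrix(rnorm(160), 80, 2) %*% A, 2, c(2, -1), `+`)
        xx <- rbind(x1, x2); ll <- rep(c("a", "b"), each = 80)
        w_fit <- fisher_direction(xx, ll, lambda = 0)
        w_oracle <- fisher_grid_oracle(xx, ll)
        expect_lt(axis_angle_deg(w_fit, w_oracle), 0.1)
      })
    }

    # affine equivariance: rescaling a coordinate leaves scores equivalent
    D <- diag(c(5, 1))
    w_scaled <- fisher_direction(x %*% D, lab, lambda = 0)
    s1 <- x %*% w
    s2 <- (x %*% D) %*% w_scaled
    expect_equal(abs(cor(s1, s2))[1, 1], 1, tolerance = 1e-8)

    # sign convention: second class projects larger
    expect_gt(mean((x %*% w)[lab == "b"]), mean((x %*% w)[lab == "a"]))

    expect_error(fisher_direction(x, rep("a", 200)), "two classes")
  })
  # singular scatter with lambda = 0 instructs regularisation
  tallp <- matrix(rnorm(4 * 10), 4, 10)
  expect_error(fisher_direction(tallp, c("a", "a", "b", "b"), lambda = 0),
               "singular|regulari")
})

test_that("classification accuracy counts sides of the threshold correctly", {
  expect_equal(classification_accuracy(c(1, 2, 3, 11, 12, 13),
                                       rep(c("lo", "hi"), each = 3)), 1)
  # six-point worked toy vs an exhaustive hand count: threshold 5,
  # scores {1,4,6} for lo and {5,8,9} for hi; 6 is a miss for lo, 5 is a
  # tie resolved to the nearer-mean class
  sc <- c(1, 4, 6, 5, 8, 9)
  lb <- rep(c("lo", "hi"), each = 3)
  # means: lo 11/3, hi 22/3; threshold 5.5 by default
  expect_equal(classification_accuracy(sc, lb), 4 / 6)
  # explicit threshold 5: {1,4} correct lo, 6 wrong; 5 is a tie ->
  # nearer mean is lo (|11/3-5| < |22/3-5|) -> wrong for hi; 8,9 correct
  expect_equal(classification_accuracy(sc, lb, threshold = 5), 4 / 6)
  withr::with_seed(6, {
    sc2 <- rnorm(400)
    lb2 <- sample(rep(c("a", "b"), 200))
    acc <- classification_accuracy(sc2, lb2)
    expect_lt(abs(acc - 0.5), 4 * sqrt(0.25 / 400))
  })
  expect_error(classification_accuracy(1:3, rep("a", 3)), "two classes")
})

test_that("the Fisher plane has orthonormal axes and detects real separation only", {
  withr::with_seed(9, {
    p <- 6
    pre <- matrix(rnorm(40 * p), 40, p)
    u_true <- rep(1 / sqrt(p), p)
    post <- pre + 8 * matrix(u_true, 40, p, byrow = TRUE) +
      matrix(rnorm(40 * p, sd = 0.3), 40, p)
    ch <- rnorm(p)
    fp <- fisher_plane(pre, post, ch)
    expect_equal(sum(fp$u^2), 1, tolerance = 1e-8)
    expect_equal(sum(fp$v^2), 1, tolerance = 1e-8)
    expect_equal(sum(fp$u * fp$v), 0, tolerance = 1e-8)
    expect_equal(fp$accuracy, 1)
    expect_gt(fp$centers["post", "x"], fp$centers["pre", "x"])
    # centers reproduce direct dot products
    expect_equal(unname(fp$centers["healthy", ]),
                 c(sum(ch * fp$u), sum(ch * fp$v)), tolerance = 1e-10)
    expect_equal(unname(fp$centers["pre", ]),
                 c(sum(colMeans(pre) * fp$u), sum(colMeans(pre) * fp$v)),
                 tolerance = 1e-10)

    # permutation null on identical rows: accuracy stays near chance in
    # a low-dimensional setting
    pool <- matrix(rnorm(200 * 4), 200, 4)
    accs <- vapply(1:200, function(i) {
      idx <- sample(200, 100)
      fisher_plane(pool[idx, ], pool[-idx, ], rnorm(4) + 2)$accuracy
    }, numeric(1))
    expect_lt(mean(accs), 0.6)

    # healthy-to-pre vector parallel to u: degenerate vertical axis
    expect_error(
      fisher_plane(pre, post, colMeans(pre) - 5 * fisher_direction(
        rbind(pre, post), rep(c("pre", "post"), each = 40))),
      "degenerate|parallel")
  })
})
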