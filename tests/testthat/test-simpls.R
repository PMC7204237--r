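test_that("one latent variable on one predictor is simple least squares", {
  set.seed(1)
  x <- rnorm(30)
  y <- 2 + 3 * x + rnorm(30, sd = 0.3)
  fit <- simpls(matrix(x, ncol = 1), y, ncomp = 1)
  slope_ols <- cov(x, y) / var(x)
  expect_equal(coef(fit, 1), slope_ols, tolerance = 1e-10)
  expect_equal(export_coefficients(fit)$coefficient, slope_ols,
               tolerance = 1e-10)
})

test_that("full-rank SIMPLS reaches the exact least-squares fit", {
  set.seed(2)
  X <- matrix(rnorm(25 * 4), 25, 4)
  beta <- c(1, -2, 0.5, 3)
  y <- drop(X %*% beta) + 7
  fit <- simpls(X, y, ncomp = 4)
  expect_lt(max(abs(fitted(fit) - y)), 1e-8)
  expect_equal(coef(fit, 4), beta, tolerance = 1e-8)
})

test_that("full-LV coefficients match the minimum-norm least-squares oracle", {
  set.seed(3)
  for (i in 1:10) {
    X <- matrix(rnorm(20 * 8), 20, 8)
    y <- rnorm(20)
    fit <- simpls(X, y, ncomp = 8)
    expect_equal(coef(fit, 8), pinv_coef(X, y), tolerance = 1e-8)
  }
})

test_that("predictions agree with an independent NIPALS oracle at every LV", {
  set.seed(4)
  for (i in 1:8) {
    n <- sample(15:30, 1); p <- sample(5:12, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% rnorm(p)) + rnorm(n)
    k <- min(6, p)
    fit <- simpls(X, y, ncomp = k)
    oracle <- nipals_pls(X, y, k)
    Xnew <- matrix(rnorm(5 * p), 5, p)
    for (a in seq_len(k)) {
      expect_equal(predict(fit, X, ncomp = a), oracle$predict(X, a),
                   tolerance = 1e-6)
      expect_equal(predict(fit, Xnew, ncomp = a), oracle$predict(Xnew, a),
                   tolerance = 1e-6)
    }
  }
})

test_that("scores are orthonormal and the coefficient path reproduces them", {
  set.seed(5)
  X <- matrix(rnorm(40 * 15), 40, 15)
  y <- drop(X %*% rnorm(15)) + rnorm(40)
  fit <- simpls(X, y, ncomp = 8)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  Xc <- sweep(X, 2, fit$x_mean, "-")
  for (k in c(1, 4, 8)) {
    via_scores <- drop(fit$scores[, 1:k, drop = FALSE] %*% fit$y_loadings[1:k]) +
      fit$y_mean
    via_coefs <- drop(Xc %*% fit$coef_path[, k]) + fit$y_mean
    expect_equal(via_coefs, via_scores, tolerance = 1e-8)
  }
})

test_that("training RMSE never increases with more latent variables", {
  set.seed(6)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- drop(X %*% rnorm(10)) + rnorm(30)
  fit <- simpls(X, y, ncomp = 10)
  rmse <- vapply(1:10, function(k) sqrt(mean((y - predict(fit, X, ncomp = k))^2)),
                 numeric(1))
  expect_true(all(diff(rmse) <= 1e-12))
})

test_that("rescaling a channel rescales its full-rank coefficient and nothing else", {
  # at the full latent-variable count the fit coincides with least squares,
  # which is equivariant under channel rescaling (partial-LV PLS is not,
  # which is why the pipeline never autoscales spectra)
  set.seed(7)
  X <- matrix(rnorm(25 * 6), 25, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(25)
  fit <- simpls(X, y, ncomp = 6)
  X2 <- X; X2[, 3] <- 5 * X[, 3]
  fit2 <- simpls(X2, y, ncomp = 6)
  expect_equal(predict(fit2, X2, ncomp = 6), predict(fit, X, ncomp = 6),
               tolerance = 1e-6)
  expect_equal(coef(fit2, 6)[3], coef(fit, 6)[3] / 5, tolerance = 1e-6)
  expect_equal(coef(fit2, 6)[-3], coef(fit, 6)[-3], tolerance = 1e-6)
})

test_that("degenerate inputs are handled as documented", {
  set.seed(8)
  X <- matrix(rnorm(20 * 5), 20, 5)
  X[, 2] <- 4  # constant channel
  y <- drop(X[, -2] %*% rnorm(4)) + rnorm(20)
  fit <- simpls(X, y, ncomp = 4)
  expect_equal(unname(coef(fit, 4)[2]), 0)
  expect_error(simpls(X, rep(1, 20), ncomp = 2), "zero variance")
  expect_warning(simpls(X[1:4, ], y[1:4], ncomp = 5), "rank")
  expect_equal(unname(predict(fit, fit$x_mean)), fit$y_mean, tolerance = 1e-10)
  expect_error(predict(fit, X[, 1:3]), "wrong number")
})

test_that("prediction is affine in the new observations", {
  set.seed(9)
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- rnorm(20)
  fit <- simpls(X, y, ncomp = 3)
  x1 <- rnorm(5); x2 <- rnorm(5); lam <- 0.3
  p_mix <- predict(fit, lam * x1 + (1 - lam) * x2, ncomp = 3)
  expect_equal(p_mix, lam * predict(fit, x1, ncomp = 3) +
                 (1 - lam) * predict(fit, x2, ncomp = 3), tolerance = 1e-10)
})

test_that("the latent-variable selector takes the first global minimum", {
  expect_equal(select_latent_variables(c(5, 3, 4)), 2)
  expect_equal(select_latent_variables(c(3, 3, 5)), 1)
  expect_equal(select_latent_variables(rev(seq_len(7))), 7)
  expect_error(select_latent_variables(numeric(0)), "nonempty")
  expect_error(select_latent_variables(c(1, -2)), "nonnegative")
})

test_that("exported coefficients follow column permutations", {
  set.seed(10)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- rnorm(30)
  fit <- simpls(X, y, ncomp = 3)
  perm <- c(4, 1, 6, 2, 5, 3)
  fitp <- simpls(X[, perm], y, ncomp = 3)
  expect_equal(coef(fitp, 3), coef(fit, 3)[perm], tolerance = 1e-8)
  tab <- export_coefficients(fit, ncomp = 3, grid = seq(100, 600, by = 100))
  expect_equal(tab$wavenumber, seq(100, 600, by = 100))
  expect_equal(tab$coefficient, coef(fit, 3))
})
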