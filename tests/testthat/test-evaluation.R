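test_that("MSEP and RMSEP are the plain mean squared error and its root", {
  expect_equal(msep(c(1, 2), c(1, 2)), 0)
  expect_equal(msep(c(1, 2), c(2, 2)), 0.5)
  expect_equal(msep(c(0, 0, 0), c(1, 1, 1)), 1)
  expect_equal(rmsep(c(0, 0, 0), c(2, 2, 2)), 2)
  expect_error(msep(1:3, 1:2), "equal")
})

test_that("R2 is one minus SSE over SST", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(4, 8, 6, 2)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)  # SSE 1, SST 2
  expect_error(r_squared(c(2, 2), c(1, 3)), "constant")
  # can be negative for predictions worse than the mean
  expect_lt(r_squared(c(1, 2, 3), c(5, 5, 5)), 0)
})

test_that("Lin's concordance uses population moments and penalizes bias", {
  expect_equal(lin_ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(lin_ccc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
  expect_equal(lin_ccc(c(5, 5), c(5, 5)), 1)
  expect_warning(ccc0 <- lin_ccc(c(5, 5), c(7, 7)), "constant")
  expect_equal(ccc0, 0)
  # |CCC| <= |pearson| over random pairs
  set.seed(20)
  for (i in 1:20) {
    o <- rnorm(15); p <- 0.5 * o + rnorm(15) + runif(1, -2, 2)
    expect_lte(abs(lin_ccc(o, p)), abs(cor(o, p)) + 1e-12)
  }
})

test_that("RPD is the reference spread over the prediction error", {
  expect_equal(rpd(100, 50), 2)
  expect_equal(rpd(86.5, 86.5), 1)
  expect_equal(rpd(135.9, 86.5), 135.9 / 86.5)
  expect_gt(rpd(135.9, 86.5), 1.57)  # ~1.571
  expect_error(rpd(100, 0), "positive")
  expect_error(rpd(-1, 10), "nonnegative")
})

test_that("every observation is validated exactly once per CV iteration", {
  set.seed(21)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- rnorm(20)
  cv <- random_cross_validate(X, y, n_splits = 10, n_iterations = 10,
                              lv_range = 1:3, seed = 99)
  expect_equal(dim(cv$fold_assignments), c(20, 10))
  for (it in 1:10) {
    sizes <- table(cv$fold_assignments[, it])
    expect_equal(length(sizes), 10L)
    expect_true(all(sizes == 2))  # n = 20 over 10 folds
  }
  # deterministic given the seed
  cv2 <- random_cross_validate(X, y, n_splits = 10, n_iterations = 10,
                               lv_range = 1:3, seed = 99)
  expect_identical(cv$rmse_by_lv, cv2$rmse_by_lv)
  expect_identical(cv$fold_assignments, cv2$fold_assignments)
})

test_that("noise-free linear responses are recovered exactly by CV", {
  set.seed(22)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- drop(X %*% c(1, -1, 2, 0.5, -0.25))
  cv <- random_cross_validate(X, y, lv_range = 1:5, seed = 7)
  expect_lt(cv$rmse_by_lv[5], 1e-6)
  ext <- external_cross_validate(X, y, lv_range = 1:5, seed = 7)
  expect_gte(ext$r2v, 0.999)
})

test_that("the reported RMSECV curve matches a naive loop re-implementation", {
  set.seed(23)
  X <- matrix(rnorm(50 * 30), 50, 30)
  y <- drop(X[, 1:5] %*% rnorm(5)) + rnorm(50)
  lv_range <- 1:8
  cv <- random_cross_validate(X, y, lv_range = lv_range, seed = 41)
  oracle <- naive_rmsecv(X, y, cv$fold_assignments, lv_range)
  expect_equal(cv$rmse_by_lv, oracle, tolerance = 1e-10)
})

test_that("external validation partitions exactly and selects LV internally", {
  set.seed(24)
  X <- matrix(rnorm(48 * 10), 48, 10)
  y <- drop(X %*% rnorm(10)) + rnorm(48)
  ext <- external_cross_validate(X, y, lv_range = 1:5, seed = 13)
  expect_equal(sort(unique(ext$quarter_assignments)), 1:4)
  expect_true(all(table(ext$quarter_assignments) == 12))
  expect_equal(length(ext$quarter_lv), 4L)
  expect_true(all(ext$quarter_lv >= 1 & ext$quarter_lv <= 5))
  expect_true(all(!is.na(ext$oof_pred)))
  expect_equal(ext$rmsev, mean(ext$quarter_rmse))
  expect_equal(ext$r2v, mean(ext$quarter_r2))
})

test_that("permuting the response destroys external-validation skill", {
  ds <- shared_dataset()
  fit_des <- hpmir:::assemble_design(ds, "M3", hp_config())
  set.seed(25)
  y_perm <- sample(fit_des$y)
  ext <- external_cross_validate(fit_des$X, y_perm, lv_range = 1:10, seed = 5)
  expect_lte(ext$r2v, 0.15)
})

test_that("cross-validated error dominates training error on noisy problems", {
  set.seed(26)
  gaps <- replicate(5, {
    X <- matrix(rnorm(40 * 20), 40, 20)
    y <- drop(X[, 1:3] %*% rnorm(3)) + rnorm(40)
    cv <- random_cross_validate(X, y, lv_range = 1:5, seed = 3)
    fit <- simpls(X, y, ncomp = 5)
    train_rmse <- sqrt(mean((y - predict(fit, X, ncomp = 5))^2))
    cv$rmse_by_lv[5] - train_rmse
  })
  expect_gt(mean(gaps), 0)      # generalization gap positive on average
  expect_gte(sum(gaps > 0), 4)  # and in nearly every replicate
})
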