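# Independent reference implementations used to check the package's own
# algorithms. These deliberately share no code with the package internals.

# NIPALS PLS (single response), the textbook construction: components from
# the deflated residual matrices, prediction through W (P'W)^-1 q.
nipals_pls <- function(X, y, ncomp) {
  X <- as.matrix(X)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm, "-"); f <- y - ym
  p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    w <- w / sqrt(sum(w^2))
    t <- E %*% w
    tt <- sum(t^2)
    pa <- crossprod(E, t) / tt
    qa <- sum(f * t) / tt
    E <- E - t %*% t(pa)
    f <- f - t * qa
    W[, a] <- w; P[, a] <- pa; q[a] <- qa
  }
  list(
    predict = function(Xn, k) {
      B <- W[, 1:k, drop = FALSE] %*%
        solve(crossprod(P[, 1:k, drop = FALSE], W[, 1:k, drop = FALSE]),
              q[1:k])
      drop(sweep(as.matrix(Xn), 2, xm, "-") %*% B + ym)
    }
  )
}

# Minimum-norm least-squares coefficients on centered data, via the SVD
# pseudoinverse.
pinv_coef <- function(X, y) {
  Xc <- sweep(X, 2, colMeans(X), "-")
  yc <- y - mean(y)
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-10
  drop(sv$v[, pos, drop = FALSE] %*%
         ((crossprod(sv$u[, pos, drop = FALSE], yc)) / sv$d[pos]))
}

# Naive repeated-CV RMSE curve: plain loops over the given fold-assignment
# matrix, no shared state with the package's CV bookkeeping.
naive_rmsecv <- function(X, y, folds, lv_range) {
  nlv <- length(lv_range)
  iter_rmse <- matrix(NA_real_, ncol(folds), nlv)
  for (it in seq_len(ncol(folds))) {
    oof <- matrix(NA_real_, length(y), nlv)
    for (f in sort(unique(folds[, it]))) {
      test <- which(folds[, it] == f)
      fit <- suppressWarnings(
        hpmir::simpls(X[-test, , drop = FALSE], y[-test], max(lv_range)))
      for (j in seq_len(nlv))
        oof[test, j] <- predict(fit, X[test, , drop = FALSE],
                                ncomp = min(lv_range[j], fit$ncomp))
    }
    iter_rmse[it, ] <- sqrt(colMeans((oof - y)^2))
  }
  colMeans(iter_rmse)
}

# Shared fixture: one default synthetic dataset, built once per test run.
shared_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- generate_dataset(generator_config(), seed = 1)
    ds
  }
})

# Small, fast dataset for pipeline-level tests.
small_config <- function(n_cows = 40L, ...) {
  generator_config(n_cows = n_cows, obs_per_cow = 1L,
                   grid_spec = c(925, 5008, 300), ...)
}
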