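#' Mean squared error of prediction
#'
#' `MSEP = sum((O_i - P_i)^2) / n` for observed `obs` and predicted `pred`.
#'
#' @param obs,pred numeric vectors of equal nonzero length.
#' @return MSEP in squared response units.
#' @export
msep <- function(obs, pred) {
  check_obs_pred(obs, pred)
  mean((obs - pred)^2)
}

#' Root mean squared error of prediction
#' @inheritParams msep
#' @return `sqrt(msep(obs, pred))`.
#' @export
rmsep <- function(obs, pred) sqrt(msep(obs, pred))

#' Coefficient of determination
#'
#' `R2 = 1 - SSE/SST` with `SST` the total sum of squares around the mean of
#' the observations. This definition (rather than a squared correlation) is
#' used throughout, including for cross-validated predictions, so R2 can be
#' negative for predictions worse than the mean.
#'
#' @inheritParams msep
#' @return unitless, at most 1.
#' @export
r_squared <- function(obs, pred) {
  check_obs_pred(obs, pred)
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("observations are constant; R2 undefined", call. = FALSE)
  1 - sum((obs - pred)^2) / sst
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (divide-by-n) moments: agreement with the 45-degree line, combining
#' precision (correlation) and accuracy (bias).
#'
#' @inheritParams msep
#' @return value in `[-1, 1]`. Two identical constant series give 1 by
#'   convention; two different constant series give 0 with a warning.
#' @export
lin_ccc <- function(obs, pred) {
  check_obs_pred(obs, pred)
  if (length(obs) < 2L) stop("at least two pairs are required", call. = FALSE)
  n <- length(obs)
  mx <- mean(obs); my <- mean(pred)
  sx2 <- mean((obs - mx)^2); sy2 <- mean((pred - my)^2)
  sxy <- mean((obs - mx) * (pred - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) return(1)  # identical constant series: perfect concordance
  if (sx2 == 0 && sy2 == 0) {
    warning("both series constant but unequal; concordance set to 0")
    return(0)
  }
  2 * sxy / denom
}

#' Ratio of performance to deviation
#'
#' `RPD = sd(reference) / RMSE`: how much wider the spread of the reference
#' values is than the prediction error. Values near 1 indicate a model no
#' better than the mean; screening use is conventionally taken to require
#' well above 2.
#'
#' @param reference_sd standard deviation of the reference observations
#'   (response units, >= 0).
#' @param rmse prediction error (response units, > 0).
#' @return unitless ratio.
#' @export
rpd <- function(reference_sd, rmse) {
  if (!is.numeric(reference_sd) || reference_sd < 0)
    stop("reference_sd must be nonnegative", call. = FALSE)
  if (!is.numeric(rmse) || rmse <= 0)
    stop("rmse must be positive", call. = FALSE)
  reference_sd / rmse
}

check_obs_pred <- function(obs, pred) {
  if (!is.numeric(obs) || !is.numeric(pred))
    stop("obs and pred must be numeric", call. = FALSE)
  if (length(obs) == 0L || length(obs) != length(pred))
    stop("obs and pred must have equal nonzero length", call. = FALSE)
  if (any(!is.finite(obs)) || any(!is.finite(pred)))
    stop("obs and pred must be finite", call. = FALSE)
}

#' Random repeated k-fold cross-validation of a SIMPLS calibration
#'
#' In each of `n_iterations` iterations the samples are partitioned at
#' random into `n_splits` near-equal folds; every fold is predicted once by
#' a SIMPLS model fitted on its complement, at every latent-variable count
#' in `lv_range`, so each observation is validated exactly once per
#' iteration. Per iteration the out-of-fold predictions are pooled into an
#' RMSE and R2 per latent-variable count; the reported RMSECV/R2CV curves
#' are the means of those per-iteration values.
#'
#' @param X predictor matrix (samples x channels).
#' @param y response vector.
#' @param n_splits folds per iteration (default 10).
#' @param n_iterations number of repeats (default 10).
#' @param lv_range integer vector of latent-variable counts to evaluate;
#'   default `1:min(20, ...)` bounded by fold-complement size and channel
#'   count.
#' @param seed integer seed; the scheme is deterministic given the seed.
#' @return an object of class `cv_result` with `scheme = "random_10x10"`
#'   (or the corresponding splits/iterations), `lv_range`, `rmse_by_lv`,
#'   `r2_by_lv`, per-iteration matrices `iter_rmse` / `iter_r2`, the
#'   `fold_assignments` matrix (samples x iterations), and `oof_pred`
#'   (samples x LV matrix of out-of-fold predictions averaged over
#'   iterations).
#' @export
random_cross_validate <- function(X, y, n_splits = 10L, n_iterations = 10L,
                                  lv_range = NULL, seed = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (n < n_splits) stop("need at least one observation per fold", call. = FALSE)
  lv_range <- default_lv_range(lv_range, n - ceiling(n / n_splits), ncol(X))
  nlv <- length(lv_range)
  max_lv <- max(lv_range)

  with_seed(seed, {
    folds <- matrix(0L, n, n_iterations)
    iter_rmse <- matrix(NA_real_, n_iterations, nlv)
    iter_r2 <- matrix(NA_real_, n_iterations, nlv)
    oof_sum <- matrix(0, n, nlv)
    for (it in seq_len(n_iterations)) {
      fold <- fold_assignment(n, n_splits)
      folds[, it] <- fold
      oof <- matrix(NA_real_, n, nlv)
      for (f in seq_len(n_splits)) {
        test <- which(fold == f)
        # rank exhaustion inside a fold is routine (collinear channels);
        # predictions above the achieved rank reuse the deepest component
        fit <- suppressWarnings(simpls(X[-test, , drop = FALSE], y[-test],
                                       ncomp = max_lv))
        for (j in seq_len(nlv))
          oof[test, j] <- predict(fit, X[test, , drop = FALSE],
                                  ncomp = min(lv_range[j], fit$ncomp))
      }
      iter_rmse[it, ] <- sqrt(colMeans((oof - y)^2))
      iter_r2[it, ] <- 1 - colSums((oof - y)^2) / sum((y - mean(y))^2)
      oof_sum <- oof_sum + oof
    }
    structure(list(scheme = sprintf("random_%dx%d", n_splits, n_iterations),
                   n_splits = n_splits, n_iterations = n_iterations,
                   lv_range = lv_range,
                   rmse_by_lv = colMeans(iter_rmse),
                   r2_by_lv = colMeans(iter_r2),
                   iter_rmse = iter_rmse, iter_r2 = iter_r2,
                   fold_assignments = folds,
                   oof_pred = oof_sum / n_iterations,
                   seed = seed),
              class = "cv_result")
  })
}

#' External cross-validation in random quarters
#'
#' The samples are split once at random into `n_quarters` near-equal parts.
#' Each part in turn is held out entirely: the latent-variable count is
#' chosen by an inner [random_cross_validate()] on the remaining parts
#' (selection never sees the held-out quarter), a SIMPLS model is fitted on
#' those parts and the held-out quarter predicted. The reported RMSEV and
#' R2V are the means of the per-quarter values.
#'
#' @inheritParams random_cross_validate
#' @param n_quarters number of external parts (default 4).
#' @param inner_splits,inner_iterations folds/repeats of the inner CV used
#'   for latent-variable selection (defaults 10 and 10).
#' @return an object of class `cv_result` with `scheme = "external_4fold"`,
#'   per-quarter RMSE/R2/selected LV, pooled out-of-fold predictions
#'   (`oof_pred`, each observation predicted exactly once), `rmsev`, `r2v`,
#'   and `quarter_assignments`.
#' @export
external_cross_validate <- function(X, y, n_quarters = 4L, lv_range = NULL,
                                    seed = NULL, inner_splits = 10L,
                                    inner_iterations = 10L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (n < n_quarters) stop("need at least one observation per quarter", call. = FALSE)
  with_seed(seed, {
    quarter <- fold_assignment(n, n_quarters)
    q_rmse <- numeric(n_quarters); q_r2 <- numeric(n_quarters)
    q_lv <- integer(n_quarters)
    oof <- rep(NA_real_, n)
    for (qi in seq_len(n_quarters)) {
      test <- which(quarter == qi)
      Xtr <- X[-test, , drop = FALSE]; ytr <- y[-test]
      inner_seed <- sample.int(.Machine$integer.max, 1L)
      inner <- random_cross_validate(Xtr, ytr, n_splits = inner_splits,
                                     n_iterations = inner_iterations,
                                     lv_range = lv_range, seed = inner_seed)
      lv <- inner$lv_range[select_latent_variables(inner$rmse_by_lv)]
      fit <- suppressWarnings(simpls(Xtr, ytr, ncomp = lv))
      pred <- predict(fit, X[test, , drop = FALSE], ncomp = fit$ncomp)
      oof[test] <- pred
      q_lv[qi] <- lv
      q_rmse[qi] <- rmsep(y[test], pred)
      q_r2[qi] <- r_squared(y[test], pred)
    }
    structure(list(scheme = sprintf("external_%dfold", n_quarters),
                   n_quarters = n_quarters,
                   quarter_assignments = quarter,
                   quarter_rmse = q_rmse, quarter_r2 = q_r2,
                   quarter_lv = q_lv,
                   rmsev = mean(q_rmse), r2v = mean(q_r2),
                   oof_pred = oof, seed = seed),
              class = "cv_result")
  })
}

default_lv_range <- function(lv_range, n_train, p) {
  cap <- min(20L, n_train - 1L, p)
  if (cap < 1L) stop("too few observations to fit any latent variable", call. = FALSE)
  if (is.null(lv_range)) return(seq_len(cap))
  lv_range <- as.integer(lv_range)
  if (any(lv_range < 1L)) stop("latent-variable counts must be >= 1", call. = FALSE)
  if (max(lv_range) > cap) {
    warning(sprintf("lv_range truncated at achievable rank %d", cap))
    lv_range <- lv_range[lv_range <= cap]
  }
  lv_range
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation (%s)\n", x$scheme))
  if (!is.null(x$rmse_by_lv)) {
    best <- select_latent_variables(x$rmse_by_lv)
    cat(sprintf("  RMSECV %.4g at %d LV (min over %d LV counts), R2CV %.4g\n",
                x$rmse_by_lv[best], x$lv_range[best], length(x$lv_range),
                x$r2_by_lv[best]))
  }
  if (!is.null(x$rmsev))
    cat(sprintf("  RMSEV %.4g, R2V %.4g (per-quarter LV: %s)\n",
                x$rmsev, x$r2v, paste(x$quarter_lv, collapse = ", ")))
  invisible(x)
}

#' Serialize a cross-validation result to JSON
#'
#' Audit record: fold assignments, per-LV curves and summary metrics.
#'
#' @param cv a `cv_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cv_json <- function(cv, path) {
  jsonlite::write_json(unclass(cv), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
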