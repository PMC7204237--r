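#' SIMPLS partial least squares regression (single response)
#'
#' De Jong's SIMPLS on the column-centered predictor matrix and centered
#' response: each component takes the dominant direction of the deflated
#' cross-product vector `s = Xc' yc` (for a single response, `s` itself),
#' forms a unit-norm score, and deflates `s` against an orthonormal basis of
#' the x-loadings accumulated so far. Predictors are centered only, never
#' scaled to unit variance — the chemometric convention for absorbance
#' spectra, where channel variance is informative. Zero-variance channels
#' (e.g. constant water-region leftovers) are retained and receive zero
#' weight.
#'
#' The loading basis is re-orthogonalized (two Gram-Schmidt passes) at every
#' deflation step so that score orthogonality survives strongly collinear
#' spectral channels.
#'
#' @param X numeric matrix, samples in rows, predictors (channels) in columns.
#' @param y numeric response vector, `length(y) == nrow(X)`, non-constant.
#' @param ncomp maximum number of latent variables; truncated with a warning
#'   if it exceeds the achievable rank (at most `min(nrow(X) - 1, ncol(X))`).
#' @return an object of class `simpls` with elements:
#'   `x_mean`, `y_mean` (centering), `weights` (R, predictors x LV),
#'   `scores` (T, samples x LV, orthonormal columns), `x_loadings` (P),
#'   `y_loadings` (q), `coef_path` (predictors x LV matrix; column k is the
#'   regression vector using k latent variables), `ncomp`.
#' @references de Jong, S. (1993) SIMPLS: an alternative approach to partial
#'   least squares regression. Chemometrics and Intelligent Laboratory
#'   Systems 18, 251-263.
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' y <- X %*% c(1, -1, 0.5) + rnorm(20, sd = 0.1)
#' fit <- simpls(X, y, ncomp = 3)
#' head(predict(fit, X))
#' @export
simpls <- function(X, y, ncomp) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (n < 2L) stop("at least two samples are required", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("X and y must be finite", call. = FALSE)
  if (stats::var(y) == 0) stop("response has zero variance", call. = FALSE)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L) stop("ncomp must be >= 1", call. = FALSE)
  max_rank <- min(n - 1L, p)
  if (ncomp > max_rank) {
    warning(sprintf("ncomp reduced from %d to achievable rank %d", ncomp, max_rank))
    ncomp <- max_rank
  }

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean, "-")
  yc <- y - y_mean

  R <- matrix(0, p, ncomp)      # weights: T = Xc %*% R
  TT <- matrix(0, n, ncomp)     # orthonormal scores
  P <- matrix(0, p, ncomp)      # x-loadings
  q <- numeric(ncomp)           # y-loadings
  V <- matrix(0, p, ncomp)      # orthonormal basis of x-loadings

  s <- crossprod(Xc, yc)
  t1norm <- NA_real_
  a <- 0L
  for (k in seq_len(ncomp)) {
    r <- s
    t <- Xc %*% r               # mean-zero because Xc is column-centered
    tn <- sqrt(sum(t^2))
    if (k == 1L) t1norm <- tn
    if (!is.finite(tn) || tn <= .Machine$double.eps^0.5 * max(t1norm, 1))
      break                     # residual rank exhausted
    t <- t / tn
    r <- r / tn
    pk <- crossprod(Xc, t)
    qk <- sum(yc * t)
    v <- pk
    if (a > 0L) {               # two passes against the loading basis
      Vk <- V[, seq_len(a), drop = FALSE]
      v <- v - Vk %*% crossprod(Vk, v)
      v <- v - Vk %*% crossprod(Vk, v)
    }
    vn <- sqrt(sum(v^2))
    if (vn <= .Machine$double.eps^0.5) break
    v <- v / vn
    s <- s - v * sum(v * s)
    a <- a + 1L
    R[, a] <- r; TT[, a] <- t; P[, a] <- pk; q[a] <- qk; V[, a] <- v
  }
  if (a == 0L) stop("no latent variable could be extracted", call. = FALSE)
  if (a < ncomp) {
    warning(sprintf("rank exhausted after %d latent variables (requested %d)", a, ncomp))
    R <- R[, seq_len(a), drop = FALSE]; TT <- TT[, seq_len(a), drop = FALSE]
    P <- P[, seq_len(a), drop = FALSE]; q <- q[seq_len(a)]
  }
  coef_path <- matrix(0, p, a)
  for (k in seq_len(a)) coef_path[, k] <- R[, seq_len(k), drop = FALSE] %*% q[seq_len(k)]
  structure(list(x_mean = x_mean, y_mean = y_mean, weights = R, scores = TT,
                 x_loadings = P, y_loadings = q, coef_path = coef_path,
                 ncomp = a),
            class = "simpls")
}

#' Predict from a SIMPLS model
#'
#' `(X_new - x_mean) %*% coef_path[, ncomp] + y_mean`.
#'
#' @param object a [simpls()] fit.
#' @param newdata matrix (or vector) of predictors with the training channel
#'   count.
#' @param ncomp number of latent variables to use, `1..object$ncomp`
#'   (default all).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.simpls <- function(object, newdata, ncomp = object$ncomp, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("newdata has the wrong number of predictors", call. = FALSE)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > object$ncomp)
    stop(sprintf("ncomp must be in 1..%d", object$ncomp), call. = FALSE)
  drop(sweep(newdata, 2L, object$x_mean, "-") %*% object$coef_path[, ncomp] +
         object$y_mean)
}

#' @export
coef.simpls <- function(object, ncomp = object$ncomp, ...) {
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > object$ncomp)
    stop(sprintf("ncomp must be in 1..%d", object$ncomp), call. = FALSE)
  object$coef_path[, ncomp]
}

#' @export
print.simpls <- function(x, ...) {
  cat(sprintf("SIMPLS model: %d predictors, %d samples, %d latent variable(s)\n",
              length(x$x_mean), nrow(x$scores), x$ncomp))
  invisible(x)
}

#' @export
fitted.simpls <- function(object, ncomp = object$ncomp, ...) {
  drop(object$scores[, seq_len(ncomp), drop = FALSE] %*%
         object$y_loadings[seq_len(ncomp)] + object$y_mean)
}

#' Choose the latent-variable count from an RMSE curve
#'
#' The global minimum of the cross-validation RMSE curve over latent
#' variables; ties are broken toward fewer latent variables.
#'
#' @param rmsecv_by_lv nonnegative numeric vector, element k the RMSECV with
#'   k latent variables.
#' @return the chosen latent-variable count (1-based).
#' @export
select_latent_variables <- function(rmsecv_by_lv) {
  if (!is.numeric(rmsecv_by_lv) || length(rmsecv_by_lv) == 0L ||
      any(!is.finite(rmsecv_by_lv)) || any(rmsecv_by_lv < 0))
    stop("rmsecv_by_lv must be a nonempty vector of nonnegative values", call. = FALSE)
  which.min(rmsecv_by_lv)  # which.min returns the first minimum
}

#' Regression coefficients against wavenumber
#'
#' Per-channel regression coefficients at a chosen latent-variable count,
#' paired with the retained wavenumber grid for coefficient-profile plots.
#'
#' @param model a [simpls()] fit.
#' @param ncomp latent-variable count (default the model's maximum).
#' @param grid wavenumbers of the model's channels (same length as
#'   `model$x_mean`); any labels are accepted.
#' @return data frame with columns `wavenumber` and `coefficient`.
#' @export
export_coefficients <- function(model, ncomp = model$ncomp,
                                grid = seq_along(model$x_mean)) {
  if (length(grid) != length(model$x_mean))
    stop("grid length must match the model's channel count", call. = FALSE)
  data.frame(wavenumber = grid, coefficient = coef(model, ncomp = ncomp))
}
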