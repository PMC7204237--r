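#' Robust Mahalanobis spectral outlier screening
#'
#' Multivariate outlier test in the latent-variable space of a PLS
#' calibration: a SIMPLS model with `n_lv` components is fitted to the
#' spectra and response, the robust center and covariance of the score
#' matrix are estimated by the minimum covariance determinant (coverage
#' fraction 0.75, via [MASS::cov.rob()]), and squared Mahalanobis distances
#' of all rows are compared against the chi-squared quantile with `n_lv`
#' degrees of freedom at tail probability `alpha`. All components are used
#' at once, so the test sees the joint spectral structure rather than single
#' channels.
#'
#' @param X spectra matrix (samples x channels), typically absorbance on the
#'   retained informative regions.
#' @param y response vector used to orient the latent variables.
#' @param n_lv number of latent variables for the score space (>= 1;
#'   `nrow(X) >= 3 * n_lv` required for a stable robust covariance).
#' @param alpha tail probability of the chi-squared cutoff (default 0.025).
#' @return list with `flag` (logical vector), `distance` (squared robust
#'   Mahalanobis distances), `cutoff`, `n_lv`, `alpha`.
#' @export
detect_spectral_outliers <- function(X, y, n_lv, alpha = 0.025) {
  X <- as.matrix(X)
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L) stop("n_lv must be >= 1", call. = FALSE)
  if (nrow(X) < 3L * n_lv)
    stop("need at least 3 * n_lv rows for robust covariance estimation", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  fit <- suppressWarnings(simpls(X, y, ncomp = n_lv))
  scores <- fit$scores
  k <- ncol(scores)
  rob <- MASS::cov.rob(scores, method = "mcd",
                       quantile.used = floor(0.75 * nrow(scores)))
  covm <- rob$cov
  d2 <- tryCatch(stats::mahalanobis(scores, rob$center, covm),
                 error = function(e) NULL)
  if (is.null(d2)) {
    warning("robust covariance singular; ridge added")
    covm <- covm + diag(1e-10 * sum(diag(covm)) / k, k)
    d2 <- stats::mahalanobis(scores, rob$center, covm)
  }
  cutoff <- stats::qchisq(1 - alpha, df = k)
  list(flag = d2 > cutoff, distance = d2, cutoff = cutoff,
       n_lv = k, alpha = alpha)
}
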