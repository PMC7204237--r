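#' Run configuration for the heat-production calibration pipeline
#'
#' Defaults follow the study design the package implements: the three
#' informative spectral regions, a random 10x10 cross-validation, an
#' external 4-fold validation with inner latent-variable selection, robust
#' outlier screening in report-only mode, raw (underivatized) absorbance
#' spectra, and the divide-by-two yield-weighted fusion.
#'
#' @param regions list of retained wavenumber intervals
#'   (default [milk_info_regions()]).
#' @param lv_range latent-variable counts to search; `NULL` (default) means
#'   `1:min(20, rank)`.
#' @param cv_splits,cv_iterations random cross-validation layout
#'   (defaults 10 and 10).
#' @param quarters external validation parts (default 4).
#' @param outlier_n_lv,outlier_alpha outlier-screen settings (defaults 10
#'   and 0.025).
#' @param drop_outliers drop flagged rows before fitting (default `FALSE`:
#'   flags are reported only).
#' @param derivative_order 0 (raw spectra, default), 1 or 2.
#' @param derivative_gap channel gap for the derivative (default 1).
#' @param m3_divisor `"two"` (default) or `"total_yield"`; see [combine_m3()].
#' @param rpd_denominator `"rmsecv"` (default) or `"sep"` (bias-corrected
#'   standard error of prediction on the cross-validated residuals).
#' @param nu_default urinary nitrogen assumed when unmeasured, g/d
#'   (default 150).
#' @return a list of class `hp_config`.
#' @export
hp_config <- function(regions = milk_info_regions(), lv_range = NULL,
                      cv_splits = 10L, cv_iterations = 10L, quarters = 4L,
                      outlier_n_lv = 10L, outlier_alpha = 0.025,
                      drop_outliers = FALSE,
                      derivative_order = 0L, derivative_gap = 1L,
                      m3_divisor = c("two", "total_yield"),
                      rpd_denominator = c("rmsecv", "sep"),
                      nu_default = 150) {
  structure(list(regions = regions, lv_range = lv_range,
                 cv_splits = as.integer(cv_splits),
                 cv_iterations = as.integer(cv_iterations),
                 quarters = as.integer(quarters),
                 outlier_n_lv = as.integer(outlier_n_lv),
                 outlier_alpha = outlier_alpha,
                 drop_outliers = isTRUE(drop_outliers),
                 derivative_order = as.integer(derivative_order),
                 derivative_gap = as.integer(derivative_gap),
                 m3_divisor = match.arg(m3_divisor),
                 rpd_denominator = match.arg(rpd_denominator),
                 nu_default = nu_default),
            class = "hp_config")
}

#' Univariate linear calibration of heat production on milk yield
#'
#' Ordinary least squares of heat production (kJ/kg^0.75) on daily milk
#' yield (L/d), the yield-only reference model against which the spectral
#' calibrations are judged.
#'
#' @param yield daily milk yield vector, L/d, non-constant.
#' @param hp heat production vector, kJ/kg^0.75/d.
#' @return object of class `l1_fit`: `mu` (intercept), `beta` (slope,
#'   kJ kg^-0.75 per L), `r2`, `residual_sd`, `fitted`, `residuals`, and
#'   the underlying `lm` fit.
#' @export
fit_l1 <- function(yield, hp) {
  if (length(yield) < 3L || length(yield) != length(hp))
    stop("need at least three paired observations", call. = FALSE)
  if (stats::var(yield) == 0) stop("milk yield is constant", call. = FALSE)
  fit <- stats::lm(hp ~ yield)
  structure(list(mu = unname(stats::coef(fit)[1]),
                 beta = unname(stats::coef(fit)[2]),
                 r2 = summary(fit)$r.squared,
                 residual_sd = summary(fit)$sigma,
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(stats::residuals(fit)),
                 lm = fit),
            class = "l1_fit")
}

#' @export
print.l1_fit <- function(x, ...) {
  cat(sprintf("Linear yield model: HP = %.2f + %.3f * yield, R2 = %.3f\n",
              x$mu, x$beta, x$r2))
  invisible(x)
}

# Assemble per-cow-day predictor matrix + response for one fusion scheme.
# Returns X (cow-days x retained channels), y (HP per mBW), retained grid,
# yields, keys; cow-days missing a session are dropped with a warning.
assemble_design <- function(dataset, mode, config) {
  stopifnot(inherits(dataset, "cowday_dataset"))
  mk <- dataset$milkings
  key <- paste(mk$cow_id, mk$date)
  am_idx <- which(mk$session == "AM")
  pm_idx <- which(mk$session == "PM")
  am <- am_idx[match(unique(key), key[am_idx])]
  pm <- pm_idx[match(unique(key), key[pm_idx])]
  ok <- !is.na(am) & !is.na(pm)
  if (any(!ok))
    warning(sprintf("%d cow-day(s) missing an AM or PM milking; skipped", sum(!ok)))
  am <- am[ok]; pm <- pm[ok]
  keys <- unique(key)[ok]
  if (length(keys) < 10L)
    stop("fewer than 10 usable cow-days", call. = FALSE)

  absorb <- to_absorbance(dataset$spectra)
  sel <- select_regions(dataset$grid, absorb, regions = config$regions)
  grid_r <- sel$grid
  A <- sel$spectrum
  if (config$derivative_order > 0L) {
    A <- apply_derivative(A, order = config$derivative_order,
                          gap = config$derivative_gap)
    drop_n <- config$derivative_order * config$derivative_gap
    grid_r <- grid_r[seq_len(length(grid_r) - drop_n)]
  }

  n <- length(keys)
  X <- matrix(NA_real_, n, ncol(A))
  for (i in seq_len(n)) {
    a_am <- A[am[i], ]; a_pm <- A[pm[i], ]
    y_am <- mk$milk_yield_l[am[i]]; y_pm <- mk$milk_yield_l[pm[i]]
    X[i, ] <- switch(mode,
      M1 = combine_m1(a_am, a_pm),
      M2 = combine_m2(a_am, a_pm, y_am, y_pm),
      M3 = combine_m3(a_am, a_pm, y_am, y_pm, divisor = config$m3_divisor))
  }

  cal <- dataset$calorimetry
  cal_key <- paste(cal$cow_id, cal$date)
  idx <- match(keys, cal_key)
  if (any(is.na(idx)))
    stop("calorimetry records missing for some cow-days", call. = FALSE)
  g <- gas_exchange(cal$v_o2[idx], cal$v_co2[idx], cal$v_ch4[idx],
                    nu = cal$nu_g[idx])
  hp <- normalize_hp(brouwer_heat_production(g), cal$bw_kg[idx])

  list(X = X, y = hp$hp_per_mbw, grid = grid_r, keys = keys,
       daily_yield = mk$milk_yield_l[am] + mk$milk_yield_l[pm])
}

#' Fit a spectra/yield heat-production calibration end to end
#'
#' The package's main fitting function. For one fusion scheme it runs:
#' absorbance transform, informative-region selection, optional derivative
#' pre-treatment, robust outlier screening, AM/PM fusion (M1 plain average;
#' M2 average times daily yield; M3 yield-weighted average), random 10x10
#' cross-validation over latent-variable counts, selection of the count
#' minimizing RMSECV, a calibration SIMPLS fit at that count, external
#' 4-fold validation with inner re-selection, and the agreement statistics
#' (Lin's concordance on the cross-validated predictions, RPD).
#'
#' @param dataset a `cowday_dataset` (from [generate_dataset()] or
#'   [read_dataset()]).
#' @param mode fusion scheme, `"M1"`, `"M2"` or `"M3"`.
#' @param config a [hp_config()].
#' @param seed integer seed driving all cross-validation randomness.
#' @return object of class `hp_pls` with the fitted [simpls()] model
#'   (`model`), chosen latent-variable count (`lv`), the metric row
#'   (`metrics`: R2/RMSEP calibration, R2CV/RMSECV, R2V/RMSEV, CCC, RPD),
#'   cross-validation objects (`cv`, `external`), retained grid, response
#'   and fitted values, and the outlier screen (`outliers`).
#' @seealso [hp_report()] to run several schemes and tabulate them.
#' @examples
#' \donttest{
#' ds <- generate_dataset(generator_config(n_cows = 30, obs_per_cow = 1))
#' fit <- hp_pls(ds, mode = "M3", seed = 7)
#' summary(fit)
#' }
#' @export
hp_pls <- function(dataset, mode = c("M3", "M2", "M1"), config = hp_config(),
                   seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "hp_config"))
  des <- assemble_design(dataset, mode, config)
  X <- des$X; y <- des$y

  out <- detect_spectral_outliers(X, y,
                                  n_lv = min(config$outlier_n_lv,
                                             nrow(X) %/% 3L, ncol(X)),
                                  alpha = config$outlier_alpha)
  if (config$drop_outliers && any(out$flag)) {
    keep <- !out$flag
    X <- X[keep, , drop = FALSE]; y <- y[keep]
    des$keys <- des$keys[keep]; des$daily_yield <- des$daily_yield[keep]
  }

  cv_seed <- (as.integer(seed) %% 1000003L) + 1L
  cv <- random_cross_validate(X, y, n_splits = config$cv_splits,
                              n_iterations = config$cv_iterations,
                              lv_range = config$lv_range, seed = cv_seed)
  best <- select_latent_variables(cv$rmse_by_lv)
  lv <- cv$lv_range[best]

  model <- suppressWarnings(simpls(X, y, ncomp = lv))
  cal_pred <- predict(model, X, ncomp = model$ncomp)
  ext <- external_cross_validate(X, y, n_quarters = config$quarters,
                                 lv_range = config$lv_range,
                                 seed = cv_seed + 1L,
                                 inner_splits = config$cv_splits,
                                 inner_iterations = config$cv_iterations)

  oof <- cv$oof_pred[, best]
  ccc <- lin_ccc(y, oof)
  rpd_denom <- if (config$rpd_denominator == "rmsecv") cv$rmse_by_lv[best]
  else {                       # bias-corrected SEP of the CV residuals
    r <- y - oof
    sqrt(sum((r - mean(r))^2) / (length(r) - 1L))
  }
  metrics <- data.frame(
    model = mode, n = length(y), lv = lv,
    r2_cal = r_squared(y, cal_pred), rmsep = rmsep(y, cal_pred),
    r2_cv = cv$r2_by_lv[best], rmsecv = cv$rmse_by_lv[best],
    r2_v = ext$r2v, rmsev = ext$rmsev,
    ccc = ccc, rpd = rpd(stats::sd(y), rpd_denom),
    stringsAsFactors = FALSE
  )
  structure(list(mode = mode, model = model, lv = lv, metrics = metrics,
                 cv = cv, external = ext, grid = des$grid, y = y,
                 fitted = cal_pred, oof_pred = oof, keys = des$keys,
                 daily_yield = des$daily_yield, outliers = out,
                 config = config, seed = seed),
            class = "hp_pls")
}

#' @export
print.hp_pls <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Heat-production PLS calibration (%s): %d cow-days, %d channels, %d LV\n",
              x$mode, m$n, length(x$grid), m$lv))
  cat(sprintf("  calibration R2 %.3f, RMSEP %.1f | R2CV %.3f, RMSECV %.1f | R2V %.3f, RMSEV %.1f\n",
              m$r2_cal, m$rmsep, m$r2_cv, m$rmsecv, m$r2_v, m$rmsev))
  cat(sprintf("  CCC %.3f, RPD %.2f\n", m$ccc, m$rpd))
  invisible(x)
}

#' @export
summary.hp_pls <- function(object, ...) {
  print(object)
  if (any(object$outliers$flag))
    cat(sprintf("  outlier screen: %d of %d cow-days flagged (alpha %.3g)%s\n",
                sum(object$outliers$flag), length(object$outliers$flag),
                object$outliers$alpha,
                if (object$config$drop_outliers) ", dropped" else ", retained"))
  else cat("  outlier screen: no cow-day flagged\n")
  invisible(object$metrics)
}

#' @export
coef.hp_pls <- function(object, ...) {
  export_coefficients(object$model, ncomp = object$model$ncomp,
                      grid = object$grid)
}

#' @export
fitted.hp_pls <- function(object, ...) object$fitted

#' @export
residuals.hp_pls <- function(object, ...) object$y - object$fitted

#' Predict heat production for new cow-days
#'
#' Applies the stored preprocessing (absorbance, region selection,
#' derivative, fusion scheme) to a new `cowday_dataset` and evaluates the
#' calibration at its chosen latent-variable count.
#'
#' @param object an [hp_pls()] fit.
#' @param newdata a `cowday_dataset`, or a ready predictor matrix with the
#'   model's channel count.
#' @param ... unused.
#' @return named vector of predicted heat production, kJ/kg^0.75/d.
#' @export
predict.hp_pls <- function(object, newdata, ...) {
  if (inherits(newdata, "cowday_dataset")) {
    des <- assemble_design(newdata, object$mode, object$config)
    pred <- predict(object$model, des$X, ncomp = object$model$ncomp)
    names(pred) <- des$keys
    pred
  } else {
    predict(object$model, newdata, ncomp = object$model$ncomp)
  }
}

#' Diagnostic plots for a heat-production calibration
#'
#' Left: cross-validation RMSE against latent-variable count with the
#' chosen count marked. Right: cross-validated predictions against observed
#' heat production with the concordance line.
#'
#' @param x an [hp_pls()] fit.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.hp_pls <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$cv$lv_range, x$cv$rmse_by_lv, type = "b", xlab = "latent variables",
       ylab = "RMSECV (kJ/kg^0.75)", main = paste("LV selection,", x$mode), ...)
  graphics::abline(v = x$lv, lty = 2)
  plot(x$y, x$oof_pred, xlab = "observed HP (kJ/kg^0.75)",
       ylab = "cross-validated prediction", main = sprintf("CCC %.2f", x$metrics$ccc),
       ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Run several calibration schemes and tabulate them
#'
#' Fits the requested fusion schemes (and the yield-only linear reference)
#' on one dataset with a shared seed and collects the statistics in one
#' table: chosen latent variables, calibration R2/RMSEP, cross-validation
#' R2CV/RMSECV, external-validation R2V/RMSEV, CCC and RPD.
#'
#' @param dataset a `cowday_dataset`.
#' @param modes subset of `c("L1", "M1", "M2", "M3")`.
#' @param config a [hp_config()].
#' @param seed integer seed shared by all schemes (paired comparisons).
#' @return object of class `hp_report`: list with `table` (one row per
#'   scheme) and `fits` (the underlying objects).
#' @export
hp_report <- function(dataset, modes = c("L1", "M1", "M2", "M3"),
                      config = hp_config(), seed = 1L) {
  modes <- match.arg(modes, several.ok = TRUE)
  fits <- list()
  rows <- list()
  for (m in modes) {
    if (m == "L1") {
      tab <- cowday_table(dataset)
      fit <- fit_l1(tab$daily_yield_l, tab$hp_per_mbw)
      rows[[m]] <- data.frame(model = "L1", n = nrow(tab), lv = NA_integer_,
                              r2_cal = fit$r2,
                              rmsep = rmsep(tab$hp_per_mbw, fit$fitted),
                              r2_cv = NA_real_, rmsecv = NA_real_,
                              r2_v = NA_real_, rmsev = NA_real_,
                              ccc = lin_ccc(tab$hp_per_mbw, fit$fitted),
                              rpd = rpd(stats::sd(tab$hp_per_mbw),
                                        rmsep(tab$hp_per_mbw, fit$fitted)),
                              stringsAsFactors = FALSE)
    } else {
      fit <- hp_pls(dataset, mode = m, config = config, seed = seed)
      rows[[m]] <- fit$metrics
    }
    fits[[m]] <- fit
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 fits = fits),
            class = "hp_report")
}

#' @export
print.hp_report <- function(x, ...) {
  cat(format_report(x$table), sep = "\n")
  invisible(x)
}

#' Format a calibration report table as aligned text
#'
#' @param table the `table` element of an [hp_report()], or any data frame
#'   with the same columns.
#' @return character vector of report lines.
#' @export
format_report <- function(table) {
  num <- vapply(names(table), function(nm) is.numeric(table[[nm]]), logical(1))
  shown <- table
  for (nm in names(shown)[num])
    shown[[nm]] <- ifelse(is.na(table[[nm]]), "-",
                          formatC(table[[nm]],
                                  digits = if (nm %in% c("n", "lv")) 0 else
                                    if (grepl("rmse", nm)) 1 else 3,
                                  format = "f"))
  widths <- pmax(nchar(names(shown)),
                 apply(shown, 2, function(col) max(nchar(col))))
  fmt_row <- function(vals) paste(mapply(formatC, vals, width = widths),
                                  collapse = "  ")
  c(fmt_row(names(shown)), apply(shown, 1, fmt_row))
}

#' Write a calibration report to CSV
#'
#' @param report an [hp_report()] or its table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  tab <- if (inherits(report, "hp_report")) report$table else report
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a calibration report CSV
#'
#' @param path CSV written by [write_report_csv()].
#' @return the report table as a data frame.
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
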