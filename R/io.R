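#' Write milking-level spectra to wide CSV
#'
#' One row per milking: `cow_id`, `date`, `session` ("AM"/"PM"),
#' `milk_yield_l`, `scale` ("transmittance" or "absorbance"), then one
#' column per channel named `wn_<wavenumber>` with the wavenumber rounded to
#' 4 significant digits (unique on the default grid).
#'
#' @param dataset a `cowday_dataset`, or a list with `grid`, `milkings`,
#'   `spectra`.
#' @param path output CSV path.
#' @param scale scale of the stored spectra (default "transmittance", the
#'   scale [generate_dataset()] produces).
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(dataset, path, scale = "transmittance") {
  mk <- dataset$milkings
  spec <- as.data.frame(dataset$spectra)
  names(spec) <- paste0("wn_", signif(dataset$grid, 4))
  out <- cbind(mk[, c("cow_id", "date", "session", "milk_yield_l")],
               scale = scale, spec)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read milking-level spectra from wide CSV
#'
#' Validates the schema written by [write_spectra_csv()]: monotonically
#' increasing channel wavenumbers, a recognized scale, nonnegative yields,
#' transmittance in (0, 1], sessions in {AM, PM}, and unique
#' (cow, date, session) keys. Errors carry the offending row number or
#' channel name.
#'
#' @param path CSV path.
#' @return list with `grid` (wavenumbers parsed from the header),
#'   `milkings` (data frame), `spectra` (matrix), `scale`.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("cow_id", "date", "session", "milk_yield_l", "scale")
  if (!all(meta_cols %in% names(df)))
    stop(sprintf("malformed header: expected columns %s",
                 paste(meta_cols, collapse = ", ")), call. = FALSE)
  wn_cols <- grep("^wn_", names(df), value = TRUE)
  if (length(wn_cols) == 0L) stop("no channel columns (wn_*) found", call. = FALSE)
  grid <- as.numeric(sub("^wn_", "", wn_cols))
  if (any(is.na(grid))) stop("non-numeric channel name in header", call. = FALSE)
  if (any(diff(grid) <= 0))
    stop("channel wavenumbers must be strictly increasing left to right", call. = FALSE)
  for (cc in wn_cols) if (!is.numeric(df[[cc]])) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))))[1]
    stop(sprintf("non-numeric spectral value in column %s, row %d", cc, bad),
         call. = FALSE)
  }
  if (!all(df$session %in% c("AM", "PM"))) {
    bad <- which(!df$session %in% c("AM", "PM"))[1]
    stop(sprintf("invalid session literal in row %d (must be AM or PM)", bad),
         call. = FALSE)
  }
  if (any(df$milk_yield_l < 0)) {
    bad <- which(df$milk_yield_l < 0)[1]
    stop(sprintf("negative milk yield in row %d", bad), call. = FALSE)
  }
  scale <- unique(df$scale)
  if (length(scale) != 1L || !scale %in% c("transmittance", "absorbance"))
    stop("scale must be uniformly 'transmittance' or 'absorbance'", call. = FALSE)
  key <- paste(df$cow_id, df$date, df$session)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop(sprintf("duplicate milking record for (%s)", d), call. = FALSE)
  }
  spectra <- as.matrix(df[, wn_cols, drop = FALSE])
  dimnames(spectra) <- list(NULL, wn_cols)
  if (scale == "transmittance") {
    bad <- which(spectra <= 0 | spectra > 1, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("transmittance outside (0, 1] in row %d, channel %s",
                   bad[1, 1], wn_cols[bad[1, 2]]), call. = FALSE)
  }
  list(grid = grid,
       milkings = df[, c("cow_id", "date", "session", "milk_yield_l")],
       spectra = spectra, scale = scale)
}

#' Write cow-day calorimetry records to CSV
#'
#' Columns: `cow_id`, `date`, `bw_kg`, `v_o2`, `v_co2`, `v_ch4`, `nu_g`,
#' `nu_assumed`.
#'
#' @param dataset a `cowday_dataset` or a data frame with those columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_calorimetry_csv <- function(dataset, path) {
  df <- if (inherits(dataset, "cowday_dataset")) dataset$calorimetry else dataset
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read cow-day calorimetry records from CSV
#'
#' Validates nonnegative gas volumes and positive body weight. A missing
#' `nu_g` column is filled with `nu_default` (urinary N assumed rather than
#' measured) and flagged in `nu_assumed`, with a message.
#'
#' @param path CSV path.
#' @param nu_default urinary nitrogen assumed when absent, g/d (default 150).
#' @return data frame with columns `cow_id`, `date`, `bw_kg`, `v_o2`,
#'   `v_co2`, `v_ch4`, `nu_g`, `nu_assumed`.
#' @export
read_calorimetry_csv <- function(path, nu_default = 150) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cow_id", "date", "bw_kg", "v_o2", "v_co2", "v_ch4")
  if (!all(need %in% names(df)))
    stop(sprintf("malformed header: expected columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  for (cc in c("bw_kg", "v_o2", "v_co2", "v_ch4")) {
    if (!is.numeric(df[[cc]]))
      stop(sprintf("column %s must be numeric", cc), call. = FALSE)
    if (cc == "bw_kg" && any(df[[cc]] <= 0)) {
      stop(sprintf("nonpositive body weight in row %d", which(df[[cc]] <= 0)[1]),
           call. = FALSE)
    }
    if (cc != "bw_kg" && any(df[[cc]] < 0)) {
      stop(sprintf("negative %s in row %d", cc, which(df[[cc]] < 0)[1]),
           call. = FALSE)
    }
  }
  if (!"nu_g" %in% names(df)) {
    message(sprintf("no urinary-N column; assuming nu = %g g/d for all records",
                    nu_default))
    df$nu_g <- nu_default
    df$nu_assumed <- TRUE
  } else if (!"nu_assumed" %in% names(df)) {
    df$nu_assumed <- FALSE
  }
  if (any(df$nu_g < 0))
    stop(sprintf("negative nu_g in row %d", which(df$nu_g < 0)[1]), call. = FALSE)
  df
}

#' Write the generator ground truth to CSV
#'
#' @param dataset a `cowday_dataset` with a `truth` element.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(dataset, path) {
  utils::write.csv(dataset$truth, path, row.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits `spectra.csv`, `calorimetry.csv` and `ground_truth.csv`, the three
#' tables the readers consume.
#'
#' @param dataset a `cowday_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_spectra_csv(dataset, file.path(dir, "spectra.csv"))
  write_calorimetry_csv(dataset, file.path(dir, "calorimetry.csv"))
  write_ground_truth_csv(dataset, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' Read a cow-day dataset from CSV tables
#'
#' Reassembles a `cowday_dataset` from `spectra.csv` and `calorimetry.csv`
#' (and `ground_truth.csv` if present) as written by [write_dataset()].
#' Absorbance-scale spectra are converted back to transmittance.
#'
#' @param dir directory containing the tables.
#' @param nu_default urinary N assumed when the calorimetry table lacks it.
#' @return a `cowday_dataset`.
#' @export
read_dataset <- function(dir, nu_default = 150) {
  sp <- read_spectra_csv(file.path(dir, "spectra.csv"))
  cal <- read_calorimetry_csv(file.path(dir, "calorimetry.csv"), nu_default)
  spectra <- sp$spectra
  if (sp$scale == "absorbance") spectra <- to_transmittance(spectra)
  truth_path <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(truth_path))
    utils::read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  structure(list(grid = sp$grid, milkings = sp$milkings, spectra = spectra,
                 calorimetry = cal, truth = truth, config = NULL),
            class = "cowday_dataset")
}

#' Serialize a SIMPLS calibration to JSON
#'
#' Stores centering vectors, the per-LV coefficient path and free-form
#' metadata (fusion scheme, retained regions, chosen latent-variable
#' count), sufficient to reapply the calibration.
#'
#' @param model a [simpls()] fit or the `model` element of an [hp_pls()].
#' @param path output JSON path.
#' @param metadata named list stored verbatim.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path, metadata = list()) {
  if (inherits(model, "hp_pls")) {
    metadata <- c(metadata, list(mode = model$mode, lv = model$lv,
                                 wavenumbers = model$grid))
    model <- model$model
  }
  payload <- list(x_mean = model$x_mean, y_mean = model$y_mean,
                  coef_path = model$coef_path, ncomp = model$ncomp,
                  metadata = metadata)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a SIMPLS calibration from JSON
#'
#' @param path JSON written by [write_model_json()].
#' @return list with `x_mean`, `y_mean`, `coef_path` (matrix), `ncomp`,
#'   `metadata`; usable with [predict.simpls()] after class restoration,
#'   which this function performs.
#' @export
read_model_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$coef_path <- as.matrix(payload$coef_path)
  structure(payload, class = "simpls")
}

#' Read a generator configuration from YAML or JSON
#'
#' Accepts a file holding any subset of the [generator_config()] fields;
#' unspecified fields keep their defaults. YAML requires the `yaml`
#' package.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return a validated `generator_config`.
#' @export
read_generator_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml, .yml or .json", call. = FALSE)
  for (f in c("composition_means", "composition_sds", "session_sds"))
    if (!is.null(vals[[f]])) vals[[f]] <- unlist(vals[[f]])
  if (!is.null(vals$band_library)) vals$band_library <- as.data.frame(vals$band_library)
  do.call(generator_config, vals)
}
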