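#' Metabolic body weight
#'
#' Allometric scaling of body weight, `mBW = BW^0.75` (kg^0.75), the
#' conventional scale for maintenance energy in ruminant energetics.
#'
#' @param bw body weight in kg; strictly positive, vectorized.
#' @return mBW in kg^0.75.
#' @examples
#' metabolic_body_weight(c(500, 915))
#' @export
metabolic_body_weight <- function(bw) {
  if (!is.numeric(bw) || any(!is.finite(bw)) || any(bw <= 0))
    stop("body weight must be a positive finite number (kg)", call. = FALSE)
  bw^0.75
}

#' Gas-exchange record
#'
#' Bundles the daily respiration-chamber measurements that feed the Brouwer
#' equation: oxygen consumption, carbon dioxide and methane production (L/d)
#' and urinary nitrogen excretion (g/d). Urinary N is rarely measured in
#' routine chamber runs; when absent it is assumed at 150 g/d and the record
#' is flagged, since the assumption contributes at most about 1% to heat
#' production at typical gas volumes (see [nu_term_fraction()]).
#'
#' @param v_o2,v_co2,v_ch4 daily gas volumes, L/d, nonnegative (vectorized).
#' @param nu urinary nitrogen, g/d, nonnegative. Default 150.
#' @param nu_assumed logical, whether `nu` was assumed rather than measured.
#' @return an object of class `gas_exchange` (a list of equal-length vectors).
#' @export
gas_exchange <- function(v_o2, v_co2, v_ch4, nu = 150, nu_assumed = missing(nu)) {
  vals <- list(v_o2 = v_o2, v_co2 = v_co2, v_ch4 = v_ch4, nu = nu)
  for (f in names(vals)) {
    v <- vals[[f]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
      stop(sprintf("gas exchange field '%s' must be nonnegative and finite", f),
           call. = FALSE)
  }
  n <- max(lengths(vals))
  vals <- lapply(vals, rep_len, n)
  structure(c(vals, list(nu_assumed = rep_len(nu_assumed, n))),
            class = "gas_exchange")
}

#' Brouwer heat production
#'
#' Indirect-calorimetry heat production (kJ/d) from daily gas exchange:
#' `HP = 16.18 V_O2 + 5.02 V_CO2 - 2.17 V_CH4 - 5.99 N_u`
#' with volumes in L/d and urinary nitrogen in g/d.
#'
#' @param g a [gas_exchange()] object.
#' @return heat production in kJ/d (vectorized over records).
#' @examples
#' brouwer_heat_production(gas_exchange(6740, 7072, 570, nu = 150))
#' @export
brouwer_heat_production <- function(g) {
  if (!inherits(g, "gas_exchange"))
    stop("'g' must be a gas_exchange object", call. = FALSE)
  16.18 * g$v_o2 + 5.02 * g$v_co2 - 2.17 * g$v_ch4 - 5.99 * g$nu
}

#' Normalize heat production to metabolic body weight
#'
#' @param hp_total heat production, kJ/d.
#' @param bw body weight, kg (> 0).
#' @return a `heat_production` list with `hp_total` (kJ/d), `mbw` (kg^0.75)
#'   and `hp_per_mbw` (kJ/kg^0.75/d), vectorized.
#' @export
normalize_hp <- function(hp_total, bw) {
  if (!is.numeric(hp_total) || any(!is.finite(hp_total)))
    stop("hp_total must be finite numeric (kJ/d)", call. = FALSE)
  mbw <- metabolic_body_weight(bw)
  n <- max(length(hp_total), length(mbw))
  hp_total <- rep_len(hp_total, n)
  mbw <- rep_len(mbw, n)
  structure(list(hp_total = hp_total, mbw = mbw, hp_per_mbw = hp_total / mbw),
            class = "heat_production")
}

#' Share of the urinary-nitrogen term in Brouwer heat production
#'
#' The percentage `100 * 5.99 * N_u / HP`, quantifying the error incurred by
#' assuming rather than measuring urinary N.
#'
#' @param g a [gas_exchange()] object with positive Brouwer heat production.
#' @return percentage (vectorized).
#' @export
nu_term_fraction <- function(g) {
  hp <- brouwer_heat_production(g)
  if (any(hp <= 0))
    stop("heat production must be positive to express the N_u share", call. = FALSE)
  100 * (5.99 * g$nu) / hp
}

#' Descriptive summary of a cow-day dataset
#'
#' Table of minimum, maximum, mean, median and sample standard deviation
#' (n-1 denominator) for body weight, metabolic body weight, daily milk
#' yield, the three gas volumes and heat production per metabolic body
#' weight, in the layout customary for chamber-study descriptive tables.
#'
#' @param dataset a `cowday_dataset` (see [generate_dataset()]) or a data
#'   frame with columns `bw_kg`, `daily_yield_l`, `v_o2`, `v_co2`, `v_ch4`,
#'   `hp_per_mbw`.
#' @return a data frame with one row per variable and columns
#'   `variable`, `minimum`, `maximum`, `mean`, `median`, `sd`.
#' @export
summarize_dataset <- function(dataset) {
  df <- if (inherits(dataset, "cowday_dataset")) cowday_table(dataset) else dataset
  if (!is.data.frame(df) || nrow(df) == 0L)
    stop("summarize_dataset needs at least one cow-day record", call. = FALSE)
  if (!"mbw" %in% names(df) && "bw_kg" %in% names(df))
    df$mbw <- metabolic_body_weight(df$bw_kg)
  vars <- c(bw_kg = "BW, kg", mbw = "mBW, kg^0.75",
            daily_yield_l = "Milk yield, L/d",
            v_o2 = "O2, L", v_co2 = "CO2, L", v_ch4 = "CH4, L",
            hp_per_mbw = "Heat production, kJ/kg^0.75")
  vars <- vars[names(vars) %in% names(df)]
  if (length(vars) == 0L) stop("no summarizable columns found", call. = FALSE)
  rows <- lapply(names(vars), function(v) {
    x <- df[[v]]
    data.frame(variable = vars[[v]], minimum = min(x), maximum = max(x),
               mean = mean(x), median = stats::median(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Flat cow-day table (one row per cow-day) from a cowday_dataset: body
# weight, gas exchange, computed HP, daily yield.
cowday_table <- function(dataset) {
  stopifnot(inherits(dataset, "cowday_dataset"))
  cal <- dataset$calorimetry
  g <- gas_exchange(cal$v_o2, cal$v_co2, cal$v_ch4, nu = cal$nu_g)
  hp <- normalize_hp(brouwer_heat_production(g), cal$bw_kg)
  yields <- stats::aggregate(milk_yield_l ~ cow_id + date, data = dataset$milkings, sum)
  names(yields)[3] <- "daily_yield_l"
  out <- merge(cal, yields, by = c("cow_id", "date"), sort = FALSE)
  out$mbw <- hp$mbw[match(paste(out$cow_id, out$date),
                          paste(cal$cow_id, cal$date))]
  out$hp_total <- hp$hp_total[match(paste(out$cow_id, out$date),
                                    paste(cal$cow_id, cal$date))]
  out$hp_per_mbw <- out$hp_total / out$mbw
  out
}
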