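#' Field (sticky-trap) analyses
#'
#' Water leftover in a sticky trap after its 72-h exposure integrates
#' evaporation (temperature, sun exposure) and refilling (rain), so it
#' serves as a trap-level eco-climatic proxy. Two Gaussian LMMs check
#' that the proxy responds to weather as expected; a Poisson GLMM then
#' models adult counts on water leftover, site and their interaction.
#'
#' @name field-analysis
NULL

#' Join weather to trap collections over the 72-h exposure windows
#'
#' Each collection aggregates the 3 calendar days ending at its date:
#' `tmax` is the mean of daily maxima, `rain` is either the 3-day total
#' divided by 3 (`"mean"`, default) or the plain total (`"sum"`).
#'
#' @param traps a `trap_records` data frame.
#' @param weather data frame with `date`, `tmax`, `rainfall`.
#' @param rainfall `"mean"` or `"sum"` aggregation.
#' @return `traps` with added `tmax` and `rain` columns; errors listing
#'   any collection dates the weather series does not cover.
#' @export
join_weather <- function(traps, weather, rainfall = c("mean", "sum")) {
  rainfall <- match.arg(rainfall)
  traps <- as.data.frame(traps)
  dates <- sort(unique(traps$collection_date))
  covered <- vapply(dates, function(d)
    sum(weather$date >= d - 2 & weather$date <= d) == 3, TRUE)
  if (!all(covered))
    stop_data("weather series does not cover the full 72-h window of collection date(s): ",
              paste(format(dates[!covered]), collapse = ", "))
  ww <- weather_window(weather, dates)
  i <- match(traps$collection_date, dates)
  traps$tmax <- ww[i, "tmax_mean"]
  traps$rain <- if (rainfall == "mean") ww[i, "rain_total"] / 3 else ww[i, "rain_total"]
  traps
}

#' Water-leftover LMM against a weather driver
#'
#' Gaussian LMM: water leftover ~ driver x site, random intercepts for
#' collection date and trap. A negative temperature slope and a positive
#' rainfall slope support water leftover as an eco-climatic proxy.
#'
#' @param traps a `trap_records` data frame.
#' @param weather data frame (`date`, `tmax`, `rainfall`).
#' @param driver `"temperature"` or `"rainfall"`.
#' @param rainfall_agg passed to [join_weather()].
#' @return a `mixed_fit`.
#' @export
run_lmm_water <- function(traps, weather, driver = c("temperature", "rainfall"),
                          rainfall_agg = "mean") {
  driver <- match.arg(driver)
  df <- join_weather(traps, weather, rainfall_agg)
  dv <- if (driver == "temperature") "tmax" else "rain"
  if (stats::sd(df[[dv]]) == 0)
    stop_data(driver, " is constant across collections; slope unidentifiable")
  df$collection <- factor(df$collection_index)
  df$trap <- factor(df$trap_id)
  df$site <- factor(df$site, levels = SITE_LEVELS)
  spec <- model_spec("gaussian", response = "water_leftover",
                     fixed = c(dv, "site", paste0(dv, ":site")),
                     random = c("collection", "trap"))
  fit_lmm(spec, df)
}

#' Poisson abundance model: counts ~ water x site
#'
#' Poisson GLMM of per-trap adult counts on water leftover, site
#' (reference: untreated) and their interaction, with random intercepts
#' for collection date and trap.
#'
#' @param traps a `trap_records` data frame (active rows are used).
#' @return a `mixed_fit`.
#' @export
run_glmm3 <- function(traps) {
  df <- as.data.frame(traps)
  df <- df[df$active & !is.na(df$n_total) & !is.na(df$water_leftover), ]
  df$collection <- factor(df$collection_index)
  df$trap <- factor(df$trap_id)
  df$site <- factor(df$site, levels = SITE_LEVELS)
  df$water <- df$water_leftover
  spec <- model_spec("poisson", response = "n_total",
                     fixed = c("water", "site", "water:site"),
                     random = c("collection", "trap"))
  fit_glmm(spec, df)
}

#' Predicted abundance as a function of water leftover, per site
#'
#' Fixed-part inverse-link curves from the abundance model with
#' delta-method 95% intervals on the log scale.
#'
#' @param fit3 `mixed_fit` from [run_glmm3()].
#' @param water_range numeric vector of water-leftover values (dl).
#' @param conf_level interval coverage.
#' @return data frame: site, water, fit, lower, upper.
#' @export
predicted_abundance_curves <- function(fit3, water_range = seq(0, 8, by = 0.25),
                                       conf_level = 0.95) {
  if (!fit3$converged) warning("abundance model did not converge", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  grid <- expand.grid(water = water_range,
                      site = factor(SITE_LEVELS, SITE_LEVELS),
                      KEEP.OUT.ATTRS = FALSE)
  fp <- fixed_predictor(fit3, grid)
  data.frame(site = grid$site, water = grid$water,
             fit = exp(fp$eta),
             lower = exp(fp$eta - z * fp$se),
             upper = exp(fp$eta + z * fp$se))
}
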