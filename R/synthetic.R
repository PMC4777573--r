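#' Synthetic two-site monitoring and cage-experiment generator
#'
#' Generates data with the statistical structure the downstream models
#' assume: Poisson sticky-trap counts with a log-linear predictor
#' (seasonal curve + site offset + per-site water slope + collection and
#' trap random intercepts + a step suppression in the treated site from a
#' configurable collection onward), water leftover driven by rainfall and
#' temperature, and binomial cage mortality with logistic distance decay
#' and date / line-within-date random intercepts.
#'
#' @name synthetic
NULL

#' Default smooth seasonal curve (log scale)
#'
#' A Gaussian bump in log-abundance peaking at collection 18 (early
#' August for a mid-June start), emulating the late-summer population
#' peak of *Aedes albopictus* in Rome.
#'
#' @param n_collections series length.
#' @param peak collection of maximum abundance.
#' @param width bump width in collections.
#' @param base,amplitude log-scale baseline and bump height.
#' @export
seasonal_curve_default <- function(n_collections = 36, peak = 18, width = 7,
                                   base = -0.9, amplitude = 3.0) {
  x <- seq_len(n_collections)
  base + amplitude * exp(-0.5 * ((x - peak) / width)^2)
}

#' Build a synthetic-data configuration
#'
#' Defaults encode the monitored study design: 24 treated and 19
#' untreated traps, 36 collections, collection/trap random-intercept SDs
#' 0.73 / 0.42, a water slope of -0.40 in the untreated site versus an
#' essentially flat 0.05 in the treated one, and a treated-site count
#' suppression of 0.3 switching on at collection 15. Cage mortality uses
#' logit p = 2.34 - 0.087 * distance (predicted mortality 0.77 at 13 m and
#' 0.22 at 41 m) with line-within-date SD 0.9, and a control-cage
#' intercept of -3.64.
#'
#' @param n_traps_treated,n_traps_untreated traps per site.
#' @param n_collections collections per trap (twice weekly).
#' @param seasonal_curve numeric vector of per-collection log-abundance.
#' @param site_effect log-scale offset of the treated site (pre-divergence).
#' @param treatment_effect multiplicative suppression in (0, 1] applied to
#'   treated-site expected counts from `divergence_index` onward.
#' @param divergence_index first collection at which the suppression acts.
#' @param water_beta named numeric, log-count slope on water leftover (dl)
#'   per site: `c(untreated = ..., treated = ...)`.
#' @param sd_collection,sd_trap random-intercept SDs (log scale).
#' @param collection_share fraction in `[0, 1]` of the collection-level
#'   variance that is shared between the two sites (shared weather
#'   shocks); the remainder is site-specific micro-climate. With 1 the
#'   two sites' collection effects are identical, as in a single-site
#'   model; the default 0.5 emulates sites ~1.4 km apart whose mean
#'   series correlate strongly but not perfectly.
#' @param family `"poisson"` or `"nbinom"` (robustness switch; `nb_size`
#'   is the dispersion parameter).
#' @param nb_size negative-binomial size when `family = "nbinom"`.
#' @param water_model list: `rain_coef` (dl per mm of 3-day rainfall),
#'   `temp_coef` (dl per degree C of mean daily max above `temp_ref`),
#'   `temp_ref`, `sd` (trap-level noise, dl), `cap` (max leftover, dl).
#' @param weather optional data frame (`date`, `tmax`, `rainfall`); if
#'   `NULL` a seasonal series is generated from the seed.
#' @param cage_model list: `beta0`, `beta_distance` (logit mortality
#'   intercept/slope for exposed cages), `beta0_control`, `sd_date`,
#'   `sd_line` (random-intercept SDs), `perm0`, `perm_k`, `perm_sdlog`
#'   (permethrin deposit p0 * exp(-k d) with log-normal noise),
#'   `n_initial` (mosquitoes per cage and sex).
#' @param seed integer seed driving all sampling.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_traps_treated = 24,
                             n_traps_untreated = 19,
                             n_collections = 36,
                             seasonal_curve = seasonal_curve_default(n_collections),
                             site_effect = -1.7,
                             treatment_effect = 0.3,
                             divergence_index = 15,
                             water_beta = c(untreated = -0.40, treated = 0.05),
                             sd_collection = 0.73,
                             sd_trap = 0.42,
                             collection_share = 0.5,
                             family = c("poisson", "nbinom"),
                             nb_size = 5,
                             water_model = list(rain_coef = 0.10, temp_coef = 0.25,
                                                temp_ref = 24, sd = 0.5, cap = 10),
                             weather = NULL,
                             cage_model = list(beta0 = 2.34, beta_distance = -0.087,
                                               beta0_control = -3.64,
                                               sd_date = 0.1, sd_line = 0.9,
                                               perm0 = 0.06, perm_k = 0.05,
                                               perm_sdlog = 0.6, n_initial = 20),
                             seed = 20130617) {
  cfg <- list(n_traps_treated = as.integer(n_traps_treated),
              n_traps_untreated = as.integer(n_traps_untreated),
              n_collections = as.integer(n_collections),
              seasonal_curve = as.numeric(seasonal_curve),
              site_effect = site_effect,
              treatment_effect = treatment_effect,
              divergence_index = as.integer(divergence_index),
              water_beta = water_beta,
              sd_collection = sd_collection, sd_trap = sd_trap,
              collection_share = collection_share,
              family = match.arg(family), nb_size = nb_size,
              water_model = water_model, weather = weather,
              cage_model = cage_model, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (n_traps_treated < 1 || n_traps_untreated < 1)
      stop_data("need at least one trap per site")
    if (length(seasonal_curve) != n_collections)
      stop_data("seasonal_curve must have length n_collections")
    if (!(treatment_effect > 0 && treatment_effect <= 1))
      stop_data("treatment_effect must be in (0, 1]")
    if (divergence_index < 1 || divergence_index > n_collections)
      stop_data("divergence_index must be in 1..n_collections")
    if (sd_collection < 0 || sd_trap < 0)
      stop_data("random-effect SDs must be >= 0")
    if (collection_share < 0 || collection_share > 1)
      stop_data("collection_share must be in [0, 1]")
    if (!all(c("untreated", "treated") %in% names(water_beta)))
      stop_data("water_beta needs named entries 'untreated' and 'treated'")
    if (cage_model$sd_date < 0 || cage_model$sd_line < 0)
      stop_data("cage random-effect SDs must be >= 0")
  })
  invisible(cfg)
}

# Seasonal Rome-summer weather: tmax bump peaking early August, sparse
# gamma-distributed rain days.
generate_weather <- function(dates) {
  day <- as.numeric(dates - dates[1]) + 1
  tmax <- 24 + 9 * exp(-0.5 * ((day - 45) / 35)^2) + stats::rnorm(length(day), 0, 1.5)
  wet <- stats::rbinom(length(day), 1, 0.18)
  rainfall <- wet * stats::rgamma(length(day), shape = 1.2, scale = 8)
  data.frame(date = dates, tmax = round(tmax, 1), rainfall = round(rainfall, 1))
}

# Mean daily tmax and total rainfall over the 3-day exposure window
# ending at each collection date.
weather_window <- function(weather, coll_dates) {
  t(vapply(coll_dates, function(d) {
    sel <- weather$date >= d - 2 & weather$date <= d
    if (!any(sel)) stop_data("weather series does not cover collection date ", d)
    c(tmax_mean = mean(weather$tmax[sel]), rain_total = sum(weather$rainfall[sel]))
  }, c(tmax_mean = 0, rain_total = 0)))
}

#' Simulate a season of two-site sticky-trap monitoring
#'
#' Counts are Poisson (optionally negative-binomial) with log-mean
#' `seasonal_curve[c] + site_effect * treated + water_beta[site] * water +
#' u_collection + u_trap + log(treatment_effect) * treated * (c >=
#' divergence_index)`. Water leftover is `5 + rain_coef * rain -
#' temp_coef * max(tmax - temp_ref, 0) + noise`, truncated at 0 and
#' capped. Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `traps` (a `trap_records` data frame) and
#'   `weather` (date, tmax, rainfall).
#' @export
simulate_monitoring <- function(config) {
  validate_synthetic_config(config)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  C <- config$n_collections
  dates <- collection_dates(C)
  weather <- config$weather
  if (is.null(weather)) {
    span <- seq(dates[1] - 6, dates[C], by = "day")
    weather <- generate_weather(span)
  }
  ww <- weather_window(weather, dates)

  n_tr <- config$n_traps_treated
  n_un <- config$n_traps_untreated
  trap_id <- c(sprintf("TR%02d", seq_len(n_tr)), sprintf("UN%02d", seq_len(n_un)))
  site <- rep(c("treated", "untreated"), c(n_tr, n_un))
  u_trap <- stats::rnorm(n_tr + n_un, 0, config$sd_trap)
  # collection effect = shared weather shock + site-specific micro-climate
  sh <- config$collection_share
  z_shared <- stats::rnorm(C)
  z_site <- matrix(stats::rnorm(2 * C), C, 2, dimnames = list(NULL, SITE_LEVELS))
  u_coll_site <- config$sd_collection *
    (sqrt(sh) * z_shared + sqrt(1 - sh) * z_site)

  wm <- config$water_model
  grid <- expand.grid(trap = seq_len(n_tr + n_un), coll = seq_len(C),
                      KEEP.OUT.ATTRS = FALSE)
  water <- 5 + wm$rain_coef * ww[grid$coll, "rain_total"] -
    wm$temp_coef * pmax(ww[grid$coll, "tmax_mean"] - wm$temp_ref, 0) +
    stats::rnorm(nrow(grid), 0, wm$sd)
  water <- pmin(pmax(water, 0), wm$cap)

  treated <- site[grid$trap] == "treated"
  suppressed <- treated & grid$coll >= config$divergence_index
  eta <- config$seasonal_curve[grid$coll] +
    config$site_effect * treated +
    config$water_beta[ifelse(treated, "treated", "untreated")] * water +
    u_coll_site[cbind(grid$coll, ifelse(treated, 2L, 1L))] + u_trap[grid$trap] +
    log(config$treatment_effect) * suppressed
  mu <- exp(eta)
  n_total <- if (config$family == "poisson") stats::rpois(nrow(grid), mu)
             else stats::rnbinom(nrow(grid), mu = mu, size = config$nb_size)
  n_female <- stats::rbinom(nrow(grid), n_total, 0.5)

  traps <- trap_records(data.frame(
    trap_id = trap_id[grid$trap],
    site = site[grid$trap],
    collection_index = grid$coll,
    collection_date = dates[grid$coll],
    n_female = n_female,
    n_male = n_total - n_female,
    n_total = n_total,
    water_leftover = round(water, 2),
    active = TRUE,
    stringsAsFactors = FALSE))
  list(traps = traps, weather = weather)
}

#' Simulate caged-mosquito spraying experiments
#'
#' For each treatment, three road lines of exposed cages at the given
#' distances, two validation cages (13 m and 41 m) and three control
#' cages, each stocked with `n_initial` females and males. Deaths are
#' Binomial with `logit p = beta0 + beta_distance * d + u_date +
#' u_line(date)` for exposed/validation cages and `beta0_control +
#' u_date` for controls; permethrin deposit decays exponentially with
#' distance under log-normal noise (controls: 0).
#'
#' @param config a [synthetic_config()].
#' @param n_treatments number of monitored sprayings (default 7, T2-T8).
#' @param distances exposed-cage distances in metres.
#' @param validation_distances validation-cage distances in metres.
#' @return a `cage_records` data frame.
#' @export
simulate_cage_experiment <- function(config, n_treatments = 7,
                                     distances = c(10, 30, 50, 70),
                                     validation_distances = c(`VC-1` = 13, `VC-2` = 41)) {
  validate_synthetic_config(config)
  if (any(distances < 0)) stop_data("distances must be >= 0")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed + 1L)

  cm <- config$cage_model
  rows <- list()
  for (t in seq_len(n_treatments)) {
    tid <- paste0("T", t + 1)            # monitored sprayings are T2-T8
    u_date <- stats::rnorm(1, 0, cm$sd_date)
    lines <- paste0("L", 1:3)
    u_line <- stats::setNames(stats::rnorm(3, 0, cm$sd_line), lines)
    add <- function(line_id, role, dist, u, eta) {
      perm <- if (role == "control") 0
              else cm$perm0 * exp(-cm$perm_k * dist) *
                   stats::rlnorm(1, 0, cm$perm_sdlog)
      p <- stats::plogis(eta)
      for (sex in SEX_LEVELS) {
        dead <- stats::rbinom(1, cm$n_initial, p)
        rows[[length(rows) + 1]] <<- data.frame(
          treatment_id = tid, line_id = line_id, role = role,
          distance_m = dist, sex = sex, n_initial = cm$n_initial,
          n_dead_24h = dead, permethrin_ug_cm2 = perm,
          stringsAsFactors = FALSE)
      }
    }
    for (ln in lines) for (d in distances)
      add(ln, "exposed", d, u_line[ln],
          cm$beta0 + cm$beta_distance * d + u_date + u_line[ln])
    for (v in seq_along(validation_distances)) {
      dv <- validation_distances[v]
      u_v <- stats::rnorm(1, 0, cm$sd_line)
      add(names(validation_distances)[v], "validation", dv, u_v,
          cm$beta0 + cm$beta_distance * dv + u_date + u_v)
    }
    for (k in 1:3)
      add(paste0("control-", k), "control", NA_real_, 0,
          cm$beta0_control + u_date)
  }
  cage_records(do.call(rbind, rows))
}
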