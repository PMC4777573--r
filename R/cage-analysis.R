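#' Cage-experiment analyses
#'
#' Two binomial GLMMs of 24-h cage mortality — an exposure/dose model
#' over exposed and control cages, and a distance-decay model over
#' exposed cages only — plus simulation-based validation of the
#' distance model against sentinel validation cages and a distance-based
#' mortality surface for mapping expected kill over an area.
#'
#' @name cage-analysis
NULL

# Model frame shared by both cage GLMMs. Reference levels: control
# cages and females.
cage_model_frame <- function(cages) {
  df <- as.data.frame(cages)
  df$exposed <- factor(ifelse(df$role == "exposed", "exposed", "control"),
                       levels = c("control", "exposed"))
  df$sex <- factor(df$sex, levels = SEX_LEVELS)
  df$date <- factor(df$treatment_id)     # one spraying date per treatment
  df$line <- factor(df$line_id)
  df$permethrin <- df$permethrin_ug_cm2
  df
}

#' Exposure / permethrin / sex mortality model (exposed vs control cages)
#'
#' Binomial GLMM of deaths out of stocked mosquitoes per cage x sex.
#' Fixed: sex, permethrin dose, exposure, plus the sex x permethrin and
#' sex x exposure interactions (the exposure x permethrin interaction is
#' near-collinear because permethrin is identically zero in controls and
#' is not fitted). Random intercepts: treatment date, and line within
#' date. Reference levels: females in control cages.
#'
#' @param cages a `cage_records` data frame (validation cages excluded
#'   automatically).
#' @return a `mixed_fit`.
#' @export
run_glmm1 <- function(cages) {
  df <- cage_model_frame(cages)
  df <- df[df$role != "validation", ]
  spec <- model_spec("binomial", response = "n_dead_24h", trials = "n_initial",
                     fixed = c("sex", "permethrin", "exposed",
                               "sex:permethrin", "sex:exposed"),
                     random = "date/line")
  fit_glmm(spec, df)
}

#' Distance-decay mortality model (exposed cages only)
#'
#' Binomial GLMM of cage mortality on distance (m) from the spraying
#' itinerary, random intercepts for treatment date and line within date.
#'
#' @param exposed_cages a `cage_records` data frame; rows with role
#'   `"exposed"` are used.
#' @return a `mixed_fit`; the `distance_m` coefficient is the logit
#'   decay per metre.
#' @export
run_glmm2 <- function(exposed_cages) {
  df <- cage_model_frame(exposed_cages)
  df <- df[df$role == "exposed", ]
  if (!nrow(df)) stop_data("no exposed cages")
  spec <- model_spec("binomial", response = "n_dead_24h", trials = "n_initial",
                     fixed = "distance_m", random = "date/line")
  fit_glmm(spec, df)
}

# Two-sided rejection bounds of a simulated count distribution at level
# alpha: lower = largest x with P(X <= x) <= alpha/2, upper = smallest x
# with P(X >= x) <= alpha/2. Values at or beyond the bounds fall in a
# tail of probability <= alpha/2.
rejection_bounds <- function(draws, n, alpha = 0.05) {
  cdf <- stats::ecdf(draws)
  xs <- 0:n
  lo_ok <- xs[cdf(xs) <= alpha / 2]
  up_tail <- 1 - cdf(xs - 1)            # P(X >= x)
  hi_ok <- xs[up_tail <= alpha / 2]
  c(lower = if (length(lo_ok)) max(lo_ok) else -1L,
    upper = if (length(hi_ok)) min(hi_ok) else n + 1L)
}

#' Simulation-based validation of the distance model
#'
#' For each treatment x validation cage (sexes pooled), predicts
#' mortality from the fixed part of the distance model at the cage's
#' distance, simulates `n_sim` binomial death counts at that
#' probability, and flags the observed count as `under` / `within` /
#' `over` the central 95% of the simulated distribution (two-sided
#' rejection bounds at 0.025 / 0.975).
#'
#' @param fit2 the distance-model `mixed_fit` from [run_glmm2()].
#' @param validation_cages `cage_records` rows with role `"validation"`
#'   (other roles are ignored).
#' @param n_sim simulated samples per cage (default 10000; below 1000 a
#'   quantile-instability warning is issued).
#' @param seed integer seed for the simulation.
#' @return data frame: treatment, cage, n_initial, observed deaths,
#'   predicted mortality, bounds `q0.025`/`q0.975` and `flag`.
#' @export
validate_cages <- function(fit2, validation_cages, n_sim = 10000, seed = 1) {
  if (!fit2$converged) stop_data("distance model did not converge")
  if (n_sim < 1000)
    warning("n_sim < 1000: empirical quantiles unstable", call. = FALSE)
  df <- as.data.frame(validation_cages)
  df <- df[df$role == "validation", ]
  if (!nrow(df)) stop_data("no validation cages supplied")
  # pool sexes: cage-level totals per treatment x cage
  agg <- stats::aggregate(cbind(n_initial, n_dead_24h) ~ treatment_id + line_id + distance_m,
                          data = df, FUN = sum)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  res <- lapply(seq_len(nrow(agg)), function(i) {
    p <- predict_response(fit2, data.frame(distance_m = agg$distance_m[i]))
    draws <- stats::rbinom(n_sim, agg$n_initial[i], p)
    b <- rejection_bounds(draws, agg$n_initial[i])
    obs <- agg$n_dead_24h[i]
    flag <- if (obs <= b["lower"]) "under" else if (obs >= b["upper"]) "over" else "within"
    data.frame(treatment_id = agg$treatment_id[i], cage_id = agg$line_id[i],
               n_initial = agg$n_initial[i], observed_dead = obs,
               predicted_p = unname(p),
               q0.025 = b[["lower"]], q0.975 = b[["upper"]],
               flag = flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Expected-mortality surface over a distance grid
#'
#' Applies the fixed part of the distance model to a user-supplied grid
#' of distances (m) to the spraying itinerary, with an optional logical
#' mask (TRUE = cell counts, e.g. not occupied by buildings), and
#' reports the fraction of unmasked area with predicted mortality above
#' each threshold.
#'
#' @param fit2 the `mixed_fit` from [run_glmm2()].
#' @param distance_grid numeric matrix of distances (m).
#' @param mask logical matrix, same shape; `NULL` = all cells.
#' @param thresholds mortality thresholds.
#' @return list of class `mortality_surface`: `predicted` (matrix),
#'   `mask`, `fractions` (named, non-increasing in threshold).
#' @export
mortality_surface <- function(fit2, distance_grid, mask = NULL,
                              thresholds = c(0.5, 0.75)) {
  if (is.null(mask)) mask <- array(TRUE, dim(distance_grid))
  if (!any(mask)) stop_data("mask excludes every cell")
  stopifnot(all(dim(mask) == dim(distance_grid)))
  p <- predict_response(fit2, data.frame(distance_m = as.vector(distance_grid)))
  pred <- matrix(p, nrow(distance_grid))
  thresholds <- sort(thresholds)
  fr <- vapply(thresholds, function(th) mean(pred[mask] > th), 0)
  structure(list(predicted = pred, mask = mask,
                 fractions = stats::setNames(fr, format(thresholds))),
            class = "mortality_surface")
}
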