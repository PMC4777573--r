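#' Henderson-Tilton effectiveness
#'
#' Single-treatment effectiveness corrected by a contemporaneous
#' untreated control:
#'
#' \deqn{\%E = 100 (1 - \frac{T_{after} \cdot U_{before}}{T_{before} \cdot U_{after}})}
#'
#' Negative values (treated site declining less than the control) are
#' clamped to 0 for reporting; the unclamped value is retained in
#' `raw_pct` for diagnostics.
#'
#' @param treated_before,treated_after,untreated_before,untreated_after
#'   mean counts (>= 0); vectors recycle.
#' @param treatment_id,stratum optional labels carried into the result.
#' @return data frame of class `effectiveness_result` with columns
#'   `treatment_id`, `stratum`, the four means, `raw_pct`,
#'   `effectiveness_pct` and `defined` (FALSE when `treated_before` or
#'   `untreated_after` is 0, a division by zero).
#' @export
henderson <- function(treated_before, treated_after,
                      untreated_before, untreated_after,
                      treatment_id = NA_character_, stratum = NA_character_) {
  df <- data.frame(treatment_id = treatment_id, stratum = stratum,
                   treated_before = treated_before, treated_after = treated_after,
                   untreated_before = untreated_before,
                   untreated_after = untreated_after,
                   stringsAsFactors = FALSE)
  if (any(df[3:6] < 0, na.rm = TRUE)) stop_data("Henderson inputs must be >= 0")
  undef <- is.na(df$treated_before) | is.na(df$untreated_after) |
    df$treated_before == 0 | df$untreated_after == 0
  df$raw_pct <- ifelse(undef, NA_real_,
                       100 * (1 - (df$treated_after * df$untreated_before) /
                                (df$treated_before * df$untreated_after)))
  df$effectiveness_pct <- pmax(df$raw_pct, 0)
  df$defined <- !undef
  if (any(undef))
    warning("Henderson effectiveness undefined for ", sum(undef),
            " stratum/treatment combination(s) (zero denominator)", call. = FALSE)
  class(df) <- c("effectiveness_result", "data.frame")
  df
}

# Cage-level totals pooled over sexes: alive before = initial stock,
# alive after = initial - dead at 24 h. Cages are closed systems, so the
# "before" count is the stocked number.
cage_alive_means <- function(cages) {
  agg <- stats::aggregate(cbind(n_initial, n_dead_24h) ~ treatment_id + line_id + role + distance_m,
                          data = transform(as.data.frame(cages),
                                           distance_m = ifelse(is.na(distance_m), -1, distance_m)),
                          FUN = sum)
  agg$alive_before <- agg$n_initial
  agg$alive_after <- agg$n_initial - agg$n_dead_24h
  agg$distance_m[agg$distance_m < 0] <- NA
  agg
}

#' Caged-mosquito effectiveness by distance band or per treatment
#'
#' Applies the Henderson formula per treatment x distance stratum with
#' control cages as the untreated arm, then either averages each distance
#' across treatments (`by = "distance"`, with a 95% t-interval over the
#' per-treatment values) or averages the 10/30/50 m strata within each
#' treatment (`by = "treatment_leq50m"`, dropping the low-mortality 70 m
#' cages).
#'
#' @param cages a `cage_records` data frame.
#' @param by `"distance"` or `"treatment_leq50m"`.
#' @param conf_level confidence level of the t-interval.
#' @return data frame with one row per distance (plus mean and CI) or per
#'   treatment.
#' @export
caged_effectiveness <- function(cages, by = c("distance", "treatment_leq50m"),
                                conf_level = 0.95) {
  by <- match.arg(by)
  cg <- cage_alive_means(cages)
  treatments <- sort(unique(cg$treatment_id))
  per <- list()
  for (tid in treatments) {
    sub <- cg[cg$treatment_id == tid, ]
    ctrl <- sub[sub$role == "control", ]
    if (!nrow(ctrl)) {
      warning("treatment ", tid, " has no control cages; skipped", call. = FALSE)
      next
    }
    ub <- mean(ctrl$alive_before); ua <- mean(ctrl$alive_after)
    exp_ <- sub[sub$role == "exposed", ]
    for (d in sort(unique(exp_$distance_m))) {
      sd_ <- exp_[exp_$distance_m == d, ]
      h <- suppressWarnings(
        henderson(mean(sd_$alive_before), mean(sd_$alive_after), ub, ua,
                  treatment_id = tid, stratum = as.character(d)))
      per[[length(per) + 1]] <- h
    }
  }
  per <- do.call(rbind, per)
  if (by == "treatment_leq50m") {
    keep <- per[as.numeric(per$stratum) <= 50, ]
    out <- stats::aggregate(effectiveness_pct ~ treatment_id, data = keep, FUN = mean)
    names(out)[2] <- "effectiveness_pct"
    return(out)
  }
  dists <- sort(unique(as.numeric(per$stratum)))
  out <- do.call(rbind, lapply(dists, function(d) {
    v <- per$effectiveness_pct[as.numeric(per$stratum) == d & per$defined]
    n <- length(v)
    half <- if (n > 1) stats::qt(1 - (1 - conf_level) / 2, n - 1) * stats::sd(v) / sqrt(n) else NA_real_
    data.frame(distance_m = d, effectiveness_pct = mean(v),
               ci_lower = mean(v) - half, ci_upper = mean(v) + half,
               n_treatments = n)
  }))
  attr(out, "per_treatment") <- per
  out
}

#' Field effectiveness of one spraying from sticky-trap collections
#'
#' `before`/`after` are the mean adult counts over active traps of each
#' site at the collections flanking the treatment (72 h before and
#' after), and the Henderson formula is applied to the four means.
#'
#' @param traps a `trap_records` data frame.
#' @param schedule a [treatment_schedule()].
#' @param treatment_id which treatment to assess.
#' @return an `effectiveness_result` row with attributes
#'   `n_active_traps` (site x pre/post counts of contributing traps).
#' @export
field_effectiveness <- function(traps, schedule, treatment_id) {
  row <- schedule[schedule$treatment_id == treatment_id, ]
  if (!nrow(row)) stop_data("unknown treatment_id: ", treatment_id)
  sm <- site_mean_series(traps, "count")
  pick <- function(site, idx) sm[sm$site == site & sm$collection_index == idx, ]
  cells <- list(tb = pick("treated", row$pre_collection_index),
                ta = pick("treated", row$post_collection_index),
                ub = pick("untreated", row$pre_collection_index),
                ua = pick("untreated", row$post_collection_index))
  if (any(vapply(cells, nrow, 0L) == 0) || any(vapply(cells, function(x) is.na(x$mean), TRUE))) {
    warning("missing pre or post collection for ", treatment_id,
            "; effectiveness undefined", call. = FALSE)
    res <- suppressWarnings(henderson(NA, NA, NA, NA, treatment_id, "field"))
  } else {
    res <- suppressWarnings(
      henderson(cells$tb$mean, cells$ta$mean, cells$ub$mean, cells$ua$mean,
                treatment_id, "field"))
  }
  attr(res, "n_active_traps") <- vapply(cells, function(x) if (nrow(x)) x$n_traps else 0L, 0L)
  res
}
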