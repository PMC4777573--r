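#' Treatment-induced divergence between site series
#'
#' The headline procedure: the treated and untreated per-collection mean
#' series are each pre-whitened with an ARIMA model (so shared trends and
#' autocorrelation cannot inflate their association), their residuals are
#' Pearson-correlated over expanding windows (shortest window = the first
#' `min_len` collections, then one collection added at a time), and the
#' resulting correlation sequence is segmented for abrupt mean shifts. A
#' drop in the mosquito-series correlation with no concurrent drop in the
#' water-leftover correlation is the signature of a treatment effect
#' rather than of diverging eco-climatic conditions.
#'
#' @name divergence
NULL

arima_aicc <- function(fit, n) {
  k <- length(fit$coef) + 1  # + innovation variance
  stats::AIC(fit) + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Pre-whiten a series with an ARIMA model
#'
#' If `order` is omitted, the differencing order d is chosen first by a
#' Phillips-Perron unit-root test (d = 1 when a unit root cannot be
#' rejected at the 5% level, up to `d_max`) — information criteria are
#' not comparable across differencing levels — and p, q are then
#' searched over `0..p_max` x `0..q_max` by corrected AIC among
#' converging fits; the residuals (innovations) are returned. Candidates
#' that fail to converge are skipped; if every candidate fails the
#' series is demeaned (order (0,0,0)) with a warning. A constant series
#' is flagged degenerate and returns zero residuals.
#'
#' @param series numeric vector, length >= 10 recommended, no NAs.
#' @param order optional fixed `c(p, d, q)`.
#' @param p_max,d_max,q_max search bounds when `order` is omitted.
#' @return list of class `residual_series`: `values` (residuals, same
#'   length as input), `order`, `aicc`, `degenerate`.
#' @export
prewhiten <- function(series, order = NULL, p_max = 3, d_max = 1, q_max = 3) {
  x <- as.numeric(series)
  if (anyNA(x)) stop_data("series contains missing values; impute or trim first")
  n <- length(x)
  if (stats::sd(x) == 0) {
    warning("constant series: residuals are all zero", call. = FALSE)
    return(structure(list(values = rep(0, n), order = c(0L, 0L, 0L),
                          aicc = NA_real_, degenerate = TRUE),
                     class = "residual_series"))
  }
  fit_one <- function(ord) {
    f <- tryCatch(suppressWarnings(
      stats::arima(x, order = ord, include.mean = ord[2] == 0, method = "ML")),
      error = function(e) NULL)
    if (is.null(f)) return(NULL)
    list(fit = f, ord = ord, aicc = arima_aicc(f, n))
  }
  if (!is.null(order)) {
    res <- fit_one(as.integer(order))
    if (is.null(res)) {
      warning("requested ARIMA order failed; falling back to demeaned series",
              call. = FALSE)
      return(structure(list(values = x - mean(x), order = c(0L, 0L, 0L),
                            aicc = NA_real_, degenerate = FALSE),
                       class = "residual_series"))
    }
  } else {
    d <- 0L
    if (d_max >= 1) {
      pp <- tryCatch(stats::PP.test(stats::ts(x))$p.value, error = function(e) 0)
      if (!is.na(pp) && pp > 0.05) d <- 1L
    }
    grid <- expand.grid(p = 0:p_max, d = d, q = 0:q_max)
    fits <- lapply(seq_len(nrow(grid)), function(i)
      fit_one(c(grid$p[i], grid$d[i], grid$q[i])))
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) {
      warning("no ARIMA candidate converged; falling back to demeaned series",
              call. = FALSE)
      return(structure(list(values = x - mean(x), order = c(0L, 0L, 0L),
                            aicc = NA_real_, degenerate = FALSE),
                       class = "residual_series"))
    }
    res <- fits[[which.min(vapply(fits, `[[`, 0, "aicc"))]]
  }
  structure(list(values = as.numeric(stats::residuals(res$fit)),
                 order = as.integer(res$ord), aicc = res$aicc,
                 degenerate = FALSE),
            class = "residual_series")
}

cor_with_p <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(c(r = NA_real_, p = NA_real_, n = length(a)))
  n <- length(a)
  r <- stats::cor(a, b)
  tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-12))
  c(r = r, p = 2 * stats::pt(-abs(tt), n - 2), n = n)
}

#' Expanding-window correlations of pre-whitened site series
#'
#' For each window `[1..k]`, `k = min_len..length`, both series are
#' pre-whitened (independently, refit on every window by default; set
#' `mode = "global"` to fit once on the full series and correlate
#' sub-windows of those residuals) and their residuals are
#' Pearson-correlated, with a two-sided t-test p-value on n - 2 df.
#'
#' @param series_a,series_b aligned per-collection mean vectors of equal
#'   length (>= `min_len`), no NAs.
#' @param min_len shortest window (default 10 collections).
#' @param mode `"window"` (refit per window) or `"global"`.
#' @param ... passed to [prewhiten()] (e.g. `p_max`, `order`).
#' @return data frame of class `correlation_series`: `window_end`, `r`,
#'   `p`, `n`. Zero-variance residual windows give `NA` r (flagged by a
#'   warning).
#' @export
expanding_correlations <- function(series_a, series_b, min_len = 10,
                                   mode = c("window", "global"), ...) {
  mode <- match.arg(mode)
  a <- as.numeric(series_a); b <- as.numeric(series_b)
  if (length(a) != length(b)) stop_data("series must be aligned (equal length)")
  if (anyNA(a) || anyNA(b)) stop_data("series contain missing values")
  C <- length(a)
  if (C < min_len) stop_data("series shorter than min_len")
  ends <- min_len:C
  if (mode == "global") {
    ra <- prewhiten(a, ...)$values
    rb <- prewhiten(b, ...)$values
    stats_mat <- t(vapply(ends, function(k) cor_with_p(ra[1:k], rb[1:k]),
                          c(r = 0, p = 0, n = 0)))
  } else {
    stats_mat <- t(vapply(ends, function(k) {
      ra <- suppressWarnings(prewhiten(a[1:k], ...))$values
      rb <- suppressWarnings(prewhiten(b[1:k], ...))$values
      cor_with_p(ra, rb)
    }, c(r = 0, p = 0, n = 0)))
  }
  out <- data.frame(window_end = ends, r = stats_mat[, "r"],
                    p = stats_mat[, "p"], n = as.integer(stats_mat[, "n"]))
  if (anyNA(out$r))
    warning("zero-variance residuals in ", sum(is.na(out$r)), " window(s)",
            call. = FALSE)
  class(out) <- c("correlation_series", "data.frame")
  out
}

#' Full divergence analysis of a monitoring season
#'
#' Runs the pre-whitening / expanding-correlation / change-point chain
#' for both the mosquito mean-count series and the water-leftover series
#' of the two sites, maps break positions back to collection indices,
#' and flags whether the mosquito divergence precedes (or coincides
#' with) any water divergence — the condition for attributing it to
#' treatment rather than climate.
#'
#' @param traps a `trap_records` data frame covering both sites.
#' @param schedule optional [treatment_schedule()] used to annotate
#'   which treatment immediately precedes the mosquito break.
#' @param min_len shortest correlation window.
#' @param ... passed to [expanding_correlations()].
#' @return list of class `divergence_report`: per variable the
#'   correlation series and `changepoint_result` plus
#'   `break_collections` (collection index at which each new regime
#'   starts), and `attribution` flags.
#' @export
divergence_report <- function(traps, schedule = NULL, min_len = 10, ...) {
  run_var <- function(variable) {
    sm <- site_mean_series(traps, variable)
    C <- max(sm$collection_index)
    tr <- site_series_vector(sm, "treated", C)
    un <- site_series_vector(sm, "untreated", C)
    if (anyNA(tr) || anyNA(un))
      stop_data("site mean series for '", variable, "' has missing collections")
    corr <- expanding_correlations(tr, un, min_len = min_len, ...)
    cp <- detect_changepoints(corr$r)
    break_collections <- if (length(cp$breaks))
      corr$window_end[pmin(cp$breaks + 1, nrow(corr))] else integer(0)
    list(correlations = corr, changepoints = cp,
         break_collections = break_collections)
  }
  mosq <- run_var("count")
  water <- run_var("water")
  first_or_inf <- function(x) if (length(x)) min(x) else Inf
  mb <- first_or_inf(mosq$break_collections)
  wb <- first_or_inf(water$break_collections)
  attribution <- list(
    mosquito_break = if (is.finite(mb)) mb else NA_integer_,
    water_break = if (is.finite(wb)) wb else NA_integer_,
    mosquito_precedes_water = is.finite(mb) && mb <= wb)
  if (!is.null(schedule) && is.finite(mb)) {
    prior <- schedule[schedule$post_collection_index <= mb, ]
    attribution$treatment_before_break <-
      if (nrow(prior)) prior$treatment_id[nrow(prior)] else NA_character_
  }
  structure(list(mosquito = mosq, water = water, attribution = attribution),
            class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  cat("Divergence analysis (expanding-window residual correlations)\n")
  for (v in c("mosquito", "water")) {
    cp <- x[[v]]$changepoints
    cat(sprintf("- %s: %d break(s)%s; segment means: %s\n", v,
                length(cp$breaks),
                if (length(x[[v]]$break_collections))
                  paste0(" at collection ", paste(x[[v]]$break_collections, collapse = ", "))
                else "",
                paste(round(cp$segment_means, 2), collapse = " -> ")))
  }
  cat("Mosquito break precedes/coincides with water break:",
      x$attribution$mosquito_precedes_water, "\n")
  invisible(x)
}
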