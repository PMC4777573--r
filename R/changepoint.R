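#' Change-point segmentation of a series' mean
#'
#' Exact dynamic-programming segmentation into piecewise-constant means:
#' for each candidate number of breaks m = 0..max_breaks the within-
#' segment sum of squares is minimised exactly (all segmentations
#' respecting the minimum segment length are considered), and m is then
#' chosen by BIC. This is the classical least-squares structural-break
#' estimator for a mean-shift model.
#'
#' @name changepoint
NULL

# Segment SSE in O(1) from prefix sums; seg_sse(i, j) covers x[i..j].
make_sse <- function(x) {
  s1 <- cumsum(c(0, x)); s2 <- cumsum(c(0, x^2))
  function(i, j) {
    n <- j - i + 1
    s2[j + 1] - s2[i] - (s1[j + 1] - s1[i])^2 / n
  }
}

# Exact DP: best[m+1, j] = minimal SSE of x[1..j] split into m+1 segments
# each of length >= h. Returns per-m optimum with break positions
# (last index of each non-final segment).
dp_segment <- function(x, max_breaks, h) {
  n <- length(x)
  sse <- make_sse(x)
  # cost[i, j] for segments [i..j] with j - i + 1 >= h
  best <- matrix(Inf, max_breaks + 1, n)     # best[m+1, j]
  argm <- matrix(NA_integer_, max_breaks + 1, n)
  for (j in h:n) best[1, j] <- sse(1, j)
  if (max_breaks > 0) {
    for (m in 1:max_breaks) {
      for (j in seq.int((m + 1) * h, n)) {
        cand_i <- seq.int(m * h, j - h)      # last index of previous part
        vals <- best[m, cand_i] + vapply(cand_i, function(i) sse(i + 1, j), 0)
        k <- which.min(vals)
        best[m + 1, j] <- vals[k]
        argm[m + 1, j] <- cand_i[k]
      }
    }
  }
  lapply(0:max_breaks, function(m) {
    if (!is.finite(best[m + 1, n])) return(NULL)
    breaks <- integer(0); j <- n
    if (m > 0) for (mm in m:1) {
      j <- argm[mm + 1, j]
      breaks <- c(j, breaks)
    }
    list(m = m, rss = best[m + 1, n], breaks = breaks)
  })
}

#' Detect mean shifts in a series
#'
#' @param x numeric vector (e.g. an expanding-window correlation
#'   sequence); no missing values.
#' @param min_segment_frac minimum segment length as a fraction of
#'   `length(x)` (default 0.15, the usual trimming of least-squares
#'   break estimators).
#' @param max_breaks maximum number of breaks considered.
#' @return list of class `changepoint_result`: `breaks` (last index of
#'   each segment but the final one; empty when no shift), `segment_means`,
#'   `segments` (start/end/mean data frame) and `criterion` (RSS and BIC
#'   per candidate break count).
#' @export
detect_changepoints <- function(x, min_segment_frac = 0.15, max_breaks = 3) {
  x <- as.numeric(x)
  if (anyNA(x)) stop_data("series contains missing values")
  n <- length(x)
  h <- max(2L, as.integer(ceiling(min_segment_frac * n)))
  if (n < 2 * h) stop_data("series too short for segmentation (need >= ", 2 * h, " points)")
  max_breaks <- min(max_breaks, n %/% h - 1L)
  cand <- Filter(Negate(is.null), dp_segment(x, max_breaks, h))
  # BIC for the mean-shift model: m+1 means, m break dates, 1 variance.
  crit <- do.call(rbind, lapply(cand, function(cc) {
    df <- 2 * cc$m + 2
    data.frame(n_breaks = cc$m, rss = cc$rss,
               bic = n * log(max(cc$rss, 1e-12) / n) + df * log(n))
  }))
  pick <- cand[[which.min(crit$bic)]]
  bounds <- c(0, pick$breaks, n)
  segs <- data.frame(start = head(bounds, -1) + 1, end = bounds[-1])
  segs$mean <- vapply(seq_len(nrow(segs)),
                      function(i) mean(x[segs$start[i]:segs$end[i]]), 0)
  structure(list(breaks = pick$breaks, segment_means = segs$mean,
                 segments = segs, criterion = crit),
            class = "changepoint_result")
}

#' @export
print.changepoint_result <- function(x, ...) {
  if (!length(x$breaks)) cat("No mean shift detected.\n")
  else cat("Breaks after position(s):", paste(x$breaks, collapse = ", "), "\n")
  print(transform(x$segments, mean = round(mean, 3)))
  invisible(x)
}
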