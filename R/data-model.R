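#' Canonical data types and tabular I/O
#'
#' The pipeline works on three tabular record types, all held as plain
#' data frames with a class tag:
#'
#' * `trap_records` — one sticky trap x collection observation (adult
#'   counts by sex, water leftover in decilitres, active flag);
#' * `cage_records` — one cage x sex observation from a spraying
#'   experiment (initial and dead mosquitoes, distance to the spraying
#'   itinerary, permethrin dose);
#' * `treatment_schedule` — the spraying calendar, each treatment anchored
#'   to the sticky-trap collection immediately before (pre) and after
#'   (post) it.
#'
#' Readers accept delimited text with a configurable column mapping so
#' that field spreadsheets with different headers can be ingested without
#' editing the files.
#'
#' @name data-model
NULL

SITE_LEVELS <- c("untreated", "treated")
ROLE_LEVELS <- c("exposed", "validation", "control")
SEX_LEVELS <- c("female", "male")

stop_data <- function(...) stop(..., call. = FALSE)

#' Validate and tag a data frame of sticky-trap observations
#'
#' Required columns: `trap_id`, `site` ("treated"/"untreated"),
#' `collection_index` (1..C), `collection_date` (Date or parseable),
#' `n_female`, `n_male`, `n_total`, `water_leftover` (decilitres),
#' `active` (logical). `n_total` must equal `n_female + n_male` wherever
#' both sexes are recorded; counts must be non-negative integers;
#' `(trap_id, collection_index)` pairs must be unique and indices must
#' increase with date within a trap.
#'
#' @param df data frame with the columns above.
#' @return the validated data frame with class `trap_records`.
#' @export
trap_records <- function(df) {
  req <- c("trap_id", "site", "collection_index", "collection_date",
           "n_female", "n_male", "n_total", "water_leftover", "active")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_data("trap table is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[req]
  df$trap_id <- as.character(df$trap_id)
  if (!all(df$site %in% SITE_LEVELS))
    stop_data("site must be one of: ", paste(SITE_LEVELS, collapse = ", "))
  df$site <- factor(df$site, levels = SITE_LEVELS)
  df$collection_index <- as.integer(df$collection_index)
  df$collection_date <- as.Date(df$collection_date)
  df$active <- as.logical(df$active)
  for (cn in c("n_female", "n_male", "n_total")) {
    v <- df[[cn]]
    if (any(!is.na(v) & (v < 0 | v != floor(v))))
      stop_data(cn, " must contain non-negative integers")
    df[[cn]] <- as.integer(v)
  }
  if (any(!is.na(df$water_leftover) & df$water_leftover < 0))
    stop_data("water_leftover must be >= 0")
  both <- !is.na(df$n_female) & !is.na(df$n_male) & !is.na(df$n_total)
  bad <- both & (df$n_total != df$n_female + df$n_male)
  if (any(bad))
    stop_data("n_total != n_female + n_male in ", sum(bad), " row(s), e.g. trap ",
              df$trap_id[which(bad)[1]], " collection ",
              df$collection_index[which(bad)[1]])
  key <- paste(df$trap_id, df$collection_index)
  if (anyDuplicated(key))
    stop_data("duplicate (trap_id, collection_index): ", key[anyDuplicated(key)])
  # collection_index must be monotone in date within each trap
  for (tid in unique(df$trap_id)) {
    sub <- df[df$trap_id == tid, ]
    o <- order(sub$collection_index)
    if (is.unsorted(as.numeric(sub$collection_date[o]), strictly = FALSE))
      stop_data("collection_index not increasing with collection_date for trap ", tid)
  }
  class(df) <- c("trap_records", "data.frame")
  df
}

#' Validate and tag a data frame of cage observations
#'
#' One row per cage x sex. Required columns: `treatment_id`, `line_id`,
#' `role` ("exposed"/"validation"/"control"), `distance_m` (NA allowed
#' for controls), `sex`, `n_initial` (> 0), `n_dead_24h`
#' (0..`n_initial`), `permethrin_ug_cm2` (>= 0; forced to 0 in controls,
#' matching a below-detection-threshold coding).
#'
#' @param df data frame with the columns above.
#' @return the validated data frame with class `cage_records`.
#' @export
cage_records <- function(df) {
  req <- c("treatment_id", "line_id", "role", "distance_m", "sex",
           "n_initial", "n_dead_24h", "permethrin_ug_cm2")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_data("cage table is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[req]
  df$treatment_id <- as.character(df$treatment_id)
  df$line_id <- as.character(df$line_id)
  if (!all(df$role %in% ROLE_LEVELS))
    stop_data("role must be one of: ", paste(ROLE_LEVELS, collapse = ", "))
  df$role <- factor(df$role, levels = ROLE_LEVELS)
  if (!all(df$sex %in% SEX_LEVELS))
    stop_data("sex must be one of: ", paste(SEX_LEVELS, collapse = ", "))
  df$sex <- factor(df$sex, levels = SEX_LEVELS)
  df$n_initial <- as.integer(df$n_initial)
  df$n_dead_24h <- as.integer(df$n_dead_24h)
  if (any(df$n_initial <= 0)) stop_data("n_initial must be positive")
  bad <- df$n_dead_24h < 0 | df$n_dead_24h > df$n_initial
  if (any(bad))
    stop_data("n_dead_24h outside [0, n_initial] in ", sum(bad), " row(s)")
  ctrl <- df$role == "control"
  df$permethrin_ug_cm2[ctrl] <- 0
  if (any(!is.na(df$permethrin_ug_cm2) & df$permethrin_ug_cm2 < 0))
    stop_data("permethrin_ug_cm2 must be >= 0")
  if (any(!ctrl & is.na(df$distance_m)))
    stop_data("distance_m required for exposed and validation cages")
  if (any(!is.na(df$distance_m) & df$distance_m < 0))
    stop_data("distance_m must be >= 0")
  class(df) <- c("cage_records", "data.frame")
  df
}

#' Default column mappings mirroring the field spreadsheet layouts
#'
#' A mapping is a named character vector `canonical = file_header`.
#' @export
trap_column_defaults <- function() {
  c(trap_id = "trap_id", site = "site", collection_index = "collection_index",
    collection_date = "collection_date", n_female = "n_female",
    n_male = "n_male", n_total = "n_total", water_leftover = "water_leftover",
    active = "active")
}

#' @rdname trap_column_defaults
#' @export
cage_column_defaults <- function() {
  c(treatment_id = "treatment_id", line_id = "line_id", role = "role",
    distance_m = "distance_m", sex = "sex", n_initial = "n_initial",
    n_dead_24h = "n_dead_24h", permethrin_ug_cm2 = "permethrin_ug_cm2")
}

read_mapped_table <- function(path, mapping, what) {
  if (!file.exists(path)) stop_data(what, " file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- mapping[!mapping %in% names(raw)]
  if (length(missing_cols))
    stop_data(what, " file ", path, " lacks mapped column(s): ",
              paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(raw), mapping)
  if (length(extra))
    stop_data(what, " file ", path, " has unrecognised column(s): ",
              paste(extra, collapse = ", "),
              " (adjust the column mapping if these are renamed fields)")
  out <- raw[, unname(mapping), drop = FALSE]
  names(out) <- names(mapping)
  out
}

#' Read a sticky-trap table from CSV
#'
#' @param path CSV file, one row per trap x collection.
#' @param mapping named character vector mapping canonical column names to
#'   the file's headers; see [trap_column_defaults()].
#' @return a `trap_records` data frame.
#' @export
read_trap_table <- function(path, mapping = trap_column_defaults()) {
  trap_records(read_mapped_table(path, mapping, "trap"))
}

#' Read a cage-experiment table from CSV
#'
#' @inheritParams read_trap_table
#' @return a `cage_records` data frame (one row per cage x sex).
#' @export
read_cage_table <- function(path, mapping = cage_column_defaults()) {
  cage_records(read_mapped_table(path, mapping, "cage"))
}

#' Write trap / cage tables back to CSV (round-trip safe)
#' @param records a `trap_records` or `cage_records` data frame.
#' @param path output CSV path.
#' @export
write_trap_table <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trap_table
#' @export
write_cage_table <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Construct a treatment schedule
#'
#' Each spraying is anchored to the last collection before it (`pre`) and
#' the first collection after it (`post`); with twice-weekly collections
#' and midnight spraying on day 7 of the trap week, pre is the day-6
#' collection and post the following week's day-3 collection.
#'
#' @param treatment_id character vector, e.g. `"T1".."T8"`.
#' @param date spraying dates (Date), strictly increasing.
#' @param pre_collection_index,post_collection_index integer anchors,
#'   `pre < post` row-wise.
#' @return data frame with class `treatment_schedule`.
#' @export
treatment_schedule <- function(treatment_id, date, pre_collection_index,
                               post_collection_index) {
  df <- data.frame(treatment_id = as.character(treatment_id),
                   date = as.Date(date),
                   pre_collection_index = as.integer(pre_collection_index),
                   post_collection_index = as.integer(post_collection_index),
                   stringsAsFactors = FALSE)
  if (any(df$pre_collection_index >= df$post_collection_index))
    stop_data("pre_collection_index must be < post_collection_index")
  if (is.unsorted(as.numeric(df$date), strictly = TRUE))
    stop_data("treatment dates must be strictly increasing")
  class(df) <- c("treatment_schedule", "data.frame")
  df
}

#' Twice-weekly collection calendar
#'
#' Collections alternate day-3 and day-6 of each trap week: dates run
#' start, start+3, start+7, start+10, ... Index 1 defaults to
#' 2013-06-17; with 36 collections the last lands on 2013-10-17.
#'
#' @param n_collections number of collections (default 36).
#' @param start date of collection 1.
#' @return Date vector of length `n_collections`.
#' @export
collection_dates <- function(n_collections = 36, start = as.Date("2013-06-17")) {
  w <- (seq_len(n_collections) - 1) %/% 2
  d3 <- (seq_len(n_collections) - 1) %% 2
  start + 7 * w + 3 * d3
}

#' Default eight-treatment spraying schedule
#'
#' Eight sprayings (T1-T8), June to October, each performed the night
#' after a day-6 collection; anchors are (pre, post) = (2w, 2w+1).
#' @param start date of collection 1.
#' @return a `treatment_schedule`.
#' @export
default_schedule <- function(start = as.Date("2013-06-17")) {
  pre <- c(2L, 6L, 14L, 18L, 22L, 26L, 30L, 34L)
  dates <- collection_dates(36, start)[pre] + 1  # sprayed the night after day-6
  treatment_schedule(paste0("T", 1:8), dates, pre, pre + 1L)
}

#' Per-site, per-collection mean series
#'
#' Averages either the total adult count or the water leftover over the
#' active traps of each site at each collection. Collections where a site
#' has no active trap yield `NA` (explicitly propagated, never dropped).
#'
#' @param records a `trap_records` data frame.
#' @param variable `"count"` (total adults) or `"water"` (leftover, dl).
#' @return data frame with columns `site`, `collection_index`, `mean`,
#'   `n_traps`, one row per site x collection, ordered by index; the
#'   result is invariant to the row order of `records`.
#' @export
site_mean_series <- function(records, variable = c("count", "water")) {
  variable <- match.arg(variable)
  records <- trap_records(as.data.frame(records))
  v <- if (variable == "count") records$n_total else records$water_leftover
  idx <- sort(unique(records$collection_index))
  out <- expand.grid(collection_index = idx, site = factor(SITE_LEVELS, SITE_LEVELS),
                     KEEP.OUT.ATTRS = FALSE)
  act <- records$active & !is.na(v)
  key <- interaction(records$collection_index, records$site, drop = FALSE)
  out$mean <- NA_real_
  out$n_traps <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- act & records$collection_index == out$collection_index[i] &
      records$site == out$site[i]
    out$n_traps[i] <- sum(sel)
    if (any(sel)) out$mean[i] <- mean(v[sel])
  }
  out[order(out$site, out$collection_index), c("site", "collection_index", "mean", "n_traps")]
}

#' Extract one site's mean series as a vector over collections 1..C
#'
#' @param series output of [site_mean_series()].
#' @param site `"treated"` or `"untreated"`.
#' @param n_collections length of the returned vector; indices absent
#'   from `series` are `NA`.
#' @export
site_series_vector <- function(series, site, n_collections = max(series$collection_index)) {
  out <- rep(NA_real_, n_collections)
  sub <- series[series$site == site, ]
  out[sub$collection_index] <- sub$mean
  out
}
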