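# Assembly of the modeling table: daily-maximum aggregation of intraday
# weather, the fixed 21-input / 4-target feature matrix, min-max
# normalisation to [-1, 1], and the random 70/30 row split.

#' Frozen input and target column orders of the feature matrix
#' @export
feature_input_cols <- c(
  "temp_c", "rh_pct", "rain_mm", "wind_kmh", "wind_dir_deg",
  "tdp_c", "twet_c", paste0("thi", 1:9),
  "programmed_feed_kg", "lactation_days", "lactation_number",
  "milking_freq", "liveweight_kg"
)

#' @rdname feature_input_cols
#' @export
feature_target_cols <- c("milk_yield_kg", "protein_pct", "fat_pct",
                         "feed_intake_kg")

#' Aggregate intraday weather records to one daily record per date
#'
#' Temperature, relative humidity and wind speed become daily maxima;
#' rainfall, recorded as a daily running total, becomes the final (i.e.
#' largest) value of the day; wind direction is the direction observed at
#' the maximum wind speed, with ties broken by the earliest record (a
#' daily "maximum" of compass degrees would be physically meaningless,
#' but `winddir_daily = "literal-max"` reproduces that literal reading).
#' Pressure, when present, is averaged.
#'
#' @param intraday data frame with a `timestamp` column (POSIXct or
#'   parseable text) plus the weather columns `temp_c`, `rh_pct`,
#'   `rain_mm`, `wind_kmh`, `wind_dir_deg` (optionally `pressure_kpa`).
#' @param winddir_daily `"at-max-speed"` (default) or `"literal-max"`.
#' @return one row per calendar day, ordered by `date`.
#' @export
aggregate_daily_max <- function(intraday,
                                winddir_daily = c("at-max-speed",
                                                  "literal-max")) {
  winddir_daily <- match.arg(winddir_daily)
  stopifnot(is.data.frame(intraday), "timestamp" %in% names(intraday))
  ts <- intraday$timestamp
  if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(ts, tz = "UTC")
  keep <- !is.na(ts)
  if (!all(keep)) {
    warning(sprintf("aggregate_daily_max: dropping %d records with unparseable timestamps",
                    sum(!keep)))
    intraday <- intraday[keep, , drop = FALSE]
    ts <- ts[keep]
  }
  day <- as.Date(ts)
  ord <- order(ts)
  intraday <- intraday[ord, , drop = FALSE]
  day <- day[ord]
  idx <- split(seq_len(nrow(intraday)), day)
  rows <- lapply(idx, function(i) {
    d <- intraday[i, , drop = FALSE]
    iw <- which(d$wind_kmh == max(d$wind_kmh))[1]  # earliest at max speed
    data.frame(
      temp_c = max(d$temp_c),
      rh_pct = max(d$rh_pct),
      rain_mm = max(d$rain_mm),
      wind_kmh = max(d$wind_kmh),
      wind_dir_deg = if (winddir_daily == "at-max-speed")
        d$wind_dir_deg[iw] else max(d$wind_dir_deg),
      pressure_kpa = if ("pressure_kpa" %in% names(d))
        mean(d$pressure_kpa) else 101.325
    )
  })
  out <- do.call(rbind, rows)
  out <- cbind(date = as.Date(names(idx)), out)
  rownames(out) <- NULL
  out
}

#' Assemble the 21-input / 4-target feature matrix
#'
#' Joins cow-day records to derived daily weather by date and lays the
#' inputs out in the frozen order of [feature_input_cols]: the five raw
#' weather maxima, dewpoint, wet-bulb, the nine THI variants, then the
#' five management inputs. Rows with any missing input (or, when targets
#' are present, any missing target) are dropped and counted. Rows with
#' zero milking frequency are retained: zero is a legitimate value of
#' both the input and the yield target.
#'
#' @param derived_daily daily weather already carrying `tdp_c`, `twet_c`
#'   and `thi1`..`thi9` (see [derive_weather()]).
#' @param cow_days cow-day records; target columns are optional (omit
#'   them to build a prediction-time matrix).
#' @return an object of class `feature_matrix`: a list with `inputs`
#'   (n x 21 matrix), `targets` (n x 4 matrix or `NULL`), `keys`
#'   (`cow_id`, `date`), `n_dropped`, and `signature` (the frozen column
#'   fingerprint that trained models verify before predicting).
#' @export
assemble_features <- function(derived_daily, cow_days) {
  need_w <- setdiff(c("date", feature_input_cols[1:16]), names(derived_daily))
  if (length(need_w)) {
    stop(sprintf("assemble_features: weather lacks column(s) %s (run derive_weather first?)",
                 paste(need_w, collapse = ", ")), call. = FALSE)
  }
  missing_dates <- setdiff(as.character(unique(cow_days$date)),
                           as.character(derived_daily$date))
  if (length(missing_dates)) {
    stop(sprintf("assemble_features: no weather for date(s) %s",
                 paste(utils::head(missing_dates, 5), collapse = ", ")),
         call. = FALSE)
  }
  wi <- match(as.character(cow_days$date), as.character(derived_daily$date))
  weather_part <- as.matrix(derived_daily[wi, feature_input_cols[1:16]])
  mgmt_cols <- feature_input_cols[17:21]
  need_m <- setdiff(mgmt_cols, names(cow_days))
  if (length(need_m)) {
    stop(sprintf("assemble_features: cow_days lacks column(s) %s",
                 paste(need_m, collapse = ", ")), call. = FALSE)
  }
  mgmt_part <- as.matrix(cow_days[, mgmt_cols])
  inputs <- cbind(weather_part, mgmt_part)
  colnames(inputs) <- feature_input_cols

  has_targets <- all(feature_target_cols %in% names(cow_days))
  targets <- if (has_targets)
    as.matrix(cow_days[, feature_target_cols]) else NULL

  complete <- stats::complete.cases(inputs)
  if (has_targets) complete <- complete & stats::complete.cases(targets)
  n_dropped <- sum(!complete)
  keys <- data.frame(cow_id = cow_days$cow_id[complete],
                     date = cow_days$date[complete])
  structure(list(
    inputs = inputs[complete, , drop = FALSE],
    targets = if (has_targets) targets[complete, , drop = FALSE] else NULL,
    keys = keys,
    n_dropped = n_dropped,
    signature = paste(c(feature_input_cols, feature_target_cols),
                      collapse = "|")
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d rows x %d inputs%s, %d dropped\n",
              nrow(x$inputs), ncol(x$inputs),
              if (is.null(x$targets)) "" else
                sprintf(" / %d targets", ncol(x$targets)),
              x$n_dropped))
  invisible(x)
}

#' Fit a column-wise min-max normalizer to [-1, 1]
#'
#' Each column is mapped by `x -> 2 * (x - min) / (max - min) - 1`, with
#' the minima and maxima taken over `rows` only (typically the training
#' rows, so that no test information leaks into the mapping). Values
#' outside the fitted range map outside `[-1, 1]` and are deliberately
#' not clipped.
#'
#' @param x numeric matrix.
#' @param rows integer row indices to fit on (default: all rows).
#' @return an object of class `minmax_normalizer`.
#' @export
fit_normalizer <- function(x, rows = NULL) {
  x <- as.matrix(x)
  if (is.null(rows)) rows <- seq_len(nrow(x))
  if (!length(rows)) stop("fit_normalizer: empty fitting set", call. = FALSE)
  mins <- apply(x[rows, , drop = FALSE], 2, min)
  maxs <- apply(x[rows, , drop = FALSE], 2, max)
  flat <- which(maxs <= mins)
  if (length(flat)) {
    stop(sprintf("fit_normalizer: constant column(s): %s",
                 paste(colnames(x)[flat], collapse = ", ")), call. = FALSE)
  }
  structure(list(min = mins, max = maxs, cols = colnames(x)),
            class = "minmax_normalizer")
}

#' @rdname fit_normalizer
#' @param norm a fitted `minmax_normalizer`.
#' @export
apply_normalizer <- function(norm, x) {
  x <- as.matrix(x)
  stopifnot(inherits(norm, "minmax_normalizer"), ncol(x) == length(norm$min))
  sweep(sweep(x, 2, norm$min), 2, norm$max - norm$min, "/") * 2 - 1
}

#' @rdname fit_normalizer
#' @export
invert_normalizer <- function(norm, x) {
  x <- as.matrix(x)
  stopifnot(inherits(norm, "minmax_normalizer"), ncol(x) == length(norm$min))
  sweep(sweep((x + 1) / 2, 2, norm$max - norm$min, "*"), 2, norm$min, "+")
}

#' Random train/test row split
#'
#' Rows (cow-days) are divided by a uniform random permutation;
#' `round(fraction * n)` rows train and the remainder test. The split is
#' at the row level, not the cow level: every cow-day is an independent
#' sample.
#'
#' @param n number of rows (>= 2).
#' @param fraction training fraction, strictly between 0 and 1
#'   (default 0.7).
#' @param seed integer RNG seed.
#' @return an object of class `split_index`: list with integer vectors
#'   `train` and `test`, plus `seed` and `fraction`.
#' @export
split_rows <- function(n, fraction = 0.7, seed = 1L) {
  stopifnot(n >= 2, fraction > 0, fraction < 1)
  n_train <- round(fraction * n)
  if (n_train < 1 || n_train >= n) {
    stop("split_rows: fraction produces an empty partition", call. = FALSE)
  }
  set.seed(seed)
  perm <- sample.int(n)
  structure(list(train = sort(perm[seq_len(n_train)]),
                 test = sort(perm[(n_train + 1):n]),
                 seed = seed, fraction = fraction),
            class = "split_index")
}

#' Normalize an assembled feature matrix and split its rows
#'
#' Convenience bundle used by the model-fitting front end: splits the
#' rows, fits input and target normalizers (on the training rows by
#' default; `normalize_on = "all"` reproduces the literal
#' whole-data-set reading at the cost of a mild leak) and returns the
#' normalized matrices together with everything needed to undo them.
#'
#' @param fm a `feature_matrix` with targets.
#' @param fraction,seed passed to [split_rows()].
#' @param normalize_on `"train"` or `"all"`.
#' @return list with `xn`, `tn` (normalized matrices), `norm_x`,
#'   `norm_t`, `split`, `signature`.
#' @export
prepare_dataset <- function(fm, fraction = 0.7, seed = 1L,
                            normalize_on = c("train", "all")) {
  normalize_on <- match.arg(normalize_on)
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$targets))
  split <- split_rows(nrow(fm$inputs), fraction, seed)
  fit_rows <- if (normalize_on == "train") split$train else
    seq_len(nrow(fm$inputs))
  norm_x <- fit_normalizer(fm$inputs, fit_rows)
  norm_t <- fit_normalizer(fm$targets, fit_rows)
  list(xn = apply_normalizer(norm_x, fm$inputs),
       tn = apply_normalizer(norm_t, fm$targets),
       norm_x = norm_x, norm_t = norm_t, split = split,
       signature = fm$signature)
}
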