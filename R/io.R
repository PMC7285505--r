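# Plain-CSV interfaces for the weather and cow-day record dialects, and
# the JSON sidecar that makes a normalization + split exactly
# reproducible.

#' Read and write the weather CSV dialect
#'
#' One row per day (or per timestamp, for intraday data destined for
#' [aggregate_daily_max()]); required columns `date` (ISO-8601; or
#' `timestamp` for intraday), `temp_c`, `rh_pct`, `rain_mm`, `wind_kmh`,
#' `wind_dir_deg`, optionally `pressure_kpa`. Derived outputs append
#' `tdp_c`, `twet_c`, `thi1`..`thi9`.
#'
#' @param path CSV file path.
#' @param weather a weather data frame.
#' @return `read_weather_csv` returns a data frame with `date` parsed
#'   as `Date`.
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temp_c", "rh_pct")
  if (!all(need %in% names(df)) ||
      !any(c("date", "timestamp") %in% names(df))) {
    stop("read_weather_csv: expected columns date (or timestamp), temp_c, rh_pct, ...",
         call. = FALSE)
  }
  if ("date" %in% names(df)) df$date <- as.Date(df$date)
  df
}

#' @rdname read_weather_csv
#' @export
write_weather_csv <- function(weather, path) {
  utils::write.csv(weather, path, row.names = FALSE)
  invisible(path)
}

#' Read and write the cow-day CSV dialect
#'
#' One row per cow per day: `cow_id`, `date`, the management inputs
#' (`programmed_feed_kg`, `lactation_days`, `lactation_number`,
#' `milking_freq`, `liveweight_kg`) and, for training data, the four
#' targets (`milk_yield_kg`, `protein_pct`, `fat_pct`,
#' `feed_intake_kg`). `latent_*` columns, when present (synthetic data
#' with `keep_latent`), round-trip unchanged.
#'
#' @param path CSV file path.
#' @param cow_days a cow-day data frame.
#' @param keep_latent drop the `latent_*` columns on write unless TRUE.
#' @export
read_cow_days_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cow_id", "date", "programmed_feed_kg", "lactation_days",
            "lactation_number", "milking_freq", "liveweight_kg")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("read_cow_days_csv: missing column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df$date <- as.Date(df$date)
  df
}

#' @rdname read_cow_days_csv
#' @export
write_cow_days_csv <- function(cow_days, path, keep_latent = FALSE) {
  if (!keep_latent) {
    cow_days <- cow_days[, !startsWith(names(cow_days), "latent_"),
                         drop = FALSE]
  }
  utils::write.csv(cow_days, path, row.names = FALSE)
  invisible(path)
}

#' Write a feature matrix as CSV with a JSON reproducibility sidecar
#'
#' The CSV holds `cow_id`, `date`, the 21 ordered input columns and the
#' 4 ordered target columns. The sidecar (`<path>.json`) records the
#' column signature and, when supplied, the fitted normalizer ranges and
#' the split (seed, fraction, row indices), which is everything needed
#' to reproduce a normalization and partition exactly.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV output path.
#' @param norm_x,norm_t optional fitted normalizers.
#' @param split optional `split_index`.
#' @export
write_feature_csv <- function(fm, path, norm_x = NULL, norm_t = NULL,
                              split = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- cbind(fm$keys, as.data.frame(fm$inputs))
  if (!is.null(fm$targets)) df <- cbind(df, as.data.frame(fm$targets))
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(signature = fm$signature, n_dropped = fm$n_dropped)
  if (!is.null(norm_x)) sidecar$norm_x <- unclass(norm_x)
  if (!is.null(norm_t)) sidecar$norm_t <- unclass(norm_t)
  if (!is.null(split)) sidecar$split <- unclass(split)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a feature-matrix CSV written by [write_feature_csv()]
#'
#' @param path CSV path (the `.json` sidecar is read when present).
#' @return a `feature_matrix`; the sidecar, if any, is attached as
#'   attribute `"sidecar"`.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(feature_input_cols, names(df))
  if (length(miss)) {
    stop(sprintf("read_feature_csv: missing input column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  has_targets <- all(feature_target_cols %in% names(df))
  fm <- structure(list(
    inputs = as.matrix(df[, feature_input_cols]),
    targets = if (has_targets) as.matrix(df[, feature_target_cols]) else NULL,
    keys = data.frame(cow_id = df$cow_id, date = as.Date(df$date)),
    n_dropped = 0L,
    signature = paste(c(feature_input_cols, feature_target_cols),
                      collapse = "|")
  ), class = "feature_matrix")
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    attr(fm, "sidecar") <- jsonlite::read_json(sidecar_path,
                                               simplifyVector = TRUE)
  }
  fm
}
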