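# Evaluation surface: pooled regression metrics per stage (training,
# testing, overall), prediction-interval outlier rates, and seasonal
# summaries of THI and the four production targets.

#' Pooled regression metrics between predictions and observations
#'
#' Predictions and observations for all four targets are pooled into one
#' pair of vectors (on the normalized scale, so targets with different
#' units are commensurable) and summarised by the Pearson correlation
#' `R`, the slope `b` of the least-squares fit `obs = b * pred + a`, and
#' the mean squared error.
#'
#' @param pred,obs numeric vectors or matrices of equal size (matrices
#'   are flattened, pooling across targets).
#' @return list with elements `r`, `b`, `mse`, `n`.
#' @export
regression_metrics <- function(pred, obs) {
  pred <- as.numeric(pred)
  obs <- as.numeric(obs)
  stopifnot(length(pred) == length(obs), length(pred) >= 2)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    stop("regression_metrics: zero variance in predictions or observations",
         call. = FALSE)
  }
  list(r = stats::cor(pred, obs),
       b = stats::cov(pred, obs) / stats::var(pred),
       mse = mean((obs - pred)^2),
       n = length(pred))
}

#' Observations outside the 95 percent bounds of the obs-on-pred fit
#'
#' Fits `obs = b * pred + a` by least squares and counts observations
#' outside the two-sided interval at the given level. The default
#' bounds are prediction intervals (which scale with the residual
#' standard deviation and therefore yield per-observation outlier
#' counts); `bounds = "confidence"` gives the much narrower
#' mean-response intervals instead.
#'
#' @param pred,obs numeric vectors (matrices are pooled).
#' @param level two-sided coverage level, default 0.95.
#' @param bounds `"prediction"` (default) or `"confidence"`.
#' @return list with `count`, `percent` (= 100 * count / n), `n`.
#' @export
outlier_fraction <- function(pred, obs, level = 0.95,
                             bounds = c("prediction", "confidence")) {
  bounds <- match.arg(bounds)
  pred <- as.numeric(pred)
  obs <- as.numeric(obs)
  n <- length(pred)
  stopifnot(n == length(obs), n >= 3, level > 0, level < 1)
  xbar <- mean(pred)
  sxx <- sum((pred - xbar)^2)
  if (sxx == 0) {
    stop("outlier_fraction: degenerate fit (constant predictions)",
         call. = FALSE)
  }
  b <- sum((pred - xbar) * (obs - mean(obs))) / sxx
  a <- mean(obs) - b * xbar
  res <- obs - (a + b * pred)
  s2 <- sum(res^2) / (n - 2)
  extra <- if (bounds == "prediction") 1 else 0
  se <- sqrt(s2 * (extra + 1 / n + (pred - xbar)^2 / sxx))
  crit <- stats::qt(1 - (1 - level) / 2, df = n - 2)
  count <- sum(abs(res) > crit * se)
  list(count = count, percent = 100 * count / n, n = n)
}

#' Stage-wise fit report for a trained milk model
#'
#' Reproduces the standard evaluation layout: for the training rows, the
#' testing rows and all rows pooled, the sample count, the observation
#' count (samples times four targets), pooled `R`, slope `b` and MSE on
#' the normalized scale, plus the 95 percent prediction-interval outlier
#' count over all observations and de-normalized per-target RMSEs for
#' interpretability.
#'
#' @param model a fitted `milk_model`.
#' @param fm the `feature_matrix` it was fitted on.
#' @param outlier_level level of the outlier bounds, default 0.95.
#' @return an object of class `fit_report`: list with `stages` (data
#'   frame: stage, samples, observations, r, b, mse), `outliers`,
#'   `per_target` (data frame of test-stage per-target normalized R and
#'   original-unit RMSE).
#' @export
build_report <- function(model, fm, outlier_level = 0.95) {
  stopifnot(inherits(model, "milk_model"), inherits(fm, "feature_matrix"),
            !is.null(fm$targets))
  if (!identical(fm$signature, model$signature)) {
    stop("build_report: feature-matrix signature does not match the model",
         call. = FALSE)
  }
  xn <- apply_normalizer(model$norm_x, fm$inputs)
  tn <- apply_normalizer(model$norm_t, fm$targets)
  yn <- forward(model, xn)
  split <- model$split
  n_targets <- ncol(tn)
  stage_rows <- list(training = split$train, test = split$test,
                     overall = seq_len(nrow(xn)))
  stages <- do.call(rbind, lapply(names(stage_rows), function(nm) {
    rows <- stage_rows[[nm]]
    m <- regression_metrics(yn[rows, ], tn[rows, ])
    data.frame(stage = nm, samples = length(rows),
               observations = length(rows) * n_targets,
               r = m$r, b = m$b, mse = m$mse)
  }))
  out <- outlier_fraction(as.numeric(yn), as.numeric(tn),
                          level = outlier_level)
  y <- invert_normalizer(model$norm_t, yn)
  per_target <- do.call(rbind, lapply(seq_len(n_targets), function(k) {
    rows <- split$test
    data.frame(
      target = feature_target_cols[k],
      r = stats::cor(yn[rows, k], tn[rows, k]),
      rmse = sqrt(mean((y[rows, k] - fm$targets[rows, k])^2)))
  }))
  structure(list(stages = stages, outliers = out, per_target = per_target),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  df <- x$stages
  df$r <- round(df$r, 3)
  df$b <- round(df$b, 3)
  df$mse <- signif(df$mse, 3)
  print(df, row.names = FALSE)
  cat(sprintf("outliers beyond 95%% prediction bounds: %d of %d (%.2f%%)\n",
              x$outliers$count, x$outliers$n, x$outliers$percent))
  invisible(x)
}

#' Write a fit report as CSV and JSON
#'
#' @param report a `fit_report`.
#' @param csv_path,json_path output paths; either may be `NULL` to skip.
#' @return invisibly, the report.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(report$stages, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(stages = report$stages, outliers = report$outliers,
           per_target = report$per_target),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

.season_of <- function(month, hemisphere) {
  north <- c("winter", "winter", "spring", "spring", "spring",
             "summer", "summer", "summer", "autumn", "autumn",
             "autumn", "winter")
  south <- c("summer", "summer", "autumn", "autumn", "autumn",
             "winter", "winter", "winter", "spring", "spring",
             "spring", "summer")
  if (hemisphere == "south") south[month] else north[month]
}

#' Seasonal means of THI-9 and the four production targets
#'
#' Groups cow-day records by meteorological season and year and averages
#' THI variant 9 and the four targets. December is assigned to the
#' following year's summer in the Southern Hemisphere (and to the
#' following year's winter in the Northern), so a season never straddles
#' a year label.
#'
#' @param cow_days cow-day records with a `date` column and the four
#'   target columns.
#' @param derived_weather daily weather carrying `thi9`.
#' @param hemisphere `"south"` (default) or `"north"`.
#' @return data frame keyed by `season`, `year` with columns
#'   `mean_thi9`, `mean_milk_yield_kg`, `mean_protein_pct`,
#'   `mean_fat_pct`, `mean_feed_intake_kg`, `n_days`.
#' @export
seasonal_summary <- function(cow_days, derived_weather,
                             hemisphere = c("south", "north")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot("thi9" %in% names(derived_weather))
  wi <- match(as.character(cow_days$date),
              as.character(derived_weather$date))
  if (anyNA(wi)) {
    stop("seasonal_summary: cow-day dates missing from weather",
         call. = FALSE)
  }
  lt <- as.POSIXlt(cow_days$date)
  month <- lt$mon + 1
  year <- lt$year + 1900 + (month == 12)  # December -> next year's season
  season <- .season_of(month, hemisphere)
  thi9 <- derived_weather$thi9[wi]
  agg <- stats::aggregate(
    cbind(mean_thi9 = thi9,
          mean_milk_yield_kg = cow_days$milk_yield_kg,
          mean_protein_pct = cow_days$protein_pct,
          mean_fat_pct = cow_days$fat_pct,
          mean_feed_intake_kg = cow_days$feed_intake_kg),
    by = list(season = season, year = year), FUN = mean)
  counts <- stats::aggregate(list(n_days = thi9),
                             by = list(season = season, year = year),
                             FUN = length)
  out <- merge(agg, counts, by = c("season", "year"))
  out[order(out$year, match(out$season,
                            c("summer", "autumn", "winter", "spring"))), ,
      drop = FALSE]
}
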