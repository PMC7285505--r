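# End-to-end orchestration: simulate -> derive -> featurize -> fit ->
# evaluate -> draft, driven by one structured configuration. The
# exported functions are the interface; run_pipeline() is the single
# entry point a script or batch job calls.

#' Default pipeline configuration
#'
#' Returns the nested configuration list consumed by [run_pipeline()]:
#' sections `weather`, `herd`, `response`, `train`, `thresholds` and
#' top-level `n_days`, `n_cows`, `start_date`, `fraction`,
#' `hemisphere`. Any section may be partially overridden; omitted
#' entries keep the module defaults.
#'
#' @param n_cows,n_days herd size and horizon length.
#' @return a named list.
#' @export
default_config <- function(n_cows = 36, n_days = 730) {
  list(
    n_cows = n_cows,
    n_days = n_days,
    start_date = "2016-06-01",
    fraction = 0.7,
    hemisphere = "south",
    weather = list(),
    herd = list(bv_range = c(93, 112)),
    response = list(),
    train = list(n_hidden = 10, max_epochs = 1000),
    thresholds = list()
  )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path path to a YAML or JSON file whose keys follow
#'   [default_config()].
#' @return the merged configuration (file values over defaults).
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- default_config()
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]])) {
      base[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  base
}

#' Run the full pipeline on synthetic data
#'
#' Generates weather, herd and cow-day records under `seed`, derives the
#' psychrometric and THI columns, assembles and normalizes the feature
#' matrix, fits the Bayesian-regularized network, and produces the fit
#' report, the seasonal summary and (optionally) a drafting decision
#' log over the final summer of the horizon.
#'
#' @param config a configuration list as from [default_config()] or
#'   [read_config()].
#' @param seed master seed; the weather, herd, response and training
#'   seeds are derived from it deterministically.
#' @param draft run the drafting simulation as well.
#' @param verbose log per-stage timings and record counts to stderr.
#' @return list with `weather`, `herd`, `cow_days`, `features`,
#'   `model`, `report`, `seasonal`, `ceiling_r` and (when `draft`)
#'   `decisions`.
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         draft = TRUE, verbose = FALSE) {
  say <- function(fmt, ...) {
    if (verbose) message(sprintf(paste0("[%s] ", fmt),
                                 format(Sys.time(), "%H:%M:%S"), ...))
  }
  seed <- as.integer(seed) %% .Machine$integer.max
  wp <- do.call(weather_sim_params,
                c(config$weather, list(seed = seed)))
  weather <- generate_weather(config$n_days, wp,
                              start_date = as.Date(config$start_date))
  weather <- derive_weather(weather)
  say("weather: %d days", nrow(weather))

  herd_args <- config$herd
  herd_args$n_cows <- config$n_cows
  herd_args$seed <- seed + 1L
  herd <- do.call(generate_herd, herd_args)
  say("herd: %d cows", nrow(herd))

  rp <- do.call(response_params, c(config$response, list(seed = seed + 2L)))
  cow_days <- generate_cow_days(weather, herd, rp)
  say("cow-days: %d records", nrow(cow_days))

  fm <- assemble_features(weather, cow_days)
  say("features: %d rows, %d dropped", nrow(fm$inputs), fm$n_dropped)

  tc <- do.call(train_config, config$train)
  t0 <- Sys.time()
  model <- fit_milk_model(fm, fraction = config$fraction, seed = seed + 3L,
                          config = tc)
  say("training: %d epochs in %.1f s (stop: %s)",
      nrow(model$history), as.numeric(Sys.time() - t0, units = "secs"),
      model$reason)

  report <- build_report(model, fm)
  seasonal <- seasonal_summary(cow_days, weather,
                               hemisphere = config$hemisphere)
  ceiling_r <- noise_ceiling_r(cow_days, model$norm_t, model$split$test)
  out <- list(weather = weather, herd = herd, cow_days = cow_days,
              features = fm, model = model, report = report,
              seasonal = seasonal, ceiling_r = ceiling_r)
  if (draft) {
    th <- do.call(drafting_thresholds, config$thresholds)
    # draft over the hottest 90-day window of the horizon
    thi_run <- stats::filter(weather$thi9, rep(1 / 90, 90), sides = 1)
    end <- which.max(thi_run)
    horizon <- weather$date[max(1, end - 89):end]
    cd <- cow_days[cow_days$date %in% horizon, , drop = FALSE]
    out$decisions <- run_drafting_sim(model, cd, weather, th)
    say("drafting: %d decisions over %d days", nrow(out$decisions),
        length(horizon))
  }
  out
}
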