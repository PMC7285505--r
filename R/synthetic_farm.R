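# Seeded synthetic robotic-dairy-farm generator: daily weather with a
# Southern-Hemisphere seasonal cycle, a herd with heat-tolerance breeding
# values, and cow-day records produced by a known generative response model
# (Wood lactation curve with a linear heat-stress decrement above a THI
# threshold). The generator exists so that feature assembly, training,
# evaluation and drafting are testable end to end against a ground truth.

.check_fields <- function(params, checks, ctor) {
  bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
  if (length(bad)) {
    stop(sprintf("%s: invalid parameter(s): %s", ctor,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
}

#' Parameters of the synthetic daily-weather generator
#'
#' Daily-maximum temperature follows an annual cosine plus an AR(1)
#' residual; relative humidity has its own seasonal cycle (peaking half a
#' year after the temperature peak) and is coupled negatively to the
#' temperature anomaly; rainfall is a wet-day Bernoulli/gamma mixture and
#' wind speed a gamma draw. Defaults describe a warm-temperate inland
#' Southern-Hemisphere site: annual mean daily-max near 21 degC with a
#' +/- 9.5 degC seasonal swing peaking in mid January, humid winters,
#' about one rain day in three.
#'
#' @param t_mean annual mean of daily-maximum temperature, degC.
#' @param t_amp seasonal amplitude of daily-maximum temperature, degC.
#' @param t_peak_doy day of year at which the seasonal cycle peaks
#'   (15 = mid January, Southern-Hemisphere summer).
#' @param t_ar1 AR(1) coefficient of the temperature residual, in `[0, 1)`.
#' @param t_sd innovation standard deviation of the AR(1) residual, degC.
#' @param rh_base,rh_amp relative-humidity base level and seasonal
#'   amplitude, percent; the humidity cycle peaks in winter.
#' @param rh_t_slope coupling of humidity to the temperature anomaly,
#'   percent per degC (negative: hot anomalies are dry).
#' @param rh_sd humidity observation noise, percent.
#' @param rain_wet_prob probability that a day is wet.
#' @param rain_shape,rain_scale gamma parameters of wet-day rainfall, mm.
#' @param wind_shape,wind_scale gamma parameters of daily-max wind speed,
#'   km/h.
#' @param wind_dir_mean,wind_dir_sd prevailing wind direction and spread,
#'   degrees.
#' @param pressure_kpa surface pressure, kPa.
#' @param seed integer RNG seed.
#' @return an object of class `weather_sim_params`.
#' @export
weather_sim_params <- function(t_mean = 21, t_amp = 9.5, t_peak_doy = 15,
                               t_ar1 = 0.7, t_sd = 3.5,
                               rh_base = 85, rh_amp = 10, rh_t_slope = -1.6,
                               rh_sd = 5,
                               rain_wet_prob = 0.35, rain_shape = 0.6,
                               rain_scale = 6.5,
                               wind_shape = 9, wind_scale = 1.8,
                               wind_dir_mean = 340, wind_dir_sd = 25,
                               pressure_kpa = 101.325, seed = 1L) {
  p <- as.list(environment())
  .check_fields(p, list(
    t_ar1 = p$t_ar1 >= 0 && p$t_ar1 < 1,
    t_sd = p$t_sd >= 0,
    t_amp = p$t_amp >= 0,
    rh_sd = p$rh_sd >= 0,
    rain_wet_prob = p$rain_wet_prob >= 0 && p$rain_wet_prob <= 1,
    rain_shape = p$rain_shape > 0,
    rain_scale = p$rain_scale > 0,
    wind_shape = p$wind_shape > 0,
    wind_scale = p$wind_scale > 0,
    pressure_kpa = p$pressure_kpa > 0
  ), "weather_sim_params")
  structure(p, class = "weather_sim_params")
}

#' Generate a seeded synthetic daily weather series
#'
#' @param n_days number of consecutive days to generate (>= 1).
#' @param params a [weather_sim_params()] object (its `seed` drives all
#'   randomness; the call is reproducible).
#' @param start_date first calendar day of the series.
#' @return data frame with columns `date`, `temp_c`, `rh_pct`, `rain_mm`,
#'   `wind_kmh`, `wind_dir_deg`, `pressure_kpa` (all values are daily
#'   maxima except rainfall, a daily total). Temperature is kept within
#'   `[-5, 48]` degC and humidity within `(5, 100]`.
#' @export
generate_weather <- function(n_days, params = weather_sim_params(),
                             start_date = as.Date("2016-06-01")) {
  stopifnot(inherits(params, "weather_sim_params"), n_days >= 1)
  set.seed(params$seed)
  dates <- start_date + seq_len(n_days) - 1L
  doy <- as.POSIXlt(dates)$yday + 1
  seas <- cos(2 * pi * (doy - params$t_peak_doy) / 365.25)
  resid <- as.numeric(stats::filter(stats::rnorm(n_days, 0, params$t_sd),
                                    params$t_ar1, method = "recursive"))
  temp <- pmin(48, pmax(-5, params$t_mean + params$t_amp * seas + resid))
  winter_seas <- cos(2 * pi * (doy - (params$t_peak_doy + 182.625)) / 365.25)
  rh <- params$rh_base + params$rh_amp * winter_seas +
    params$rh_t_slope * resid + stats::rnorm(n_days, 0, params$rh_sd)
  rh <- pmin(100, pmax(6, rh))
  wet <- stats::runif(n_days) < params$rain_wet_prob
  rain <- round(ifelse(
    wet, stats::rgamma(n_days, params$rain_shape, scale = params$rain_scale),
    0), 1)
  wind <- round(stats::rgamma(n_days, params$wind_shape,
                              scale = params$wind_scale), 1)
  wdir <- (params$wind_dir_mean +
             stats::rnorm(n_days, 0, params$wind_dir_sd)) %% 360
  data.frame(
    date = dates, temp_c = temp, rh_pct = rh, rain_mm = rain,
    wind_kmh = wind, wind_dir_deg = wdir, pressure_kpa = params$pressure_kpa
  )
}

#' Generate a synthetic herd
#'
#' Heat-tolerance breeding values are drawn uniformly on `bv_range`
#' (genomic scores centred at 100; the default range 93-112 spans cows
#' 7 percent less to 12 percent more tolerant than average). Lactation
#' numbers span parities 1-8, calving dates are staggered uniformly over
#' the year before the simulation start, and a configurable fraction of
#' cows are extended-lactation "carryover" cows that failed to conceive
#' on schedule and run lactations past 600 days.
#'
#' @param n_cows herd size (>= 1).
#' @param bv_range length-2 numeric, inclusive range of heat-tolerance
#'   breeding values.
#' @param seed integer RNG seed.
#' @param carryover_frac fraction of cows on an extended lactation cycle.
#' @return data frame with columns `cow_id`, `heat_tolerance_bv`,
#'   `lactation_number`, `days_in_milk0` (days since calving at simulation
#'   start), `cycle_days` (calving-to-calving interval), `liveweight_kg`.
#' @export
generate_herd <- function(n_cows, bv_range = c(93, 112), seed = 1L,
                          carryover_frac = 0.1) {
  if (n_cows < 1) stop("generate_herd: n_cows must be >= 1", call. = FALSE)
  if (length(bv_range) != 2 || bv_range[2] < bv_range[1] ||
      any(bv_range <= 0)) {
    stop("generate_herd: invalid bv_range", call. = FALSE)
  }
  set.seed(seed)
  data.frame(
    cow_id = sprintf("cow%04d", seq_len(n_cows)),
    heat_tolerance_bv = stats::runif(n_cows, bv_range[1], bv_range[2]),
    lactation_number = sample(1:8, n_cows, replace = TRUE,
                              prob = c(.18, .22, .20, .15, .10, .07, .05, .03)),
    days_in_milk0 = sample(0:360, n_cows, replace = TRUE),
    cycle_days = ifelse(stats::runif(n_cows) < carryover_frac, 720L, 370L),
    liveweight_kg = pmin(960, pmax(335, stats::rnorm(n_cows, 660, 70)))
  )
}

#' Parameters of the generative production-response model
#'
#' The latent (noiseless) milk yield of a cow on lactation day `t` is a
#' Wood curve `A * t^b * exp(-c * t)`, scaled by parity and liveweight,
#' by a milking-frequency factor, and by a heat-stress decrement that is
#' linear in the excess of THI variant 9 over a threshold `thi0`:
#' `1 - k_yield * s(bv) * max(0, thi9 - thi0)`, where
#' `s(bv) = 1 - (bv - 100) / 100` converts a heat-tolerance breeding
#' value into a susceptibility multiplier (bv 93 is 7 percent more
#' susceptible than average, bv 110 is 10 percent less). Milk protein and
#' fat are baselines with seasonal cycles, a heat term (protein) and a
#' yield-dilution term (fat); concentrate intake is the programmed
#' allocation capped by a heat-depressed appetite capacity. Observed
#' targets are the latent values plus Gaussian noise, clipped at zero.
#' Days with milking frequency zero have zero yield and zero intake.
#'
#' @param wood_a,wood_b,wood_c Wood lactation-curve parameters; the
#'   defaults peak near 32 kg/day around day 70.
#' @param thi0 THI-9 comfort threshold above which heat stress acts.
#' @param k_yield fractional yield loss per THI unit of excess for an
#'   average (bv 100) cow.
#' @param k_intake fractional appetite-capacity loss per THI unit of
#'   excess.
#' @param parity_gain vector of multiplicative parity factors indexed by
#'   `min(lactation_number, length(parity_gain))`.
#' @param liveweight_exp exponent of the liveweight scaling
#'   `(liveweight / 660)^liveweight_exp` of yield potential.
#' @param freq_exp exponent of the milking-frequency factor
#'   `(freq / 2.4)^freq_exp` (zero frequency always forces zero yield).
#' @param cow_effect_sd standard deviation of a log-normal cow-level
#'   yield-potential effect (unexplained individual merit).
#' @param protein_base,protein_seas_amp,protein_heat_slope milk protein
#'   percent: baseline, winter-peaking seasonal amplitude, and loss per
#'   THI unit of excess.
#' @param fat_base,fat_seas_amp,fat_dilution_slope milk fat percent:
#'   baseline, autumn-peaking seasonal amplitude, and dilution slope per
#'   kg of latent yield above `yield_ref`.
#' @param yield_ref reference yield (kg/day) for the fat-dilution and
#'   feed-programming terms.
#' @param feed_base,feed_yield_slope programmed concentrate feed kg/day:
#'   intercept and slope on pre-heat yield potential; clipped to
#'   `[0, 23]`.
#' @param intake_capacity_kg appetite capacity of an average cow at
#'   thermoneutrality, kg/day.
#' @param sd_yield,sd_protein,sd_fat,sd_intake observation-noise standard
#'   deviations of the four targets.
#' @param milking_freq_probs probabilities of milking frequencies
#'   0, 1, 2, 3, 4 per day.
#' @param seed integer RNG seed.
#' @return an object of class `response_params`.
#' @export
response_params <- function(wood_a = 14, wood_b = 0.25, wood_c = 0.0035,
                            thi0 = 72, k_yield = 0.008, k_intake = 0.02,
                            parity_gain = c(0.85, 1, 1.05, 1.08, 1.08),
                            liveweight_exp = 0.7, freq_exp = 0.15,
                            cow_effect_sd = 0.03,
                            protein_base = 3.35, protein_seas_amp = 0.12,
                            protein_heat_slope = 0.010,
                            fat_base = 4.2, fat_seas_amp = 0.12,
                            fat_dilution_slope = 0.025, yield_ref = 28,
                            feed_base = 2.5, feed_yield_slope = 0.22,
                            intake_capacity_kg = 10,
                            sd_yield = 2.5, sd_protein = 0.28, sd_fat = 0.55,
                            sd_intake = 0.9,
                            milking_freq_probs = c(0.01, 0.09, 0.5, 0.3, 0.1),
                            seed = 1L) {
  p <- as.list(environment())
  .check_fields(p, list(
    wood_a = p$wood_a >= 0, k_yield = p$k_yield >= 0,
    k_intake = p$k_intake >= 0,
    sd_yield = p$sd_yield >= 0, sd_protein = p$sd_protein >= 0,
    sd_fat = p$sd_fat >= 0, sd_intake = p$sd_intake >= 0,
    cow_effect_sd = p$cow_effect_sd >= 0,
    intake_capacity_kg = p$intake_capacity_kg > 0,
    milking_freq_probs = length(p$milking_freq_probs) == 5 &&
      all(p$milking_freq_probs >= 0) && sum(p$milking_freq_probs) > 0,
    thi0 = p$thi0 > 0
  ), "response_params")
  structure(p, class = "response_params")
}

#' Generate cow-day management and production records
#'
#' Crosses every cow in `herd` with every date in `weather` and applies
#' the generative response model of [response_params()]. Latent
#' (noiseless) values of the four targets are retained alongside the
#' observed ones so that downstream model fits can be compared against
#' the attainable noise ceiling.
#'
#' @param weather daily weather as from [generate_weather()]; derived
#'   columns are computed via [derive_weather()] when absent.
#' @param herd a herd as from [generate_herd()].
#' @param params a [response_params()] object.
#' @return data frame keyed by (`cow_id`, `date`) with management inputs
#'   (`programmed_feed_kg`, `lactation_days`, `lactation_number`,
#'   `milking_freq`, `liveweight_kg`), observed targets
#'   (`milk_yield_kg`, `protein_pct`, `fat_pct`, `feed_intake_kg`) and
#'   latent targets (`latent_*`).
#' @export
generate_cow_days <- function(weather, herd, params = response_params()) {
  stopifnot(inherits(params, "response_params"), nrow(herd) >= 1)
  if (!"thi9" %in% names(weather)) weather <- derive_weather(weather)
  set.seed(params$seed)
  n_cows <- nrow(herd)
  n_days <- nrow(weather)
  n <- n_cows * n_days
  ci <- rep(seq_len(n_cows), each = n_days)   # cow index
  di <- rep(seq_len(n_days), times = n_cows)  # day index

  cow_eff <- exp(stats::rnorm(n_cows, 0, params$cow_effect_sd))

  days_since <- herd$days_in_milk0[ci] + di - 1L
  cycle <- herd$cycle_days[ci]
  lact_days <- days_since %% cycle
  lact_no <- pmin(8L, herd$lactation_number[ci] + days_since %/% cycle)

  pf <- params$parity_gain[pmin(lact_no, length(params$parity_gain))]
  lw <- herd$liveweight_kg[ci] + stats::rnorm(n, 0, 3)
  lw_f <- (herd$liveweight_kg[ci] / 660)^params$liveweight_exp

  wood <- params$wood_a * lact_days^params$wood_b *
    exp(-params$wood_c * lact_days)
  potential <- wood * pf * lw_f * cow_eff[ci]

  excess <- pmax(0, weather$thi9[di] - params$thi0)
  s_bv <- 1 - (herd$heat_tolerance_bv[ci] - 100) / 100
  heat_f <- pmax(0, 1 - params$k_yield * s_bv * excess)

  freq <- sample(0:4, n, replace = TRUE,
                 prob = params$milking_freq_probs / sum(params$milking_freq_probs))
  freq_f <- ifelse(freq == 0, 0, (freq / 2.4)^params$freq_exp)

  latent_yield <- potential * heat_f * freq_f
  milk_yield <- pmax(0, latent_yield + stats::rnorm(n, 0, params$sd_yield))
  milk_yield[freq == 0] <- 0

  doy <- as.POSIXlt(weather$date)$yday + 1
  winter_seas <- cos(2 * pi * (doy - 197) / 365.25)[di]  # peak mid July
  autumn_seas <- cos(2 * pi * (doy - 105) / 365.25)[di]  # peak mid April

  latent_protein <- params$protein_base +
    params$protein_seas_amp * winter_seas -
    params$protein_heat_slope * excess
  protein <- pmax(0, latent_protein + stats::rnorm(n, 0, params$sd_protein))

  latent_fat <- params$fat_base + params$fat_seas_amp * autumn_seas -
    params$fat_dilution_slope * (latent_yield - params$yield_ref)
  fat <- pmax(0, latent_fat + stats::rnorm(n, 0, params$sd_fat))

  programmed <- pmin(23, pmax(
    0, round(params$feed_base + params$feed_yield_slope * potential, 1)))
  capacity <- params$intake_capacity_kg * (herd$liveweight_kg[ci] / 660) *
    pmax(0, 1 - params$k_intake * excess)
  latent_intake <- pmin(programmed, capacity)
  latent_intake[freq == 0] <- 0
  intake <- pmax(0, pmin(programmed + 2 * params$sd_intake,
                         latent_intake + stats::rnorm(n, 0, params$sd_intake)))
  intake[freq == 0] <- 0

  out <- data.frame(
    cow_id = herd$cow_id[ci],
    date = weather$date[di],
    programmed_feed_kg = programmed,
    lactation_days = lact_days,
    lactation_number = lact_no,
    milking_freq = freq,
    liveweight_kg = lw,
    milk_yield_kg = milk_yield,
    protein_pct = protein,
    fat_pct = fat,
    feed_intake_kg = intake,
    latent_milk_yield_kg = latent_yield,
    latent_protein_pct = pmax(0, latent_protein),
    latent_fat_pct = pmax(0, latent_fat),
    latent_feed_intake_kg = latent_intake
  )
  out[order(out$date, out$cow_id), , drop = FALSE]
}
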