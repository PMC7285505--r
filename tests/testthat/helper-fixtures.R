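# Shared fixtures, built in code at test time.

# Independently coded one-line transcriptions of the nine THI formulas
# (left-to-right grouping) used as oracles against thi().
thi_oracles <- list(
  function(t, rh, tw, td) 0.4 * (t + tw) * 1.8 + 32 + 15,
  function(t, rh, tw, td) (0.15 * t + 0.85 * tw) * 1.8 + 32,
  function(t, rh, tw, td) (t * 0.35 + tw * 0.65) * 1.8 + 32,
  function(t, rh, tw, td) 0.72 * (t + tw) + 40.6,
  function(t, rh, tw, td) (1.8 * t + 32) - (0.55 - 0.0055 * rh) * (1.8 + t - 26),
  function(t, rh, tw, td) (0.55 * t + 0.2 * td) * 1.8 + 32 + 17.5,
  function(t, rh, tw, td) t + 0.36 * td + 41.2,
  function(t, rh, tw, td) 0.8 * t + (rh / 100) * (t - 14.4) + 46.4,
  function(t, rh, tw, td) 3.43 + 1.058 * t - 0.293 * rh + 0.0164 * t * rh + 35.7
)

# Brute-force wet-bulb oracle: minimise |psychrometer balance| on a
# fine grid over the physical bracket.
wet_bulb_grid_oracle <- function(t, tdp, p_kpa = 101.325, step = 1e-4) {
  es <- function(x) 6.112 * exp(17.67 * x / (243.5 + x))
  grid <- seq(tdp, t, by = step)
  bal <- es(grid) - 6.6e-4 * (p_kpa * 10) * (t - grid) - es(tdp)
  grid[which.min(abs(bal))]
}

# Small derived daily weather table spanning both seasons.
tiny_weather <- function(n_days = 120, seed = 11,
                         start = as.Date("2016-12-01")) {
  derive_weather(generate_weather(
    n_days, weather_sim_params(seed = seed), start_date = start))
}

# Small complete farm: weather + herd + cow-days + feature matrix.
tiny_farm <- function(n_cows = 6, n_days = 60, seed = 7, ...) {
  weather <- derive_weather(generate_weather(
    n_days, weather_sim_params(seed = seed),
    start_date = as.Date("2017-01-01")))
  herd <- generate_herd(n_cows, seed = seed + 1)
  cow_days <- generate_cow_days(weather, herd,
                                response_params(seed = seed + 2, ...))
  list(weather = weather, herd = herd, cow_days = cow_days,
       fm = assemble_features(weather, cow_days))
}
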