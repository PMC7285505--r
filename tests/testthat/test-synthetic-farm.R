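test_that("weather generation is seed-reproducible and physically bounded", {
  p <- weather_sim_params(seed = 5)
  w1 <- generate_weather(730, p)
  w2 <- generate_weather(730, p)
  expect_identical(w1, w2)
  w3 <- generate_weather(730, weather_sim_params(seed = 6))
  expect_false(isTRUE(all.equal(w1$temp_c, w3$temp_c)))
  expect_true(all(w1$temp_c >= -5 & w1$temp_c <= 48))
  expect_true(all(w1$rh_pct > 5 & w1$rh_pct <= 100))
  expect_true(all(w1$rain_mm >= 0))
  expect_true(all(w1$wind_kmh >= 0))
  expect_true(all(w1$wind_dir_deg >= 0 & w1$wind_dir_deg <= 360))
})

test_that("the seasonal phase puts Southern-Hemisphere summer above winter", {
  w <- derive_weather(generate_weather(3650, weather_sim_params(seed = 2)))
  month <- as.POSIXlt(w$date)$mon + 1
  djf <- w$thi9[month %in% c(12, 1, 2)]
  jja <- w$thi9[month %in% 6:8]
  expect_true(mean(djf) > mean(jja))
})

test_that("degenerate weather parameters give a constant series", {
  p <- weather_sim_params(t_amp = 0, t_sd = 0, seed = 1)
  w <- generate_weather(100, p)
  expect_equal(w$temp_c, rep(p$t_mean, 100))
})

test_that("invalid generator parameters are rejected with field names", {
  expect_error(weather_sim_params(t_ar1 = 1.2), "t_ar1")
  expect_error(weather_sim_params(t_sd = -1, rain_shape = 0),
               "t_sd.*rain_shape|rain_shape.*t_sd")
  expect_error(response_params(k_yield = -0.1), "k_yield")
})

test_that("herd generation respects the breeding-value range and parity bounds", {
  herd <- generate_herd(36, c(93, 112), seed = 4)
  expect_equal(nrow(herd), 36)
  expect_true(all(herd$heat_tolerance_bv >= 93 & herd$heat_tolerance_bv <= 112))
  expect_true(all(herd$lactation_number %in% 1:8))
  big <- generate_herd(312, c(85, 120), seed = 4)
  expect_equal(nrow(big), 312)
  one <- generate_herd(1, c(100, 100), seed = 4)
  expect_equal(one$heat_tolerance_bv, 100)
  expect_error(generate_herd(0), "n_cows")
  expect_error(generate_herd(5, c(110, 93)), "bv_range")
})

test_that("with noise and all modifiers off, observed yield is the pure Wood curve", {
  weather <- derive_weather(generate_weather(
    40, weather_sim_params(seed = 9), start_date = as.Date("2017-06-01")))
  herd <- generate_herd(3, seed = 10)
  rp <- response_params(
    k_yield = 0, sd_yield = 0, sd_protein = 0, sd_fat = 0, sd_intake = 0,
    cow_effect_sd = 0, liveweight_exp = 0, freq_exp = 0,
    parity_gain = c(1, 1, 1, 1, 1),
    milking_freq_probs = c(0, 0, 1, 0, 0), seed = 11)
  cd <- generate_cow_days(weather, herd, rp)
  wood <- rp$wood_a * cd$lactation_days^rp$wood_b *
    exp(-rp$wood_c * cd$lactation_days)
  expect_equal(cd$milk_yield_kg, wood, tolerance = 1e-10)
  expect_equal(cd$latent_milk_yield_kg, wood, tolerance = 1e-10)
})

test_that("lower heat tolerance means lower latent yield on a hot day", {
  hot <- derive_weather(data.frame(
    date = as.Date("2018-01-15"), temp_c = 38, rh_pct = 45, rain_mm = 0,
    wind_kmh = 10, wind_dir_deg = 340, pressure_kpa = 101.325))
  expect_true(hot$thi9 > 80)
  herd <- generate_herd(2, c(100, 100), seed = 1)
  herd$heat_tolerance_bv <- c(93, 112)
  herd$lactation_number <- c(2L, 2L)
  herd$days_in_milk0 <- c(100L, 100L)
  herd$cycle_days <- c(370L, 370L)
  herd$liveweight_kg <- c(660, 660)
  rp <- response_params(sd_yield = 0, cow_effect_sd = 0,
                        milking_freq_probs = c(0, 0, 1, 0, 0), seed = 2)
  cd <- generate_cow_days(hot, herd, rp)
  y <- setNames(cd$latent_milk_yield_kg, cd$cow_id)
  expect_true(y[[herd$cow_id[1]]] < y[[herd$cow_id[2]]])
})

test_that("cow-day records keep the structural invariants", {
  farm <- tiny_farm(n_cows = 8, n_days = 90)
  cd <- farm$cow_days
  expect_equal(nrow(cd), 8 * 90)
  expect_true(all(cd$milk_yield_kg[cd$milking_freq == 0] == 0))
  expect_true(all(cd$feed_intake_kg <=
                    cd$programmed_feed_kg + 2 * response_params()$sd_intake + 1e-9))
  expect_true(all(cd$milk_yield_kg >= 0 & cd$protein_pct >= 0 &
                    cd$fat_pct >= 0 & cd$feed_intake_kg >= 0))
  # identical seeds reproduce bit for bit
  farm2 <- tiny_farm(n_cows = 8, n_days = 90)
  expect_identical(cd, farm2$cow_days)
})

test_that("default target means fall inside the published min-max envelopes", {
  weather <- derive_weather(generate_weather(730, weather_sim_params(seed = 21)))
  herd <- generate_herd(60, seed = 22)
  cd <- generate_cow_days(weather, herd, response_params(seed = 23))
  m <- colMeans(cd[, c("milk_yield_kg", "protein_pct", "fat_pct",
                       "feed_intake_kg")])
  expect_gt(m[["milk_yield_kg"]], 0); expect_lt(m[["milk_yield_kg"]], 65.4)
  expect_gt(m[["protein_pct"]], 0.9); expect_lt(m[["protein_pct"]], 6.1)
  expect_gt(m[["fat_pct"]], 0.7); expect_lt(m[["fat_pct"]], 10.9)
  expect_gt(m[["feed_intake_kg"]], 0); expect_lt(m[["feed_intake_kg"]], 24.3)
})
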