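test_that("intraday records aggregate to daily maxima with the documented tie-break", {
  ts <- as.POSIXct("2018-01-03 00:00", tz = "UTC") + seq(0, 95) * 900
  intraday <- data.frame(
    timestamp = ts,
    temp_c = c(20 + 11 * sin(seq(0, pi, length.out = 95)), 31.2),
    rh_pct = 70 + seq(0, 95) %% 20,
    rain_mm = cumsum(rep(c(0, 0.2), 48)),  # running total
    wind_kmh = 10 + (seq(0, 95) %% 7),
    wind_dir_deg = seq(0, 95) * 3 %% 360)
  day <- aggregate_daily_max(intraday)
  expect_equal(nrow(day), 1)
  expect_equal(day$temp_c, max(intraday$temp_c))
  expect_equal(day$temp_c, 31.2, tolerance = 1e-9)
  expect_equal(day$rain_mm, max(intraday$rain_mm))
  expect_equal(day$wind_kmh, max(intraday$wind_kmh))
  # earliest record among those at max wind speed supplies the direction
  first_max <- which(intraday$wind_kmh == max(intraday$wind_kmh))[1]
  expect_equal(day$wind_dir_deg, intraday$wind_dir_deg[first_max])
  # literal-max dialect takes the (physically meaningless) max of degrees
  lit <- aggregate_daily_max(intraday, winddir_daily = "literal-max")
  expect_equal(lit$wind_dir_deg, max(intraday$wind_dir_deg))
})

test_that("single-record days pass through aggregation unchanged", {
  one <- data.frame(timestamp = as.POSIXct("2018-02-01 14:00", tz = "UTC"),
                    temp_c = 33.1, rh_pct = 41, rain_mm = 0.4,
                    wind_kmh = 22, wind_dir_deg = 310)
  day <- aggregate_daily_max(one)
  expect_equal(day$temp_c, 33.1)
  expect_equal(day$wind_dir_deg, 310)
  expect_equal(day$date, as.Date("2018-02-01"))
})

test_that("the feature matrix has the frozen 21 + 4 column layout", {
  farm <- tiny_farm(n_cows = 2, n_days = 3)
  fm <- farm$fm
  expect_s3_class(fm, "feature_matrix")
  expect_equal(dim(fm$inputs), c(6, 21))
  expect_equal(dim(fm$targets), c(6, 4))
  expect_identical(colnames(fm$inputs), feature_input_cols)
  expect_identical(colnames(fm$targets), feature_target_cols)
  expect_equal(fm$n_dropped, 0)
  # column 8 (thi1) is reproducible from columns 1 and 7
  expect_equal(fm$inputs[, "thi1"],
               thi(1, fm$inputs[, "temp_c"], twet_c = fm$inputs[, "twet_c"]),
               tolerance = 1e-12)
  expect_equal(fm$inputs[, "thi9"],
               thi(9, fm$inputs[, "temp_c"], rh_pct = fm$inputs[, "rh_pct"]),
               tolerance = 1e-12)
})

test_that("rows with missing values are dropped and counted; zero milking frequency is retained", {
  farm <- tiny_farm(n_cows = 2, n_days = 3)
  cd <- farm$cow_days
  cd$liveweight_kg[2] <- NA
  fm <- assemble_features(farm$weather, cd)
  expect_equal(nrow(fm$inputs), 5)
  expect_equal(fm$n_dropped, 1)
  cd2 <- farm$cow_days
  cd2$milking_freq <- 0
  cd2$milk_yield_kg <- 0
  fm2 <- assemble_features(farm$weather, cd2)
  expect_equal(nrow(fm2$inputs), 6)
})

test_that("assembly fails loudly when a cow-day has no weather", {
  farm <- tiny_farm(n_cows = 2, n_days = 3)
  cd <- farm$cow_days
  cd$date[1] <- as.Date("1999-01-01")
  expect_error(assemble_features(farm$weather, cd), "1999-01-01")
})

test_that("assembly is permutation-invariant up to row keys", {
  farm <- tiny_farm(n_cows = 3, n_days = 4)
  shuffled <- farm$cow_days[sample(nrow(farm$cow_days)), ]
  fm1 <- farm$fm
  fm2 <- assemble_features(farm$weather, shuffled)
  key1 <- paste(fm1$keys$cow_id, fm1$keys$date)
  key2 <- paste(fm2$keys$cow_id, fm2$keys$date)
  ord <- match(key1, key2)
  expect_equal(fm1$inputs, fm2$inputs[ord, ], ignore_attr = TRUE)
  expect_equal(fm1$targets, fm2$targets[ord, ], ignore_attr = TRUE)
})

test_that("min-max normalization maps extremes to +/-1 and round-trips", {
  x <- cbind(a = c(2, 5, 11), b = c(-4, 0, 4))
  norm <- fit_normalizer(x)
  xn <- apply_normalizer(norm, x)
  expect_equal(unname(xn[1, "a"]), -1)
  expect_equal(unname(xn[3, "a"]), 1)
  expect_equal(invert_normalizer(norm, xn), x, tolerance = 1e-12)
  set.seed(1)
  y <- matrix(rnorm(300), 100, 3)
  n2 <- fit_normalizer(y)
  expect_equal(invert_normalizer(n2, apply_normalizer(n2, y)), y,
               tolerance = 1e-12)
})

test_that("values outside the fitted range map outside [-1, 1] unclipped", {
  x <- matrix(c(0, 1, 2), dimnames = list(NULL, "v"))
  norm <- fit_normalizer(x, rows = 1:2)  # fitted on [0, 1]
  expect_equal(apply_normalizer(norm, matrix(2))[1], 3)
})

test_that("constant columns are rejected by name", {
  x <- cbind(ok = 1:3, flat = c(7, 7, 7))
  expect_error(fit_normalizer(x), "flat")
})

test_that("the random split reproduces the published partition arithmetic", {
  s1 <- split_rows(29114, 0.7, seed = 123)
  expect_equal(length(s1$train), 20380)
  expect_equal(length(s1$test), 8734)
  s2 <- split_rows(166459, 0.7, seed = 99)
  expect_equal(length(s2$train), 116521)
  expect_equal(length(s2$test), 49938)
  expect_equal(sort(c(s1$train, s1$test)), 1:29114)
  expect_length(intersect(s1$train, s1$test), 0)
  # deterministic under seed
  expect_identical(split_rows(10, 0.7, seed = 5), split_rows(10, 0.7, seed = 5))
  expect_error(split_rows(2, 0.1), "empty partition")
})

test_that("prepare_dataset fits the normalizer on training rows only by default", {
  farm <- tiny_farm(n_cows = 4, n_days = 30)
  ds <- prepare_dataset(farm$fm, seed = 3)
  train_x <- ds$xn[ds$split$train, ]
  expect_equal(max(train_x), 1, tolerance = 1e-12)
  expect_equal(min(train_x), -1, tolerance = 1e-12)
  # with normalize_on = "all" the global extremes are the +/-1 points
  ds2 <- prepare_dataset(farm$fm, seed = 3, normalize_on = "all")
  expect_equal(range(ds2$xn), c(-1, 1), tolerance = 1e-12)
})

test_that("feature CSV and sidecar round-trip", {
  farm <- tiny_farm(n_cows = 2, n_days = 5)
  tmp <- tempfile(fileext = ".csv")
  ds <- prepare_dataset(farm$fm, seed = 1)
  write_feature_csv(farm$fm, tmp, norm_x = ds$norm_x, norm_t = ds$norm_t,
                    split = ds$split)
  back <- read_feature_csv(tmp)
  expect_equal(back$inputs, farm$fm$inputs, ignore_attr = TRUE,
               tolerance = 1e-9)
  side <- attr(back, "sidecar")
  expect_equal(unlist(side$split$train), ds$split$train)
  expect_equal(unlist(side$norm_x$min), unname(ds$norm_x$min))
  unlink(c(tmp, paste0(tmp, ".json")))
})
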