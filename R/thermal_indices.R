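#' @keywords internal
"_PACKAGE"

# Magnus constants shared by the dewpoint formula and the saturation
# vapour-pressure curve used in the wet-bulb balance (reference 6.112 hPa).
.magnus_a <- 17.67
.magnus_b <- 243.5
.magnus_e0 <- 6.112

#' Saturation vapour pressure (Magnus form)
#'
#' @param temp_c temperature in degrees Celsius.
#' @return saturation vapour pressure in hPa.
#' @keywords internal
saturation_vp_hpa <- function(temp_c) {
  .magnus_e0 * exp(.magnus_a * temp_c / (.magnus_b + temp_c))
}

#' Dewpoint temperature from dry-bulb temperature and relative humidity
#'
#' Magnus-form dewpoint with constants 17.67 and 243.5 degC. At `rh_pct = 100`
#' the formula collapses to the identity `tdp = temp_c`.
#'
#' @param temp_c dry-bulb temperature, degC; must exceed -243.5.
#' @param rh_pct relative humidity in percent, on (0, 100].
#' @return dewpoint temperature in degC, never above `temp_c`.
#' @examples
#' dewpoint_c(25, 100) # 25
#' dewpoint_c(25, 50)  # about 13.87
#' @export
dewpoint_c <- function(temp_c, rh_pct) {
  if (any(!is.finite(temp_c)) || any(!is.finite(rh_pct))) {
    stop("dewpoint_c: non-finite inputs", call. = FALSE)
  }
  if (any(rh_pct <= 0)) {
    stop("dewpoint_c: rh_pct must be > 0 (log undefined at or below 0)",
         call. = FALSE)
  }
  if (any(rh_pct > 100)) {
    stop("dewpoint_c: rh_pct must be <= 100", call. = FALSE)
  }
  if (any(temp_c <= -.magnus_b)) {
    stop("dewpoint_c: temp_c must exceed -243.5", call. = FALSE)
  }
  g <- .magnus_a * temp_c / (.magnus_b + temp_c) + log(rh_pct / 100)
  .magnus_b * g / (.magnus_a - g)
}

#' Wet-bulb temperature by bisection on the psychrometer balance
#'
#' Solves `e(tdp) = es(twet) - A * P * (temp - twet)` for `twet` on the
#' bracket `[tdp, temp]`, where `es` is the Magnus saturation curve and
#' `A = 6.6e-4 / degC` is the psychrometer coefficient for an unventilated
#' thermometer. The root is bracketed by construction: the balance is
#' negative at `tdp` and non-negative at `temp`.
#'
#' @param temp_c dry-bulb temperature, degC.
#' @param tdp_c dewpoint temperature, degC; must not exceed `temp_c`.
#' @param pressure_kpa surface pressure in kPa (default one standard
#'   atmosphere, 101.325 kPa).
#' @param tol absolute convergence tolerance on the bracket width, degC.
#' @param max_iter iteration cap for the bisection.
#' @return wet-bulb temperature in degC, with `tdp_c <= twet <= temp_c`.
#' @export
wet_bulb_c <- function(temp_c, tdp_c, pressure_kpa = 101.325,
                       tol = 1e-3, max_iter = 100L) {
  if (any(tdp_c > temp_c + 1e-9)) {
    stop("wet_bulb_c: tdp_c exceeds temp_c (invalid psychrometric state)",
         call. = FALSE)
  }
  if (any(pressure_kpa <= 0)) {
    stop("wet_bulb_c: pressure_kpa must be positive", call. = FALSE)
  }
  n <- max(length(temp_c), length(tdp_c), length(pressure_kpa))
  temp_c <- rep_len(temp_c, n)
  tdp_c <- pmin(rep_len(tdp_c, n), temp_c)
  p_hpa <- rep_len(pressure_kpa, n) * 10
  a_psy <- 6.6e-4
  e_act <- saturation_vp_hpa(tdp_c)
  balance <- function(tw) {
    saturation_vp_hpa(tw) - a_psy * p_hpa * (temp_c - tw) - e_act
  }
  lo <- tdp_c
  hi <- temp_c
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    if (all(hi - lo < tol)) {
      converged <- TRUE
      break
    }
    mid <- (lo + hi) / 2
    up <- balance(mid) > 0
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
  }
  if (!converged && any(hi - lo >= tol)) {
    j <- which(hi - lo >= tol)[1]
    stop(sprintf(
      "wet_bulb_c: bisection did not converge within %d iterations on bracket [%.4f, %.4f]",
      max_iter, lo[j], hi[j]), call. = FALSE)
  }
  (lo + hi) / 2
}

#' Temperature-humidity index, nine published variants
#'
#' Evaluates variant `k` (1-9) of the temperature-humidity index. Each
#' formula is evaluated with strict left-to-right grouping; in particular
#' `thi(1, ...)` is `((0.4 * (T + Twet)) * 1.8) + 32 + 15`, so
#' `thi(1, ...) - thi(4, ...)` is identically 6.4 for any input.
#'
#' Variants 1-4 require the wet-bulb temperature, 6-7 the dewpoint, and
#' 5, 8, 9 the relative humidity.
#'
#' Variant 5 exists in two dialects. The default, `"printed"`, uses the
#' term `(1.8 + T - 26)`; the `"corrected"` dialect uses `(1.8 * T - 26)`
#' as in most of the index literature. Neither is asserted as canonical:
#' the two differ only through a multiplier `0.55 - 0.0055 * RH` that is
#' near zero in humid conditions.
#'
#' @param k integer index of the variant, 1 through 9.
#' @param temp_c dry-bulb temperature, degC.
#' @param rh_pct relative humidity, percent (variants 5, 8, 9).
#' @param twet_c wet-bulb temperature, degC (variants 1-4).
#' @param tdp_c dewpoint temperature, degC (variants 6-7).
#' @param thi5_dialect `"printed"` or `"corrected"`, see Details.
#' @return dimensionless index value(s).
#' @examples
#' thi(9, temp_c = 30, rh_pct = 60) # 82.81
#' @export
thi <- function(k, temp_c, rh_pct = NULL, twet_c = NULL, tdp_c = NULL,
                thi5_dialect = c("printed", "corrected")) {
  thi5_dialect <- match.arg(thi5_dialect)
  if (length(k) != 1L || !(k %in% 1:9)) {
    stop("thi: k must be a single integer in 1..9", call. = FALSE)
  }
  need <- function(x, nm) {
    if (is.null(x)) {
      stop(sprintf("thi: variant %d requires %s", k, nm), call. = FALSE)
    }
    x
  }
  t <- temp_c
  switch(as.character(k),
    "1" = {
      tw <- need(twet_c, "twet_c")
      0.4 * (t + tw) * 1.8 + 32 + 15
    },
    "2" = {
      tw <- need(twet_c, "twet_c")
      (0.15 * t + 0.85 * tw) * 1.8 + 32
    },
    "3" = {
      tw <- need(twet_c, "twet_c")
      (t * 0.35 + tw * 0.65) * 1.8 + 32
    },
    "4" = {
      tw <- need(twet_c, "twet_c")
      0.72 * (t + tw) + 40.6
    },
    "5" = {
      rh <- need(rh_pct, "rh_pct")
      lin <- if (thi5_dialect == "printed") 1.8 + t - 26 else 1.8 * t - 26
      (1.8 * t + 32) - (0.55 - 0.0055 * rh) * lin
    },
    "6" = {
      td <- need(tdp_c, "tdp_c")
      (0.55 * t + 0.2 * td) * 1.8 + 32 + 17.5
    },
    "7" = {
      td <- need(tdp_c, "tdp_c")
      t + 0.36 * td + 41.2
    },
    "8" = {
      rh <- need(rh_pct, "rh_pct")
      0.8 * t + (rh / 100) * (t - 14.4) + 46.4
    },
    "9" = {
      rh <- need(rh_pct, "rh_pct")
      3.43 + 1.058 * t - 0.293 * rh + 0.0164 * t * rh + 35.7
    }
  )
}

#' Derive psychrometric quantities and all nine THI variants
#'
#' Takes a weather table with columns `temp_c` and `rh_pct` (and optionally
#' `pressure_kpa`; defaulted to 101.325 when absent) and appends `tdp_c`,
#' `twet_c` and `thi1` ... `thi9`. Rows already carrying these columns are
#' recomputed, so the operation is idempotent.
#'
#' @param weather data frame with at least `temp_c` and `rh_pct`; a `date`
#'   column, if present, is used to tag validation errors.
#' @param thi5_dialect passed to [thi()].
#' @return the input data frame with columns `tdp_c`, `twet_c`,
#'   `thi1`..`thi9` appended (or replaced).
#' @export
derive_weather <- function(weather, thi5_dialect = c("printed", "corrected")) {
  thi5_dialect <- match.arg(thi5_dialect)
  stopifnot(is.data.frame(weather))
  for (col in c("temp_c", "rh_pct")) {
    if (!col %in% names(weather)) {
      stop(sprintf("derive_weather: missing column '%s'", col), call. = FALSE)
    }
  }
  tag <- function(i) {
    if ("date" %in% names(weather)) as.character(weather$date[i]) else
      sprintf("row %d", i)
  }
  bad_rh <- which(!is.finite(weather$rh_pct) | weather$rh_pct <= 0 |
                    weather$rh_pct > 100)
  if (length(bad_rh)) {
    stop(sprintf("derive_weather: rh_pct out of (0, 100] on %s",
                 tag(bad_rh[1])), call. = FALSE)
  }
  bad_t <- which(!is.finite(weather$temp_c))
  if (length(bad_t)) {
    stop(sprintf("derive_weather: non-finite temp_c on %s", tag(bad_t[1])),
         call. = FALSE)
  }
  p <- if ("pressure_kpa" %in% names(weather)) weather$pressure_kpa else 101.325
  if (any(p <= 0)) {
    stop(sprintf("derive_weather: pressure_kpa must be positive on %s",
                 tag(which(p <= 0)[1])), call. = FALSE)
  }
  tdp <- dewpoint_c(weather$temp_c, weather$rh_pct)
  twet <- wet_bulb_c(weather$temp_c, tdp, p)
  weather$tdp_c <- tdp
  weather$twet_c <- twet
  for (k in 1:9) {
    weather[[paste0("thi", k)]] <- thi(
      k, weather$temp_c, rh_pct = weather$rh_pct,
      twet_c = twet, tdp_c = tdp, thi5_dialect = thi5_dialect)
  }
  weather
}
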