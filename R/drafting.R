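# Heat-stress drafting-gate decision system: each cow presenting for
# milking is routed to sprinkler cooling or to normal milking from the
# day's weather-derived THI and the model's predicted production, with a
# next-day reassessment state machine (a cow still stressed on day two
# is cooled AND milked, to avoid mastitis).

#' Drafting thresholds
#'
#' A cow is flagged as heat-stressed when the day's THI-9 exceeds
#' `thi_threshold` and (by default) at least one model-predicted output
#' falls below its floor. Floors set to `-Inf` are inactive.
#'
#' @param min_yield_kg minimum acceptable predicted milk yield, kg/day.
#' @param min_protein_pct minimum acceptable predicted milk protein.
#' @param min_fat_pct minimum acceptable predicted milk fat.
#' @param thi_threshold THI-9 comfort boundary, within `[50, 90]`.
#' @return an object of class `drafting_thresholds`.
#' @export
drafting_thresholds <- function(min_yield_kg = 20, min_protein_pct = 3.0,
                                min_fat_pct = 3.5, thi_threshold = 72) {
  stopifnot(is.finite(thi_threshold), thi_threshold >= 50,
            thi_threshold <= 90)
  structure(list(min_yield_kg = min_yield_kg,
                 min_protein_pct = min_protein_pct,
                 min_fat_pct = min_fat_pct,
                 thi_threshold = thi_threshold),
            class = "drafting_thresholds")
}

.stress_states <- c("NORMAL", "STRESSED_DAY1", "STRESSED_PERSISTENT")

#' Assess one cow on one day and route her through the drafting gate
#'
#' The stress flag is, by default, the conjunction of an environmental
#' trigger (THI-9 above the threshold) and a production trigger (any
#' predicted target below its floor); `mode = "disjunction"` flags on
#' either. Routing follows the reassessment state machine: a newly
#' flagged cow is drafted to cooling (`COOLING`, state
#' `STRESSED_DAY1`); a cow flagged again the next day is cooled and
#' milked (`COOLING_AND_MILK`, state `STRESSED_PERSISTENT`, where she
#' remains while flagged); an unflagged cow is milked normally and
#' returns to `NORMAL`.
#'
#' @param pred named numeric vector of predicted targets (needs
#'   `milk_yield_kg`, `protein_pct`, `fat_pct`).
#' @param thi9 the day's THI variant 9.
#' @param state current state, one of `"NORMAL"`, `"STRESSED_DAY1"`,
#'   `"STRESSED_PERSISTENT"`.
#' @param thresholds a [drafting_thresholds()] object.
#' @param mode `"conjunction"` (default) or `"disjunction"`.
#' @return list with `route` (`"MILKING"`, `"COOLING"` or
#'   `"COOLING_AND_MILK"`), `state` (the new state) and `trigger`
#'   (comma-separated names of the fired thresholds, `""` when none).
#' @export
assess_cow <- function(pred, thi9, state, thresholds,
                       mode = c("conjunction", "disjunction")) {
  mode <- match.arg(mode)
  stopifnot(inherits(thresholds, "drafting_thresholds"),
            state %in% .stress_states)
  hot <- thi9 > thresholds$thi_threshold
  shortfall <- c(
    yield = unname(pred["milk_yield_kg"] < thresholds$min_yield_kg),
    protein = unname(pred["protein_pct"] < thresholds$min_protein_pct),
    fat = unname(pred["fat_pct"] < thresholds$min_fat_pct))
  shortfall[is.na(shortfall)] <- FALSE
  flagged <- if (mode == "conjunction") hot && any(shortfall) else
    hot || any(shortfall)
  trigger <- paste(c(if (hot) "thi",
                     names(shortfall)[shortfall]), collapse = ",")
  if (!flagged) {
    return(list(route = "MILKING", state = "NORMAL", trigger = ""))
  }
  if (state == "NORMAL") {
    list(route = "COOLING", state = "STRESSED_DAY1", trigger = trigger)
  } else {
    list(route = "COOLING_AND_MILK", state = "STRESSED_PERSISTENT",
         trigger = trigger)
  }
}

#' Run the drafting simulation over a weather horizon
#'
#' Builds the model's feature rows for every cow-day, predicts the four
#' targets, and replays the drafting state machine chronologically,
#' producing one decision per cow per day.
#'
#' @param model a fitted `milk_model`.
#' @param cow_days management records (targets not required) covering
#'   the horizon; one row per cow per day.
#' @param derived_weather daily weather carrying `thi9` and the derived
#'   columns, covering every date in `cow_days`.
#' @param thresholds a [drafting_thresholds()] object.
#' @param mode passed to [assess_cow()].
#' @return an object of class `decision_log`: data frame with `cow_id`,
#'   `date`, `route`, `state`, `trigger` and the four predicted
#'   targets.
#' @export
run_drafting_sim <- function(model, cow_days, derived_weather,
                             thresholds = drafting_thresholds(),
                             mode = c("conjunction", "disjunction")) {
  mode <- match.arg(mode)
  missing_dates <- setdiff(as.character(unique(cow_days$date)),
                           as.character(derived_weather$date))
  if (length(missing_dates)) {
    stop(sprintf("run_drafting_sim: weather gap on %s",
                 paste(utils::head(missing_dates, 5), collapse = ", ")),
         call. = FALSE)
  }
  fm <- assemble_features(derived_weather, cow_days)
  pred <- predict_targets(model, fm)
  ord <- order(fm$keys$date, fm$keys$cow_id)
  keys <- fm$keys[ord, , drop = FALSE]
  pred <- pred[ord, , drop = FALSE]
  thi9 <- derived_weather$thi9[match(as.character(keys$date),
                                     as.character(derived_weather$date))]
  states <- stats::setNames(rep("NORMAL", length(unique(keys$cow_id))),
                            unique(keys$cow_id))
  n <- nrow(keys)
  route <- character(n)
  state_out <- character(n)
  trigger <- character(n)
  for (i in seq_len(n)) {
    cow <- keys$cow_id[i]
    d <- assess_cow(pred[i, ], thi9[i], states[[cow]], thresholds, mode)
    route[i] <- d$route
    state_out[i] <- d$state
    trigger[i] <- d$trigger
    states[[cow]] <- d$state
  }
  structure(cbind(keys,
                  data.frame(route = route, state = state_out,
                             trigger = trigger),
                  as.data.frame(pred)),
            class = c("decision_log", "data.frame"))
}

#' Audit a decision log for illegal state transitions
#'
#' Replays each cow's chronological state sequence through the legal
#' transition table (`NORMAL -> {NORMAL, STRESSED_DAY1}`,
#' `STRESSED_DAY1 -> {NORMAL, STRESSED_PERSISTENT}`,
#' `STRESSED_PERSISTENT -> {NORMAL, STRESSED_PERSISTENT}`) and checks
#' that `COOLING_AND_MILK` is only ever issued on entry to or while in
#' `STRESSED_PERSISTENT`.
#'
#' @param log a `decision_log`.
#' @return number of violations (0 for a legal log).
#' @export
audit_decision_log <- function(log) {
  legal <- list(NORMAL = c("NORMAL", "STRESSED_DAY1"),
                STRESSED_DAY1 = c("NORMAL", "STRESSED_PERSISTENT"),
                STRESSED_PERSISTENT = c("NORMAL", "STRESSED_PERSISTENT"))
  violations <- 0L
  for (cow in unique(log$cow_id)) {
    rows <- log[log$cow_id == cow, , drop = FALSE]
    rows <- rows[order(rows$date), , drop = FALSE]
    prev <- "NORMAL"
    for (i in seq_len(nrow(rows))) {
      if (!(rows$state[i] %in% legal[[prev]])) violations <- violations + 1L
      if (rows$route[i] == "COOLING_AND_MILK" &&
          rows$state[i] != "STRESSED_PERSISTENT") {
        violations <- violations + 1L
      }
      prev <- rows$state[i]
    }
  }
  violations
}
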