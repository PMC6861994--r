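#' Build the default weight-loss goal schedule
#'
#' The program goal is 7% of baseline body weight over 12 weeks, split into
#' 3.0%, 2.5% and 1.5% targets over three 4-week periods. Each period's kg
#' target is its percentage of the baseline weight.
#'
#' @param baseline_weight Baseline body weight, kg (> 0).
#' @param pct_splits Per-period targets as percent of baseline; default
#'   `c(3.0, 2.5, 1.5)`.
#' @param weeks_per_period Length of each period in weeks; default 4.
#' @return A tibble (class `enbal_schedule`) with columns `period`, `weeks`,
#'   `pct_target` and `kg_target`, carrying `baseline_weight` as an
#'   attribute.
#' @export
#' @examples
#' build_goal_schedule(81.3)
build_goal_schedule <- function(baseline_weight,
                                pct_splits = default_config()$prescription$pct_splits,
                                weeks_per_period = default_config()$prescription$weeks_per_period) {
  if (!is.numeric(baseline_weight) || length(baseline_weight) != 1 ||
      !is.finite(baseline_weight) || baseline_weight <= 0) {
    stop("baseline_weight must be a single positive number", call. = FALSE)
  }
  if (any(pct_splits < 0)) stop("pct_splits must be >= 0", call. = FALSE)
  out <- tibble::tibble(
    period = seq_along(pct_splits),
    weeks = as.integer(weeks_per_period),
    pct_target = as.numeric(pct_splits),
    kg_target = pct_splits / 100 * baseline_weight
  )
  attr(out, "baseline_weight") <- baseline_weight
  attr(out, "orig_pct") <- as.numeric(pct_splits)
  class(out) <- c("enbal_schedule", class(out))
  out
}

#' Calorie deficit required for a given weight loss
#'
#' Uses the energy density of body-weight change: a fixed calorie deficit
#' per kg lost (default 7000 kcal/kg; some literature uses 7700).
#'
#' @param kg_to_lose Weight to lose, kg (>= 0); vectorized.
#' @param kcal_per_kg Deficit per kg; default 7000.
#' @return Required deficit in kcal.
#' @export
#' @examples
#' deficit_for_loss(1) # 7000
deficit_for_loss <- function(kg_to_lose,
                             kcal_per_kg = default_config()$prescription$kcal_per_kg) {
  if (any(!is.finite(kg_to_lose)) || any(kg_to_lose < 0)) {
    stop("kg_to_lose must be finite and >= 0", call. = FALSE)
  }
  kcal_per_kg * kg_to_lose
}

#' Prescribe daily calorie intake for one goal period
#'
#' Converts a period's weight-loss target into a daily calorie deficit,
#' splits it between diet and activity per the user's chosen
#' `activity_share`, and subtracts the diet-side deficit from total energy
#' expenditure. Prescribed intake is never allowed below the sex-specific
#' safety floor (1200 kcal/day for women, 1500 for men); when the floor
#' binds, the deficit the diet could not deliver is reported in
#' `unmet_deficit_kcal` rather than silently shifted into activity.
#'
#' @param tee Total energy expenditure, kcal/day (> 0); vectorized.
#' @param period_kg_target Weight to lose this period, kg (>= 0).
#' @param period_days Days in the period (> 0); default 28.
#' @param sex `"female"` or `"male"` (floor selection); vectorized.
#' @param activity_share Fraction of the deficit to meet through added
#'   activity rather than intake restriction, in \[0, 1\]; default 0.
#' @param kcal_per_kg Deficit per kg lost; default 7000.
#' @param floor_female,floor_male Minimum prescribed intake, kcal/day.
#' @return A tibble with columns `daily_intake_kcal`, `daily_deficit_kcal`
#'   (the diet-side deficit actually prescribed), `activity_kcal`,
#'   `floor_applied` and `unmet_deficit_kcal`.
#' @export
#' @examples
#' prescribe_daily(tee = 2497, period_kg_target = 2.439, sex = "male")
prescribe_daily <- function(tee, period_kg_target, period_days = 28L, sex,
                            activity_share = default_config()$prescription$activity_share,
                            kcal_per_kg = default_config()$prescription$kcal_per_kg,
                            floor_female = default_config()$prescription$floor_female,
                            floor_male = default_config()$prescription$floor_male) {
  if (any(!is.finite(tee)) || any(tee <= 0)) {
    stop("tee must be finite and > 0", call. = FALSE)
  }
  if (any(period_days <= 0)) stop("period_days must be > 0", call. = FALSE)
  if (any(activity_share < 0 | activity_share > 1)) {
    stop("activity_share must lie in [0, 1]", call. = FALSE)
  }
  sex <- match_sex(sex)
  total_deficit <- deficit_for_loss(period_kg_target, kcal_per_kg) / period_days
  diet_deficit <- (1 - activity_share) * total_deficit
  activity_kcal <- activity_share * total_deficit
  floor <- ifelse(sex == "female", floor_female, floor_male)
  raw_intake <- tee - diet_deficit
  floor_applied <- raw_intake < floor
  intake <- pmax(raw_intake, floor)
  tibble::tibble(
    daily_intake_kcal = intake,
    daily_deficit_kcal = tee - intake,
    activity_kcal = activity_kcal,
    floor_applied = floor_applied,
    unmet_deficit_kcal = pmax(floor - raw_intake, 0)
  )
}

#' Reset remaining goals from a measured weight
#'
#' At a period boundary the remaining kg targets are recomputed so the
#' program still ends at 93% of baseline: the remaining loss
#' (measured weight minus 0.93 x baseline, clamped at zero when the goal is
#' already exceeded) is redistributed across the remaining periods in
#' proportion to their original percentage splits.
#'
#' @param schedule A goal schedule from [build_goal_schedule()].
#' @param measured_weight Current measured weight, kg (> 0).
#' @param completed_periods Number of periods already completed, in
#'   `[0, nrow(schedule))`.
#' @return The schedule with remaining `kg_target` (and `pct_target`)
#'   updated.
#' @export
#' @examples
#' s <- build_goal_schedule(100)
#' reassess(s, measured_weight = 98, completed_periods = 1)
reassess <- function(schedule, measured_weight, completed_periods) {
  stopifnot(inherits(schedule, "enbal_schedule"))
  if (!is.numeric(measured_weight) || length(measured_weight) != 1 ||
      !is.finite(measured_weight) || measured_weight <= 0) {
    stop("measured_weight must be a single positive number", call. = FALSE)
  }
  n <- nrow(schedule)
  if (completed_periods < 0 || completed_periods >= n) {
    stop("completed_periods must lie in [0, number of periods)", call. = FALSE)
  }
  baseline <- attr(schedule, "baseline_weight")
  orig_pct <- attr(schedule, "orig_pct")
  if (is.null(orig_pct)) orig_pct <- schedule$pct_target
  # endpoint anchored to the original split total (7% by default)
  endpoint <- baseline * (1 - sum(orig_pct) / 100)
  remaining <- seq_len(n) > completed_periods
  w <- orig_pct[remaining]
  to_lose <- max(measured_weight - endpoint, 0)
  if (sum(w) > 0) {
    share <- w / sum(w)
  } else {
    share <- rep(1 / sum(remaining), sum(remaining))
  }
  schedule$kg_target[remaining] <- to_lose * share
  schedule$pct_target[remaining] <- schedule$kg_target[remaining] / baseline * 100
  attr(schedule, "orig_pct") <- orig_pct
  schedule
}

# normalize sex coding to "female"/"male"
match_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("f", "female", "w", "woman")] <- "female"
  s[s %in% c("m", "male", "man")] <- "male"
  if (!all(s %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'", call. = FALSE)
  }
  s
}

#' Prescribe intake for a table of participants
#'
#' Data-frame-first wrapper: builds (or reassesses) each participant's goal
#' schedule and prescribes daily intake for the requested period. Requires
#' columns `weight` (baseline, kg), `sex` and `tee` (use
#' [estimate_energy()] upstream); optional `measured_weight` drives
#' reassessment when `period > 1`.
#'
#' @param data Participant tibble.
#' @param period Goal period to prescribe for (1-based); default 1.
#' @param activity_share,config See [prescribe_daily()] and
#'   [default_config()].
#' @return `data` with the prescription columns and the period's
#'   `kg_target` appended.
#' @export
prescribe_cohort <- function(data, period = 1L,
                             activity_share = NULL,
                             config = default_config()) {
  p <- config$prescription
  if (is.null(activity_share)) activity_share <- p$activity_share
  need <- c("weight", "sex", "tee")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  period_days <- p$weeks_per_period * 7L
  kg_target <- purrr::map_dbl(seq_len(nrow(data)), function(i) {
    s <- build_goal_schedule(data$weight[i], p$pct_splits, p$weeks_per_period)
    if (period > 1 && "measured_weight" %in% names(data)) {
      s <- reassess(s, data$measured_weight[i], completed_periods = period - 1L)
    }
    s$kg_target[period]
  })
  rx <- prescribe_daily(data$tee, kg_target, period_days, data$sex,
                        activity_share, p$kcal_per_kg,
                        p$floor_female, p$floor_male)
  dplyr::bind_cols(tibble::as_tibble(data),
                   tibble::tibble(period = as.integer(period),
                                  kg_target = kg_target),
                   rx)
}
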