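#' Achievement score for the competition leaderboard
#'
#' A score in \[0, 1\] combining three ingredients of program success:
#' * `success` — 1 if current weight is at or below 93% of baseline (the
#'   7% loss target met), else 0;
#' * `proximity` — closeness to the current monthly goal weight,
#'   `clamp(1 - |current - goal| / (baseline - goal), 0, 1)`;
#' * `adherence` — logging engagement, `max(diet days, tracker days) /
#'   period days` (either channel counts).
#'
#' The three are combined additively with non-negative weights summing
#' to 1 (equal thirds by default).
#'
#' @param data Tibble with columns `baseline_weight`, `current_weight`,
#'   `monthly_goal_weight` (kg, all > 0, goal < baseline), `diet_log_days`,
#'   `tracker_days` and `period_days` (day counts, logs within
#'   `[0, period_days]`).
#' @param weights Numeric length-3 vector `(success, proximity, adherence)`,
#'   non-negative, summing to 1.
#' @param loss_success_pct Percent loss counted as success; default 7.
#' @return `data` with `success`, `proximity`, `adherence` and `score`
#'   columns appended.
#' @export
#' @examples
#' tibble::tibble(
#'   baseline_weight = 100, current_weight = 93, monthly_goal_weight = 97,
#'   diet_log_days = 28, tracker_days = 0, period_days = 28
#' ) |> achievement_score()
achievement_score <- function(data,
                              weights = c(1, 1, 1) / 3,
                              loss_success_pct = default_config()$scoring$loss_success_pct) {
  if (length(weights) != 3 || any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be 3 non-negative values summing to 1", call. = FALSE)
  }
  need <- c("baseline_weight", "current_weight", "monthly_goal_weight",
            "diet_log_days", "tracker_days", "period_days")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- tibble::as_tibble(data)
  if (any(d$baseline_weight <= 0 | d$current_weight <= 0 |
            d$monthly_goal_weight <= 0)) {
    stop("weights (kg) must be > 0", call. = FALSE)
  }
  if (any(d$monthly_goal_weight >= d$baseline_weight)) {
    stop("monthly_goal_weight must be below baseline_weight", call. = FALSE)
  }
  bad_days <- d$diet_log_days < 0 | d$diet_log_days > d$period_days |
    d$tracker_days < 0 | d$tracker_days > d$period_days
  if (any(bad_days)) {
    stop("log day counts must lie in [0, period_days]", call. = FALSE)
  }
  d$success <- as.numeric(
    d$current_weight <= (1 - loss_success_pct / 100) * d$baseline_weight
  )
  d$proximity <- pmin(pmax(
    1 - abs(d$current_weight - d$monthly_goal_weight) /
      (d$baseline_weight - d$monthly_goal_weight), 0), 1)
  d$adherence <- pmax(d$diet_log_days, d$tracker_days) / d$period_days
  d$score <- weights[1] * d$success + weights[2] * d$proximity +
    weights[3] * d$adherence
  d
}

#' Rank a leaderboard with competition ("1224") tie handling
#'
#' Orders descending by value; tied values share the best rank and the next
#' distinct value takes the rank it would have with all ties counted
#' (10, 10, 5 ranks as 1, 1, 3).
#'
#' @param data Tibble with an id column and a value column.
#' @param value Column to rank by (tidy-eval); e.g. `score` or `steps`.
#' @return `data` sorted descending by `value` with a dense-competition
#'   `rank` column appended.
#' @export
#' @examples
#' rank_leaderboard(tibble::tibble(id = 1:3, steps = c(10, 10, 5)), steps)
rank_leaderboard <- function(data, value) {
  d <- tibble::as_tibble(data)
  if (nrow(d) == 0) return(dplyr::mutate(d, rank = integer()))
  v <- dplyr::pull(d, {{ value }})
  d$rank <- dplyr::min_rank(dplyr::desc(v))
  dplyr::arrange(d, .data$rank)
}

#' Health age (not implemented)
#'
#' Placeholder for a health-risk-appraisal "health age" readout. The
#' underlying appraisal formula is not part of this package's model and no
#' implementation is provided.
#'
#' @param ... Ignored.
#' @export
health_age <- function(...) {
  stop("health_age is not implemented: the health-risk-appraisal formula ",
       "is out of scope for this package", call. = FALSE)
}
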