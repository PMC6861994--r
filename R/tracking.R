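#' Construct a food table
#'
#' A food database is a plain tibble with columns `id`, `name`,
#' `kcal_per_serving`, `serving_desc` and `source`. Sources reflect how the
#' item got into the database: `cafeteria`, `nearby` and `frequent` items
#' are pre-entered (workplace cafeteria menu, nearby restaurants, frequently
#' logged items), `user` items were typed in by a user, and `database`
#' items come from the bundled nutrition table.
#'
#' @param id,name,kcal_per_serving,serving_desc,source Vectors of equal
#'   length; kcal must be >= 0 and names non-empty.
#' @return A validated food tibble.
#' @export
food_table <- function(id, name, kcal_per_serving,
                       serving_desc = "1 serving", source = "database") {
  db <- tibble::tibble(
    id = as.character(id), name = as.character(name),
    kcal_per_serving = as.numeric(kcal_per_serving),
    serving_desc = serving_desc, source = as.character(source)
  )
  validate_food_table(db)
  db
}

food_sources <- c("cafeteria", "nearby", "frequent", "user", "database")

validate_food_table <- function(db) {
  need <- c("id", "name", "kcal_per_serving", "serving_desc", "source")
  miss <- setdiff(need, names(db))
  if (length(miss) > 0) {
    stop("food table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(db$kcal_per_serving < 0)) {
    stop("kcal_per_serving must be >= 0", call. = FALSE)
  }
  if (any(!nzchar(db$name))) stop("food names must be non-empty", call. = FALSE)
  if (any(duplicated(db$id))) stop("food ids must be unique", call. = FALSE)
  if (!all(db$source %in% food_sources)) {
    stop("source must be one of: ", paste(food_sources, collapse = ", "),
         call. = FALSE)
  }
  invisible(db)
}

#' Read a food database from CSV
#'
#' Expected header: `id,name,kcal_per_serving,serving_desc,source`.
#'
#' @param path CSV file path.
#' @return A validated food tibble.
#' @export
read_food_table <- function(path) {
  db <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          id = readr::col_character(),
                          name = readr::col_character(),
                          kcal_per_serving = readr::col_double(),
                          serving_desc = readr::col_character(),
                          source = readr::col_character()
                        ))
  validate_food_table(db)
  db
}

#' Search the food database
#'
#' Case-insensitive substring match on the food name. Pre-entered items
#' (cafeteria, nearby restaurants, frequently used) rank above user-entered
#' items, which rank above the bulk nutrition database; ties break
#' alphabetically by name, so results are deterministic.
#'
#' @param db A food tibble (see [food_table()]).
#' @param query Non-empty search string.
#' @return The matching rows, ranked.
#' @export
#' @examples
#' db <- food_table(1:2, c("fried rice", "rice cake"), c(520, 210))
#' search_food(db, "rice")
search_food <- function(db, query) {
  validate_food_table(db)
  if (!is.character(query) || length(query) != 1 || !nzchar(trimws(query))) {
    stop("query must be a non-empty string", call. = FALSE)
  }
  src_rank <- c(cafeteria = 1, nearby = 1, frequent = 1, user = 2, database = 3)
  db |>
    dplyr::filter(grepl(query, .data$name, fixed = FALSE, ignore.case = TRUE)) |>
    dplyr::arrange(src_rank[.data$source], .data$name)
}

#' Calories burned by a manually logged activity
#'
#' Standard compendium convention: 1 MET is approximately 1 kcal per kg of
#' body weight per hour, so kcal = MET x weight(kg) x minutes / 60.
#'
#' @param met Activity intensity in METs (>= 1; below 1 would be less than
#'   resting).
#' @param duration_min Duration in minutes (>= 0).
#' @param weight Body weight, kg (> 0).
#' @return kcal expended; vectorized.
#' @export
#' @examples
#' manual_activity_kcal(8, 30, 80) # 320
manual_activity_kcal <- function(met, duration_min, weight) {
  if (any(met < 1)) stop("met must be >= 1", call. = FALSE)
  if (any(duration_min < 0)) stop("duration_min must be >= 0", call. = FALSE)
  if (any(weight <= 0)) stop("weight must be > 0", call. = FALSE)
  met * weight * duration_min / 60
}

#' Daily energy balance against the prescribed goal
#'
#' Sums the day's diet entries (portions x kcal per serving, looked up in
#' the food table) and activity entries (manual MET entries converted via
#' [manual_activity_kcal()], tracker entries taken at their reported kcal),
#' then compares intake with the prescribed goal. Status is `on_goal` when
#' intake is within `tolerance_kcal` of the goal, `under_goal` below,
#' `over_goal` above.
#'
#' @param diet Tibble of diet entries: `date`, `food_id`, `portions` (> 0).
#'   May be `NULL`/empty.
#' @param activity Tibble of activity entries: `date`, `kind` (`"manual"`
#'   or `"tracker"`), and `met`+`duration_min` (manual) or `kcal`
#'   (tracker). May be `NULL`/empty.
#' @param db Food tibble for lookups (required when `diet` is non-empty).
#' @param tee Total energy expenditure, kcal/day.
#' @param goal Prescribed intake, kcal/day.
#' @param weight Body weight, kg, for manual MET conversion.
#' @param tolerance_kcal Half-width of the on-goal band; default 50.
#' @param add_logged_exercise Add logged exercise kcal on top of `tee`
#'   (default). Set `FALSE` when the TEE estimate already includes the
#'   logged exercise, to avoid double counting.
#' @return One-row tibble: `date`, `intake_kcal`, `expended_kcal`,
#'   `net_kcal` (intake minus expended), `goal_kcal`, `status`.
#' @export
daily_balance <- function(diet = NULL, activity = NULL, db = NULL,
                          tee, goal, weight = NULL,
                          tolerance_kcal = default_config()$tracking$goal_tolerance_kcal,
                          add_logged_exercise = default_config()$tracking$add_logged_exercise) {
  dates <- c(
    if (!is.null(diet) && nrow(diet) > 0) as.character(diet$date),
    if (!is.null(activity) && nrow(activity) > 0) as.character(activity$date)
  )
  date <- if (length(dates) > 0) unique(dates) else NA_character_
  if (length(date) > 1) {
    stop("entries span multiple dates; pass one day at a time", call. = FALSE)
  }
  intake <- 0
  if (!is.null(diet) && nrow(diet) > 0) {
    if (is.null(db)) stop("db is required to price diet entries", call. = FALSE)
    validate_food_table(db)
    if (any(diet$portions <= 0)) stop("portions must be > 0", call. = FALSE)
    idx <- match(as.character(diet$food_id), db$id)
    if (anyNA(idx)) {
      stop("unknown food_id: ",
           paste(unique(diet$food_id[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    intake <- sum(diet$portions * db$kcal_per_serving[idx])
  }
  exercise <- 0
  if (!is.null(activity) && nrow(activity) > 0) {
    kc <- purrr::map_dbl(seq_len(nrow(activity)), function(i) {
      if (activity$kind[i] == "manual") {
        if (is.null(weight)) {
          stop("weight is required for manual activity entries", call. = FALSE)
        }
        manual_activity_kcal(activity$met[i], activity$duration_min[i], weight)
      } else if (activity$kind[i] == "tracker") {
        k <- activity$kcal[i]
        if (is.na(k) || k < 0) stop("tracker kcal must be >= 0", call. = FALSE)
        k
      } else {
        stop("activity kind must be 'manual' or 'tracker'", call. = FALSE)
      }
    })
    exercise <- sum(kc)
  }
  expended <- if (add_logged_exercise) tee + exercise else tee
  status <- dplyr::case_when(
    abs(intake - goal) <= tolerance_kcal ~ "on_goal",
    intake < goal ~ "under_goal",
    TRUE ~ "over_goal"
  )
  tibble::tibble(
    date = date, intake_kcal = intake, expended_kcal = expended,
    net_kcal = intake - expended, goal_kcal = goal, status = status
  )
}

#' Daily balances over a log spanning many days
#'
#' Splits diet and activity logs by date and applies [daily_balance()] to
#' each day.
#'
#' @inheritParams daily_balance
#' @param dates Optional vector of dates to report on; defaults to all
#'   dates present in either log.
#' @return A tibble with one [daily_balance()] row per date.
#' @export
balance_history <- function(diet = NULL, activity = NULL, db = NULL,
                            tee, goal, weight = NULL, dates = NULL,
                            tolerance_kcal = default_config()$tracking$goal_tolerance_kcal,
                            add_logged_exercise = default_config()$tracking$add_logged_exercise) {
  if (is.null(dates)) {
    dates <- sort(unique(c(
      if (!is.null(diet)) as.character(diet$date),
      if (!is.null(activity)) as.character(activity$date)
    )))
  }
  purrr::map_dfr(dates, function(d) {
    di <- if (!is.null(diet)) diet[as.character(diet$date) == d, , drop = FALSE]
    ac <- if (!is.null(activity)) {
      activity[as.character(activity$date) == d, , drop = FALSE]
    }
    daily_balance(di, ac, db, tee, goal, weight, tolerance_kcal,
                  add_logged_exercise)
  })
}

#' Weekly summary of daily balance reports
#'
#' Aggregates daily balance rows by ISO week: total and mean intake,
#' expenditure and net balance, days logged and days on goal.
#'
#' @param reports Tibble of daily balance rows (see [daily_balance()]);
#'   `date` must be parseable by [as.Date()].
#' @return One row per ISO week (`iso_year`, `iso_week`), or an empty
#'   tibble for empty input.
#' @export
history_summary <- function(reports) {
  if (is.null(reports) || nrow(reports) == 0) {
    return(tibble::tibble(
      iso_year = integer(), iso_week = integer(), days = integer(),
      intake_total = numeric(), intake_mean = numeric(),
      expended_total = numeric(), net_total = numeric(),
      net_mean = numeric(), days_on_goal = integer()
    ))
  }
  d <- as.Date(reports$date)
  reports |>
    dplyr::mutate(
      iso_year = as.integer(format(d, "%G")),
      iso_week = as.integer(format(d, "%V"))
    ) |>
    dplyr::group_by(.data$iso_year, .data$iso_week) |>
    dplyr::summarise(
      days = dplyr::n(),
      intake_total = sum(.data$intake_kcal),
      intake_mean = mean(.data$intake_kcal),
      expended_total = sum(.data$expended_kcal),
      net_total = sum(.data$net_kcal),
      net_mean = mean(.data$net_kcal),
      days_on_goal = sum(.data$status == "on_goal"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$iso_year, .data$iso_week)
}
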