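#' Resting metabolic rate from fat-free mass (Cunningham equation)
#'
#' RMR (kcal/day) = intercept + slope x FFM (kg). The fat-free-mass form is
#' preferred over weight-based predictors (Harris-Benedict, Mifflin) for
#' obese adults because it is insensitive to fat mass, which contributes
#' little to resting expenditure.
#'
#' @param fat_free_mass Fat-free (lean body) mass in kg; vectorized.
#' @param intercept,slope Regression constants; defaults 500 and 22
#'   (kcal/day and kcal/day/kg).
#' @return RMR in kcal/day.
#' @export
#' @examples
#' rmr_cunningham(55.4) # 1718.8
rmr_cunningham <- function(fat_free_mass,
                           intercept = default_config()$energy$cunningham_intercept,
                           slope = default_config()$energy$cunningham_slope) {
  if (any(!is.finite(fat_free_mass)) || any(fat_free_mass < 0)) {
    stop("fat_free_mass must be finite and >= 0", call. = FALSE)
  }
  intercept + slope * fat_free_mass
}

#' Weekly MET-minutes from an IPAQ-SF response
#'
#' Scores the short-form questionnaire per the IPAQ scoring protocol:
#' weekly MET-minutes = sum over domains of MET x minutes/day x days/week,
#' with each domain's minutes/day truncated at `truncate_min` (protocol
#' default 180; set `Inf` to disable). Walking bouts shorter than 10 minutes
#' are excluded from the instrument by convention and must not be entered.
#'
#' @param walking_days,walking_min,moderate_days,moderate_min,vigorous_days,vigorous_min
#'   Days/week (0-7) and minutes/day (>= 0) per activity domain; vectorized.
#' @param met_walking,met_moderate,met_vigorous MET intensities; protocol
#'   defaults 3.3 / 4.0 / 8.0.
#' @param truncate_min Per-domain minutes/day cap.
#' @return Weekly MET-minutes (MET-min/week).
#' @export
ipaq_met_minutes <- function(walking_days = 0, walking_min = 0,
                             moderate_days = 0, moderate_min = 0,
                             vigorous_days = 0, vigorous_min = 0,
                             met_walking = default_config()$energy$met_walking,
                             met_moderate = default_config()$energy$met_moderate,
                             met_vigorous = default_config()$energy$met_vigorous,
                             truncate_min = default_config()$energy$ipaq_truncate_min) {
  days <- list(walking_days, moderate_days, vigorous_days)
  mins <- list(walking_min, moderate_min, vigorous_min)
  for (d in days) {
    if (any(d < 0 | d > 7)) stop("days/week must lie in [0, 7]", call. = FALSE)
  }
  for (m in mins) {
    if (any(m < 0)) stop("minutes/day must be >= 0", call. = FALSE)
  }
  cap <- function(m) pmin(m, truncate_min)
  met_walking * cap(walking_min) * walking_days +
    met_moderate * cap(moderate_min) * moderate_days +
    met_vigorous * cap(vigorous_min) * vigorous_days
}

#' Activity energy expenditure from an IPAQ-SF response
#'
#' Converts weekly MET-minutes to a daily calorie figure using the IPAQ
#' convention kcal = MET-min x weight(kg) / 60, averaged over 7 days. This
#' is the questionnaire-measured component of activity expenditure; see
#' [daily_activity_component()] for the unmeasured daily-living remainder.
#'
#' @inheritParams ipaq_met_minutes
#' @param weight Body weight in kg (> 0); vectorized.
#' @return Activity expenditure in kcal/day.
#' @export
#' @examples
#' tea_from_ipaq(80, walking_days = 5, walking_min = 30) # 94.29 kcal/day
tea_from_ipaq <- function(weight,
                          walking_days = 0, walking_min = 0,
                          moderate_days = 0, moderate_min = 0,
                          vigorous_days = 0, vigorous_min = 0,
                          met_walking = default_config()$energy$met_walking,
                          met_moderate = default_config()$energy$met_moderate,
                          met_vigorous = default_config()$energy$met_vigorous,
                          truncate_min = default_config()$energy$ipaq_truncate_min) {
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("weight must be finite and > 0", call. = FALSE)
  }
  mm <- ipaq_met_minutes(walking_days, walking_min, moderate_days, moderate_min,
                         vigorous_days, vigorous_min,
                         met_walking, met_moderate, met_vigorous, truncate_min)
  mm * weight / 60 / 7
}

#' Daily-living activity expenditure not captured by the questionnaire
#'
#' Short walking bouts, showering, talking and other incidental activity are
#' not covered by the IPAQ-SF; on the premise that the target population is
#' sedentary, this component is estimated as a fixed fraction (default 10%)
#' of RMR.
#'
#' @param rmr Resting metabolic rate in kcal/day (>= 0); vectorized.
#' @param fraction Fraction of RMR; default 0.10.
#' @return kcal/day.
#' @export
daily_activity_component <- function(rmr,
                                     fraction = default_config()$energy$daily_activity_fraction) {
  if (any(rmr < 0)) stop("rmr must be >= 0", call. = FALSE)
  fraction * rmr
}

#' Thermic effect of food
#'
#' Energy cost of digestion and absorption, taken as a fixed fraction
#' (default 10%) of RMR plus activity expenditure.
#'
#' @param rmr Resting metabolic rate in kcal/day (>= 0).
#' @param tea_total Total activity expenditure in kcal/day (>= 0); pass the
#'   questionnaire component alone to base TEF on measured activity only.
#' @param fraction Fraction applied; default 0.10.
#' @return kcal/day.
#' @export
tef_component <- function(rmr, tea_total,
                          fraction = default_config()$energy$tef_fraction) {
  if (any(rmr < 0)) stop("rmr must be >= 0", call. = FALSE)
  if (any(tea_total < 0)) stop("tea_total must be >= 0", call. = FALSE)
  fraction * (rmr + tea_total)
}

#' Total energy expenditure
#'
#' TEE = RMR + TEA(questionnaire) + TEA(daily living) + TEF, composed from
#' [rmr_cunningham()], [tea_from_ipaq()], [daily_activity_component()] and
#' [tef_component()]. With no reported activity the closed form is
#' TEE = 1.21 x RMR.
#'
#' @param weight Body weight, kg (> 0).
#' @param fat_free_mass Fat-free mass, kg (>= 0, <= weight).
#' @inheritParams ipaq_met_minutes
#' @param tef_base `"total"` (default) bases TEF on RMR plus both activity
#'   components; `"ipaq_only"` excludes the daily-living component from the
#'   TEF base.
#' @param config Optional config list (see [default_config()]); supplies the
#'   model constants.
#' @return A tibble with columns `rmr`, `tea_ipaq`, `tea_daily`, `tef`,
#'   `tee`, all kcal/day, one row per input element.
#' @export
#' @examples
#' total_energy_expenditure(80, 50, walking_days = 5, walking_min = 30)
total_energy_expenditure <- function(weight, fat_free_mass,
                                     walking_days = 0, walking_min = 0,
                                     moderate_days = 0, moderate_min = 0,
                                     vigorous_days = 0, vigorous_min = 0,
                                     tef_base = NULL,
                                     config = default_config()) {
  e <- config$energy
  if (is.null(tef_base)) tef_base <- e$tef_base
  tef_base <- match.arg(tef_base, c("total", "ipaq_only"))
  if (any(fat_free_mass > weight)) {
    stop("fat_free_mass cannot exceed weight", call. = FALSE)
  }
  rmr <- rmr_cunningham(fat_free_mass, e$cunningham_intercept, e$cunningham_slope)
  tea1 <- tea_from_ipaq(weight, walking_days, walking_min,
                        moderate_days, moderate_min,
                        vigorous_days, vigorous_min,
                        e$met_walking, e$met_moderate, e$met_vigorous,
                        e$ipaq_truncate_min)
  tea2 <- daily_activity_component(rmr, e$daily_activity_fraction)
  tef_in <- if (tef_base == "total") tea1 + tea2 else tea1
  tef <- tef_component(rmr, tef_in, e$tef_fraction)
  tibble::tibble(
    rmr = rmr, tea_ipaq = tea1, tea_daily = tea2, tef = tef,
    tee = rmr + tea1 + tea2 + tef
  )
}

#' Add energy-expenditure columns to a participant table
#'
#' Data-frame-first wrapper around [total_energy_expenditure()]. Requires
#' `weight` and `fat_free_mass` columns; IPAQ columns (`walking_days`,
#' `walking_min`, `moderate_days`, `moderate_min`, `vigorous_days`,
#' `vigorous_min`) are used when present and taken as zero otherwise.
#'
#' @param data A data frame of participants.
#' @inheritParams total_energy_expenditure
#' @return `data` as a tibble with `rmr`, `tea_ipaq`, `tea_daily`, `tef`
#'   and `tee` columns appended.
#' @export
#' @examples
#' tibble::tibble(weight = 81.3, fat_free_mass = 55.4) |> estimate_energy()
estimate_energy <- function(data, tef_base = NULL, config = default_config()) {
  need <- c("weight", "fat_free_mass")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  col <- function(nm) if (nm %in% names(data)) data[[nm]] else 0
  eb <- total_energy_expenditure(
    weight = data$weight, fat_free_mass = data$fat_free_mass,
    walking_days = col("walking_days"), walking_min = col("walking_min"),
    moderate_days = col("moderate_days"), moderate_min = col("moderate_min"),
    vigorous_days = col("vigorous_days"), vigorous_min = col("vigorous_min"),
    tef_base = tef_base, config = config
  )
  dplyr::bind_cols(tibble::as_tibble(data), eb)
}
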