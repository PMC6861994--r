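#' Default model configuration
#'
#' All numeric constants used across the package, grouped by stage. Every
#' user-facing function exposes the constants it needs as arguments whose
#' defaults come from this list, so a config file can drive a whole pipeline
#' run while interactive use stays ergonomic.
#'
#' Key constants and their provenance (see the methods vignette for
#' discussion):
#' * `energy$cunningham_intercept`, `energy$cunningham_slope`: RMR =
#'   500 + 22 x FFM(kg), the classic fat-free-mass regression.
#' * `energy$met_*`: IPAQ-SF scoring-protocol MET values (walking 3.3,
#'   moderate 4.0, vigorous 8.0).
#' * `prescription$kcal_per_kg`: 7000 kcal of deficit per kg of weight lost.
#' * `prescription$pct_splits`: 3.0/2.5/1.5% of baseline weight per 4-week
#'   period (7% over 12 weeks).
#' * `prescription$floor_female` / `floor_male`: 1200 / 1500 kcal/day
#'   minimum prescribed intake.
#' * `adiposity$hu_window`: adipose attenuation window, -250 to -50 HU,
#'   inclusive at both ends.
#'
#' @return A named nested list of constants.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$prescription$kcal_per_kg
default_config <- function() {
  list(
    energy = list(
      cunningham_intercept = 500,
      cunningham_slope = 22,
      met_walking = 3.3,
      met_moderate = 4.0,
      met_vigorous = 8.0,
      ipaq_truncate_min = 180,
      daily_activity_fraction = 0.10,
      tef_fraction = 0.10,
      tef_base = "total"
    ),
    prescription = list(
      pct_splits = c(3.0, 2.5, 1.5),
      weeks_per_period = 4,
      kcal_per_kg = 7000,
      floor_female = 1200,
      floor_male = 1500,
      activity_share = 0
    ),
    tracking = list(
      goal_tolerance_kcal = 50,
      add_logged_exercise = TRUE
    ),
    scoring = list(
      weight_success = 1 / 3,
      weight_proximity = 1 / 3,
      weight_adherence = 1 / 3,
      loss_success_pct = 7.0
    ),
    adiposity = list(
      hu_window = c(-250, -50),
      vat_obesity_cm2 = 100
    ),
    simulate = list(
      n = 30,
      weeks = 12,
      adherence_mean = 0.83,
      adherence_sd = 0.20,
      weight_noise_sd = 0.3,
      reassess = TRUE
    ),
    analysis = list(
      exact_n = 25,
      continuity = TRUE,
      quantile_type = 7
    )
  )
}

#' Load a configuration file
#'
#' Reads a YAML (or JSON) config and merges it over [default_config()].
#' Unknown keys are rejected rather than silently ignored, so typos in a
#' config file fail loudly.
#'
#' @param path Path to a YAML or JSON file; sections and keys must be a
#'   subset of those in [default_config()].
#' @return The merged, validated config list.
#' @export
load_config <- function(path) {
  stopifnot(is.character(path), length(path) == 1, file.exists(path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_config(default_config(), raw)
}

#' Validate a configuration list
#'
#' @param config A config list shaped like [default_config()].
#' @return `config`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_config <- function(config) {
  merge_config(default_config(), config)
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  e <- merge_config(default_config(), config)
  chk(e$energy$cunningham_slope > 0, "energy$cunningham_slope must be > 0")
  chk(all(c(e$energy$met_walking, e$energy$met_moderate, e$energy$met_vigorous) >= 1),
      "MET values must be >= 1")
  chk(e$energy$tef_base %in% c("total", "ipaq_only"), "energy$tef_base")
  chk(all(e$prescription$pct_splits >= 0), "prescription$pct_splits must be >= 0")
  chk(e$prescription$kcal_per_kg > 0, "prescription$kcal_per_kg must be > 0")
  chk(e$prescription$floor_female > 0 && e$prescription$floor_male > 0,
      "intake floors must be > 0")
  s <- e$scoring
  chk(abs(s$weight_success + s$weight_proximity + s$weight_adherence - 1) < 1e-8,
      "scoring weights must sum to 1")
  chk(e$adiposity$hu_window[1] <= e$adiposity$hu_window[2], "adiposity$hu_window")
  chk(e$simulate$n >= 1, "simulate$n must be >= 1")
  chk(e$simulate$adherence_mean >= 0 && e$simulate$adherence_mean <= 1.5,
      "simulate$adherence_mean must lie in [0, 1.5]")
  chk(e$simulate$adherence_sd >= 0 && e$simulate$weight_noise_sd >= 0,
      "simulation sds must be >= 0")
  invisible(e)
}

# recursive merge of `over` onto `base`; unknown keys in `over` are an error
merge_config <- function(base, over, path = character()) {
  if (is.null(over)) return(base)
  if (!is.list(base)) return(over)
  if (!is.list(over)) {
    stop("invalid config: expected a section at ",
         paste(path, collapse = "$"), call. = FALSE)
  }
  extra <- setdiff(names(over), names(base))
  if (length(extra) > 0) {
    stop("invalid config: unknown key(s): ",
         paste(c(paste(path, collapse = "$"), extra[1]), collapse = "$"),
         call. = FALSE)
  }
  for (nm in names(over)) {
    base[[nm]] <- merge_config(base[[nm]], over[[nm]], c(path, nm))
  }
  base
}
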