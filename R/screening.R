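#' Screen participants for program eligibility
#'
#' Applies the inclusion rule (BMI >= 25 kg/m2) and eight exclusion rules to
#' each row of a profile table. Threshold rules are inclusive as stated
#' (SBP >= 160 mmHg, DBP >= 100 mmHg, fasting glucose >= 160 mg/dl,
#' triglyceride >= 500 mg/dl, LDL-C >= 190 mg/dl); recent drastic weight
#' change is strict (more than 10% in a month, either direction). The
#' questionnaire- and lab-triggered rules (PAR-Q, eating-disorder survey,
#' abnormal labs/BP) model the study's clinician judgement: they fire only
#' when `counseling_cleared` is `FALSE`, since the printed criteria excluded
#' people "judged ineligible after counseling".
#'
#' Required columns: `bmi`, `sbp`, `dbp`, `fbs`, `triglyceride`, `ldl`,
#' `parq_any_yes`, `eating_disorder_flag`, `obesity_treatment_within_month`,
#' `weight_change_pct_month`, `severe_illness_flag`, `thyroid_disease`,
#' `counseling_cleared`, `investigator_veto`. Missing columns or NA values
#' in them are an error (safety-first: absent labs are never treated as a
#' pass).
#'
#' @param profiles Data frame, one row per candidate.
#' @return `profiles` as a tibble with `eligible` (logical) and `reasons`
#'   (comma-separated rule codes, `""` when eligible) appended.
#' @export
#' @examples
#' p <- tibble::tibble(
#'   bmi = 27, sbp = 120, dbp = 80, fbs = 90, triglyceride = 150, ldl = 120,
#'   parq_any_yes = FALSE, eating_disorder_flag = FALSE,
#'   obesity_treatment_within_month = FALSE, weight_change_pct_month = 0,
#'   severe_illness_flag = FALSE, thyroid_disease = FALSE,
#'   counseling_cleared = FALSE, investigator_veto = FALSE
#' )
#' screen(p)
screen <- function(profiles) {
  need <- c("bmi", "sbp", "dbp", "fbs", "triglyceride", "ldl",
            "parq_any_yes", "eating_disorder_flag",
            "obesity_treatment_within_month", "weight_change_pct_month",
            "severe_illness_flag", "thyroid_disease",
            "counseling_cleared", "investigator_veto")
  miss <- setdiff(need, names(profiles))
  if (length(miss) > 0) {
    stop("missing required field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (nm in need) {
    if (anyNA(profiles[[nm]])) {
      stop("missing value in required field: ", nm, call. = FALSE)
    }
  }
  num <- c("bmi", "sbp", "dbp", "fbs", "triglyceride", "ldl")
  for (nm in num) {
    if (any(profiles[[nm]] < 0)) {
      stop("physiologic field must be >= 0: ", nm, call. = FALSE)
    }
  }
  p <- tibble::as_tibble(profiles)
  cleared <- p$counseling_cleared
  rules <- list(
    bmi_below_25 = p$bmi < 25,
    parq_positive = p$parq_any_yes & !cleared,
    eating_disorder = p$eating_disorder_flag & !cleared,
    sbp_ge_160 = p$sbp >= 160 & !cleared,
    dbp_ge_100 = p$dbp >= 100 & !cleared,
    fbs_ge_160 = p$fbs >= 160 & !cleared,
    tg_ge_500 = p$triglyceride >= 500 & !cleared,
    ldl_ge_190 = p$ldl >= 190 & !cleared,
    recent_obesity_treatment = p$obesity_treatment_within_month,
    weight_change_gt_10pct = abs(p$weight_change_pct_month) > 10,
    severe_illness = p$severe_illness_flag,
    thyroid_disease = p$thyroid_disease,
    investigator_veto = p$investigator_veto
  )
  fired <- do.call(cbind, rules)
  reasons <- apply(fired, 1, function(r) paste(names(rules)[r], collapse = ","))
  p$eligible <- !apply(fired, 1, any)
  p$reasons <- reasons
  p
}
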