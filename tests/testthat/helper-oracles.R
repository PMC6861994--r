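# Independent oracles used across tests.

# Two-sided Wilcoxon signed-rank p by full 2^n sign enumeration
# (zeros dropped, midranks). Only for small n.
wsr_brute_p <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 14)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- as.numeric(signs %*% r)
  lo <- mean(sums <= v + 1e-9)
  hi <- mean(sums >= v - 1e-9)
  min(2 * min(lo, hi), 1)
}

# Per-pixel loop count of adipose pixels inside/outside the visceral mask.
fat_areas_loop <- function(slice, lo = -250, hi = -50) {
  n_vat <- 0L
  n_sat <- 0L
  for (i in seq_len(nrow(slice$hu))) {
    for (j in seq_len(ncol(slice$hu))) {
      h <- slice$hu[i, j]
      if (h >= lo && h <= hi) {
        if (slice$visceral_mask[i, j]) n_vat <- n_vat + 1L else n_sat <- n_sat + 1L
      }
    }
  }
  px <- prod(slice$pixel_spacing) / 100
  c(vat = n_vat * px, sat = n_sat * px)
}

# Small food-database fixture used by the tracking tests.
fixture_food_db <- function() {
  food_table(
    id = c("f1", "f2", "f3", "f4", "f5"),
    name = c("fried rice", "rice cake", "bibimbap", "banana", "green salad"),
    kcal_per_serving = c(520, 210, 560, 90, 60),
    serving_desc = c("1 bowl", "2 pieces", "1 bowl", "1 medium", "1 bowl"),
    source = c("cafeteria", "database", "nearby", "database", "frequent")
  )
}

# A screening profile with every field unremarkable; override as needed.
fixture_profile <- function(...) {
  base <- tibble::tibble(
    bmi = 27, sbp = 120, dbp = 80, fbs = 90, triglyceride = 150, ldl = 120,
    parq_any_yes = FALSE, eating_disorder_flag = FALSE,
    obesity_treatment_within_month = FALSE, weight_change_pct_month = 0,
    severe_illness_flag = FALSE, thyroid_disease = FALSE,
    counseling_cleared = FALSE, investigator_veto = FALSE
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}
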