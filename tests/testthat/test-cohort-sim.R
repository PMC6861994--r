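test_that("identical config and seed reproduce the cohort exactly", {
  a <- simulate_cohort(n = 10, seed = 123)
  b <- simulate_cohort(n = 10, seed = 123)
  expect_identical(a$baseline, b$baseline)
  expect_identical(a$weekly, b$weekly)
  expect_identical(a$daily, b$daily)
  c2 <- simulate_cohort(n = 10, seed = 124)
  expect_false(identical(a$baseline, c2$baseline))
})

test_that("full adherence with zero noise loses exactly 7% of baseline", {
  sim <- simulate_cohort(n = 8, seed = 5, adherence_mean = 1,
                         adherence_sd = 0, weight_noise_sd = 0)
  expect_equal(pct_weight_loss(sim), rep(7, 8), tolerance = 1e-12)
  final <- sim$weekly$weight[sim$weekly$week == 12]
  expect_equal(final, 0.93 * sim$baseline$weight)
})

test_that("zero adherence gives flat trajectories", {
  sim <- simulate_cohort(n = 5, seed = 6, adherence_mean = 0,
                         adherence_sd = 0, weight_noise_sd = 0)
  wk <- tidyr::pivot_wider(sim$weekly, names_from = week,
                           values_from = weight)
  expect_true(all(abs(as.matrix(wk[-1]) - wk$`0`) < 1e-12))
  expect_true(all(sim$daily$achieved_kcal == 0))
})

test_that("mass balance: weight change x kcal_per_kg equals achieved deficit", {
  sim <- simulate_cohort(n = 20, seed = 8, adherence_mean = 0.7,
                         adherence_sd = 0.3, weight_noise_sd = 0)
  ach <- sim$daily |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(total = sum(achieved_kcal), .groups = "drop")
  loss_kg <- sim$baseline$weight - sim$final_true_weight
  expect_equal(loss_kg * 7000, ach$total, tolerance = 1e-10)
})

test_that("without goal resetting, mean loss approaches adherence x 7%", {
  sim <- simulate_cohort(n = 400, seed = 9, adherence_mean = 0.8,
                         adherence_sd = 0.2, weight_noise_sd = 0,
                         reassess = FALSE)
  expect_equal(mean(pct_weight_loss(sim)), 0.8 * 7, tolerance = 0.02)
})

test_that("adherence is recovered unbiased from the trajectories", {
  sim <- simulate_cohort(n = 1000, seed = 10, adherence_mean = 0.8,
                         adherence_sd = 0.2, weight_noise_sd = 0.3)
  est <- recover_adherence(sim)
  expect_equal(est, 0.8, tolerance = 0.01)
  per <- recover_adherence(sim, by = "participant")
  expect_equal(nrow(per), 1000)
  expect_equal(mean(per$adherence), 0.8, tolerance = 0.01)
})

test_that("baseline marginals match their configured medians at scale", {
  sim <- simulate_cohort(n = 4000, seed = 11)
  b <- sim$baseline
  m <- cohort_marginals()
  for (v in c("weight", "fat_free_mass", "sbp", "triglyceride", "vat_cm2")) {
    target <- m$median[m$var == v]
    expect_equal(stats::median(b[[v]]), target, tolerance = 0.05 * target)
  }
  expect_equal(mean(b$sex == "male"), 28 / 30, tolerance = 0.03)
})

test_that("pre/post table pairs outcomes and respects zero-change cohorts", {
  sim0 <- simulate_cohort(n = 6, seed = 12, adherence_mean = 0,
                          adherence_sd = 0, weight_noise_sd = 0)
  pp0 <- emit_prepost(sim0)
  expect_equal(pp0$post_weight, pp0$pre_weight)
  expect_equal(pp0$post_bmi, pp0$pre_bmi)
  # deterministic across calls given the sim's seed
  expect_identical(pp0, emit_prepost(sim0))
  # long reshape pairs every pre_/post_ column
  long <- prepost_long(pp0)
  expect_setequal(unique(long$outcome),
                  c("weight", "bmi", outcome_slopes()$var))
  expect_equal(nrow(long), 6 * (2 + nrow(outcome_slopes())))
})

test_that("secondary outcomes track percent weight loss with expected signs", {
  sim <- simulate_cohort(n = 2000, seed = 13, adherence_mean = 1,
                         adherence_sd = 0, weight_noise_sd = 0)
  pp <- emit_prepost(sim)
  # everyone lost exactly 7%: medians shift by about slope x 7
  sl <- outcome_slopes()
  for (v in c("sbp", "triglyceride", "hdl", "vat_cm2")) {
    slope <- sl$slope[sl$var == v]
    shift <- stats::median(pp[[paste0("post_", v)]] - pp[[paste0("pre_", v)]])
    expect_equal(shift, -slope * 7, tolerance = max(0.3, abs(slope)))
  }
})

test_that("invalid simulator settings are rejected", {
  expect_error(simulate_cohort(n = 0, seed = 1), "n must")
  expect_error(simulate_cohort(n = 5, seed = 1, adherence_mean = 2),
               "adherence_mean")
  expect_error(simulate_cohort(n = 5, seed = 1, adherence_sd = -1), "sds")
})
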