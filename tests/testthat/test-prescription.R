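test_that("goal schedule splits 7% across three 4-week periods", {
  s <- build_goal_schedule(100)
  expect_equal(s$kg_target, c(3.0, 2.5, 1.5))
  expect_equal(sum(s$pct_target), 7.0)
  s2 <- build_goal_schedule(81.3)
  expect_equal(s2$kg_target, c(2.439, 2.0325, 1.2195))
  s0 <- build_goal_schedule(90, pct_splits = c(0, 0, 0))
  expect_equal(s0$kg_target, c(0, 0, 0))
  expect_error(build_goal_schedule(0), "positive")
  expect_error(build_goal_schedule(80, pct_splits = c(3, -1)), "pct_splits")
})

test_that("deficit-per-kg conversion is linear and conserves the 7% budget", {
  expect_equal(deficit_for_loss(1), 7000)
  expect_equal(deficit_for_loss(0), 0)
  expect_equal(deficit_for_loss(2.439), 17073)
  expect_error(deficit_for_loss(-0.1), "kg_to_lose")
  set.seed(3)
  a <- runif(20, 0, 3); b <- runif(20, 0, 3)
  expect_equal(deficit_for_loss(a + b),
               deficit_for_loss(a) + deficit_for_loss(b))
  s <- build_goal_schedule(81.3)
  expect_equal(sum(deficit_for_loss(s$kg_target)), 7000 * 0.07 * 81.3)
})

test_that("daily prescription subtracts the deficit and honors safety floors", {
  rx <- prescribe_daily(2497, 2.439, 28, "male")
  expect_equal(rx$daily_deficit_kcal, 609.75)
  expect_equal(rx$daily_intake_kcal, 1887.25)
  expect_false(rx$floor_applied)
  # female floor engages at 1200 and the unmet deficit is reported:
  # tee 2100 - 7000*4/28 = 1100 unconstrained, clamped up to 1200
  rx2 <- prescribe_daily(2100, 4.0, 28, "female")
  expect_equal(rx2$daily_intake_kcal, 1200)
  expect_true(rx2$floor_applied)
  expect_equal(rx2$unmet_deficit_kcal, 1200 - (2100 - 1000))
  # the male floor sits higher: the same unconstrained 1300 kcal/day that
  # passes for a woman is clamped to 1500 for a man
  expect_equal(prescribe_daily(2300, 4.0, 28, "female")$daily_intake_kcal, 1300)
  rx2m <- prescribe_daily(2300, 4.0, 28, "male")
  expect_equal(rx2m$daily_intake_kcal, 1500)
  expect_true(rx2m$floor_applied)
  # zero target: intake = tee
  rx3 <- prescribe_daily(2100, 0, 28, "male")
  expect_equal(rx3$daily_intake_kcal, 2100)
  expect_equal(rx3$daily_deficit_kcal, 0)
  # activity share moves part of the deficit out of the diet
  rx4 <- prescribe_daily(2497, 2.439, 28, "female", activity_share = 0.4)
  expect_equal(rx4$activity_kcal, 0.4 * 609.75)
  expect_equal(rx4$daily_intake_kcal, 2497 - 0.6 * 609.75)
  expect_error(prescribe_daily(2000, 1, 0, "male"), "period_days")
  expect_error(prescribe_daily(2000, 1, 28, "male", activity_share = 1.2),
               "activity_share")
})

test_that("prescribed intake never falls below the sex floor (property)", {
  set.seed(11)
  for (i in 1:200) {
    tee <- runif(1, 1000, 3500)
    kg <- runif(1, 0, 8)
    sex <- sample(c("female", "male"), 1)
    share <- runif(1)
    rx <- prescribe_daily(tee, kg, 28, sex, activity_share = share)
    floor <- if (sex == "female") 1200 else 1500
    expect_gte(rx$daily_intake_kcal, floor)
  }
})

test_that("reassessment keeps the endpoint at 93% of baseline", {
  s <- build_goal_schedule(100)
  # on-track: remaining targets unchanged
  s_on <- reassess(s, measured_weight = 97, completed_periods = 1)
  expect_equal(s_on$kg_target[2:3], c(2.5, 1.5))
  # 1 kg behind: remaining 5 kg redistributed 2.5:1.5
  s_behind <- reassess(s, measured_weight = 98, completed_periods = 1)
  expect_equal(s_behind$kg_target[2:3], c(5 * 2.5 / 4, 5 * 1.5 / 4))
  expect_equal(sum(s_behind$kg_target[2:3]), 98 - 93)
  # over-achieved: clamp at zero
  s_over <- reassess(s, measured_weight = 92, completed_periods = 1)
  expect_equal(s_over$kg_target[2:3], c(0, 0))
  expect_error(reassess(s, -1, 1), "measured_weight")
  expect_error(reassess(s, 95, 3), "completed_periods")
})

test_that("reassessment with on-track weights is idempotent", {
  s <- build_goal_schedule(81.3)
  w <- 81.3
  for (k in 1:2) {
    w <- w - s$kg_target[k]
    s_new <- reassess(s, w, completed_periods = k)
    expect_equal(s_new$kg_target, s$kg_target)
    # applying it twice changes nothing further
    expect_equal(reassess(s_new, w, k)$kg_target, s_new$kg_target)
    s <- s_new
  }
})

test_that("prescribe_cohort maps the prescription over a participant table", {
  d <- tibble::tibble(weight = c(100, 80), sex = c("male", "female"),
                      tee = c(2400, 2000))
  rx <- prescribe_cohort(d)
  expect_equal(rx$kg_target, c(3.0, 2.4))
  expect_equal(rx$daily_intake_kcal,
               c(2400 - 7000 * 3 / 28, 2000 - 7000 * 2.4 / 28))
  # period 2 with a measured weight drives reassessment
  d$measured_weight <- c(98, 78.5)
  rx2 <- prescribe_cohort(d, period = 2L)
  expect_equal(rx2$kg_target[1], (98 - 93) * 2.5 / 4)
  expect_error(prescribe_cohort(dplyr::select(d, -tee)), "tee")
})
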