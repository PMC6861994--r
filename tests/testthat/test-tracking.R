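test_that("food search is case-insensitive, ranked and deterministic", {
  db <- fixture_food_db()
  hits <- search_food(db, "RICE")
  expect_equal(hits$id, c("f1", "f2")) # cafeteria item before database item
  expect_equal(nrow(search_food(db, "banana")), 1)
  expect_equal(nrow(search_food(db, "pizza")), 0)
  expect_error(search_food(db, ""), "query")
  # frequent (pre-entered) outranks database even when alphabetically later
  hits2 <- search_food(db, "a") # matches several
  pre <- hits2$source %in% c("cafeteria", "nearby", "frequent")
  expect_true(all(diff(as.integer(!pre)) >= 0)) # pre-entered block first
})

test_that("manual activity converts METs to kcal by weight and duration", {
  expect_equal(manual_activity_kcal(8, 0, 80), 0)
  expect_equal(manual_activity_kcal(8, 30, 80), 320)
  expect_equal(manual_activity_kcal(4, 60, 60), 240)
  expect_error(manual_activity_kcal(0.5, 30, 80), "met")
})

test_that("daily balance sums entries and classifies against the goal", {
  db <- fixture_food_db()
  # no entries: intake 0, well under goal
  r0 <- daily_balance(tee = 2000, goal = 1800)
  expect_equal(r0$intake_kcal, 0)
  expect_equal(r0$status, "under_goal")
  # boundary: intake exactly at goal is on_goal
  diet_goal <- tibble::tibble(date = "2026-01-05", food_id = "f3",
                              portions = 1800 / 560)
  r1 <- daily_balance(diet_goal, db = db, tee = 2000, goal = 1800)
  expect_equal(r1$status, "on_goal")
  # hand-computed fixture day: 3 diet + 1 manual activity entries
  diet <- tibble::tibble(date = "2026-01-05", food_id = c("f1", "f4", "f5"),
                         portions = c(1, 2, 0.5))
  act <- tibble::tibble(date = "2026-01-05", kind = "manual",
                        met = 6, duration_min = 40, steps = NA, kcal = NA)
  r2 <- daily_balance(diet, act, db, tee = 2000, goal = 1800, weight = 80)
  expect_equal(r2$intake_kcal, 520 + 180 + 30)
  expect_equal(r2$expended_kcal, 2000 + 6 * 80 * 40 / 60)
  expect_equal(r2$net_kcal, r2$intake_kcal - r2$expended_kcal)
  expect_equal(r2$status, "under_goal")
  # double-counting guard: exercise excluded when TEE already covers it
  r3 <- daily_balance(diet, act, db, tee = 2000, goal = 1800, weight = 80,
                      add_logged_exercise = FALSE)
  expect_equal(r3$expended_kcal, 2000)
  # mixed dates rejected
  diet_mixed <- tibble::tibble(date = c("2026-01-05", "2026-01-06"),
                               food_id = c("f1", "f1"), portions = c(1, 1))
  expect_error(daily_balance(diet_mixed, db = db, tee = 2000, goal = 1800),
               "multiple dates")
  expect_error(
    daily_balance(tibble::tibble(date = "2026-01-05", food_id = "nope",
                                 portions = 1),
                  db = db, tee = 2000, goal = 1800),
    "unknown food_id")
})

test_that("splitting an entry into half portions leaves the report unchanged", {
  db <- fixture_food_db()
  one <- tibble::tibble(date = "2026-01-05", food_id = "f1", portions = 1)
  two <- tibble::tibble(date = "2026-01-05", food_id = c("f1", "f1"),
                        portions = c(0.5, 0.5))
  r1 <- daily_balance(one, db = db, tee = 2000, goal = 1800)
  r2 <- daily_balance(two, db = db, tee = 2000, goal = 1800)
  expect_equal(r1, r2)
})

test_that("a manual entry matching a tracker entry's kcal is equivalent", {
  # 6 MET x 80 kg x 30 min / 60 = 240 kcal
  manual <- tibble::tibble(date = "2026-01-05", kind = "manual",
                           met = 6, duration_min = 30, steps = NA, kcal = NA)
  tracker <- tibble::tibble(date = "2026-01-05", kind = "tracker",
                            met = NA, duration_min = NA, steps = 4000,
                            kcal = 240)
  rm <- daily_balance(activity = manual, tee = 2000, goal = 1800, weight = 80)
  rt <- daily_balance(activity = tracker, tee = 2000, goal = 1800)
  expect_equal(rm$expended_kcal, rt$expended_kcal)
})

test_that("weekly history aggregates by ISO week", {
  expect_equal(nrow(history_summary(NULL)), 0)
  # one week of identical days: mean equals the day's value
  db <- fixture_food_db()
  diet <- tibble::tibble(
    date = rep(as.character(seq(as.Date("2026-01-05"), by = 1, length.out = 7)),
               each = 1),
    food_id = "f1", portions = 1
  )
  rep1 <- balance_history(diet, db = db, tee = 2000, goal = 1800)
  h1 <- history_summary(rep1)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$intake_mean, 520)
  expect_equal(h1$days, 7)
  # 14-day fixture spanning two ISO weeks: totals recomputed by hand
  diet14 <- tibble::tibble(
    date = as.character(seq(as.Date("2026-01-05"), by = 1, length.out = 14)),
    food_id = rep(c("f1", "f4"), 7),
    portions = 1
  )
  rep2 <- balance_history(diet14, db = db, tee = 2000, goal = 1800)
  h2 <- history_summary(rep2)
  expect_equal(nrow(h2), 2)
  # 2026-01-05 is a Monday, so each ISO week holds exactly 7 days
  expect_equal(h2$days, c(7, 7))
  expect_equal(h2$intake_total, c(520 * 4 + 90 * 3, 520 * 3 + 90 * 4))
})
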