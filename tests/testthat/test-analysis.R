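test_that("median and IQR use linear interpolation (type 7)", {
  m <- median_iqr(c(1, 2, 3))
  expect_equal(unlist(m), c(median = 2, q1 = 1.5, q3 = 2.5))
  m2 <- median_iqr(rep(4.2, 10))
  expect_equal(m2$median, 4.2)
  expect_equal(m2$q1, 4.2)
  expect_equal(m2$q3, 4.2)
  m3 <- median_iqr(7)
  expect_equal(unlist(m3), c(median = 7, q1 = 7, q3 = 7))
  expect_error(median_iqr(numeric()), "non-empty")
  expect_error(median_iqr(c(1, NA)), "NA")
})

test_that("signed-rank exact p matches closed-form and handles degeneracy", {
  # 5 pairs all in one direction: one-sided 1/32, two-sided 1/16
  w <- wilcoxon_signed_rank(pre = c(5, 6, 7, 8, 9), post = c(4, 5, 6, 7, 8))
  expect_equal(w$p_value, 1 / 16)
  expect_equal(w$method, "exact")
  expect_equal(w$statistic, 0)
  # identical vectors: degenerate flag, no p
  d <- wilcoxon_signed_rank(1:6, 1:6)
  expect_true(d$degenerate)
  expect_true(is.na(d$p_value))
  expect_equal(d$n_zero, 6)
  # zero differences are dropped, not ranked
  w2 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), c(1, 1, 2, 3, 4, 5))
  expect_equal(w2$n, 5)
  expect_equal(w2$n_zero, 1)
})

test_that("exact path equals brute-force sign enumeration for n <= 10", {
  set.seed(51)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    pre <- rnorm(n)
    post <- pre + rnorm(n, sd = 1.5)
    expect_equal(wilcoxon_signed_rank(pre, post)$p_value,
                 wsr_brute_p(pre, post))
  }
})

test_that("exact path with ties equals brute force over midranks", {
  set.seed(52)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    pre <- sample(1:6, n, replace = TRUE)
    post <- sample(1:6, n, replace = TRUE)
    if (all(post == pre)) post[1] <- post[1] + 1
    expect_equal(wilcoxon_signed_rank(pre, post)$p_value,
                 wsr_brute_p(pre, post))
  }
})

test_that("tie-free exact p agrees with stats::wilcox.test", {
  set.seed(53)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    pre <- rnorm(n)
    post <- pre + rnorm(n)
    expect_equal(wilcoxon_signed_rank(pre, post)$p_value,
                 stats::wilcox.test(post, pre, paired = TRUE,
                                    exact = TRUE)$p.value)
  }
})

test_that("normal approximation converges to the exact p", {
  set.seed(54)
  diffs <- numeric(100)
  for (i in 1:100) {
    pre <- rnorm(20)
    post <- pre + rnorm(20, -0.2)
    pe <- wilcoxon_signed_rank(pre, post, exact_n = 25)$p_value
    pn <- wilcoxon_signed_rank(pre, post, exact_n = 0)$p_value
    diffs[i] <- abs(pe - pn)
  }
  expect_lt(max(diffs), 0.01)
})

test_that("median difference sign agrees with the test direction", {
  pre <- seq(80, 100, length.out = 15)
  post <- pre - runif(15, 0.5, 2)
  w <- wilcoxon_signed_rank(pre, post)
  dd <- median_iqr(post - pre)
  expect_lt(dd$median, 0)
  expect_lt(w$statistic, 15 * 16 / 4) # below the null mean: losses dominate
})

test_that("outcome summary reproduces its inputs' structure", {
  sim <- simulate_cohort(n = 30, seed = 55, adherence_mean = 1,
                         adherence_sd = 0, weight_noise_sd = 0)
  long <- prepost_long(emit_prepost(sim))
  sm <- summarize_outcomes(long)
  expect_s3_class(sm, "enbal_outcomes")
  expect_setequal(sm$outcome, unique(long$outcome))
  # deterministic full-adherence cohort: weight change is exactly -7%
  expect_equal(sm$mean_pct_change[sm$outcome == "weight"], -7)
  expect_false(any(sm$degenerate[sm$outcome == "weight"]))
  # zero-change cohort: zero medians and degenerate weight test
  sim0 <- simulate_cohort(n = 10, seed = 56, adherence_mean = 0,
                          adherence_sd = 0, weight_noise_sd = 0)
  sm0 <- summarize_outcomes(prepost_long(emit_prepost(sim0)))
  w0 <- sm0[sm0$outcome == "weight", ]
  expect_equal(w0$diff_median, 0)
  expect_true(w0$degenerate)
  # reproducible end to end with the same seed
  sm0b <- summarize_outcomes(prepost_long(emit_prepost(
    simulate_cohort(n = 10, seed = 56, adherence_mean = 0,
                    adherence_sd = 0, weight_noise_sd = 0))))
  expect_identical(sm0, sm0b)
  expect_error(summarize_outcomes(tibble::tibble(outcome = "x", pre = 1)),
               "post")
})

test_that("markdown report renders one row per outcome", {
  sim <- simulate_cohort(n = 12, seed = 57)
  sm <- summarize_outcomes(prepost_long(emit_prepost(sim)))
  lines <- format_outcome_report(sm)
  expect_equal(length(lines), nrow(sm) + 2)
  expect_match(lines[1], "Baseline")
  p <- tempfile(fileext = ".md")
  format_outcome_report(sm, p)
  expect_true(file.exists(p))
})

test_that("tidy and glance expose the test and simulation results", {
  w <- wilcoxon_signed_rank(c(3, 4, 5, 7, 9), c(1, 2, 3, 4, 5))
  td <- tidy(w)
  expect_equal(td$p.value, w$p_value)
  expect_equal(td$n, 5)
  sim <- simulate_cohort(n = 6, seed = 58)
  expect_equal(nrow(tidy(sim)), 6 * 13)
  g <- glance(sim)
  expect_equal(g$n, 6)
  expect_true(g$mean_pct_loss > 0)
})
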