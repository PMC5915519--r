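test_that("product-limit estimator matches hand computation", {
  # 5 subjects, events at days 2 and 4, no censoring
  km <- kaplan_meier(make_events(c(2, 4, -7, -7, -7)))
  expect_equal(km$survival[km$time == 2], 0.8)
  expect_equal(km$survival[km$time == 4], 0.6)
  # all censored -> survival stays 1
  expect_true(all(kaplan_meier(make_events(c(-3, -5, -9)))$survival == 1))
  # all events at one day -> drop straight to 0
  km0 <- kaplan_meier(make_events(c(6, 6, 6)))
  expect_equal(km0$survival, 0)
  expect_true(all(diff(kaplan_meier(make_events(c(1, 3, -4, 5, 8)))$survival) <= 0))
})

test_that("product-limit estimator agrees with survival::survfit on mixed data", {
  skip_if_not_installed("survival")
  ev <- make_events(c(2, 4, -4, 5, -6, 8, -8, 3, 3, -10))
  km <- kaplan_meier(ev)
  sf <- survival::survfit(survival::Surv(ev$day, ev$status == "event") ~ 1)
  ref <- summary(sf, times = km$time)
  expect_equal(km$survival, ref$surv)
  expect_equal(km$n_risk, ref$n.risk)
  expect_equal(km$std_err[km$n_event > 0], ref$std.err[ref$n.event > 0],
               tolerance = 1e-8)
})

test_that("censoring ties are processed after events and split censor times are inert", {
  # subject censored at an event day stays at risk for that day's event
  km <- kaplan_meier(make_events(c(3, -3, -5)))
  expect_equal(km$survival[km$time == 3], 1 - 1 / 3)
  # moving a no-event censoring time slightly leaves the curve unchanged
  a <- kaplan_meier(make_events(c(2, -4, -4, 7)))
  b <- kaplan_meier(make_events(c(2, -4, -4.5, 7)))
  expect_equal(a$survival[a$n_event > 0], b$survival[b$n_event > 0])
})

test_that("log-rank matches the hand/hypergeometric oracle and is symmetric", {
  a <- make_events(1:3)
  b <- make_events(4:6)
  lr <- logrank_test(a, b)
  # frozen from summing O, E and hypergeometric V over event times by hand
  expect_equal(lr$chi_square, 5.051661, tolerance = 1e-6)
  expect_equal(lr$observed, 3)
  expect_equal(lr$expected, 1.15)
  expect_equal(lr$p_value, pchisq(5.051661, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  flipped <- logrank_test(b, a)
  expect_equal(flipped$chi_square, lr$chi_square)
  # identical event-time multisets -> chi-square 0, p 1
  same <- logrank_test(make_events(c(1, 5, 9)), make_events(c(1, 5, 9)))
  expect_equal(same$chi_square, 0)
  expect_equal(same$p_value, 1)
  # no events at all -> undefined statistic
  none <- logrank_test(make_events(c(-2, -3)), make_events(c(-4)))
  expect_true(is.na(none$chi_square))
})

test_that("log-rank agrees with survival::survdiff", {
  skip_if_not_installed("survival")
  a <- make_events(c(3, 5, 7, -9, 11, -15))
  b <- make_events(c(4, 6, -8, 10, 12, -18))
  lr <- logrank_test(a, b)
  sd <- survival::survdiff(
    survival::Surv(c(a$day, b$day),
                   c(a$status, b$status) == "event") ~ rep(1:2, c(6, 6)))
  expect_equal(lr$chi_square, sd$chisq, tolerance = 1e-10)
})

test_that("early censored subjects only affect at-risk counts before their time", {
  a <- make_events(c(5, 8, 12))
  b <- make_events(c(6, 9, -14))
  base <- logrank_test(a, b)
  with_early <- logrank_test(a, dplyr::bind_rows(b, make_events(-2)))
  # censored before the first event: O and E at later times unchanged
  expect_equal(with_early$observed, base$observed)
  expect_equal(with_early$chi_square, base$chi_square, tolerance = 0.2)
})

test_that("chi-square log-rank p is consistent with a 10,000-shuffle permutation null", {
  time <- c(3, 5, 7, 9, 11, 13, 15, 16, 4, 6, 8, 10, 12, 14, 17, 18)
  event <- rep(c(rep(TRUE, 6), FALSE, FALSE), 2)
  grp <- rep(c(1L, 2L), each = 8)
  oe <- alphadose:::logrank_oe(time, event, grp)
  chi_obs <- (oe$obs - oe$exp)^2 / oe$sum_v
  p_chi <- pchisq(chi_obs, 1, lower.tail = FALSE)
  set.seed(42)
  perm <- replicate(10000, {
    r <- alphadose:::logrank_oe(time, event, sample(grp))
    if (r$sum_v == 0) 0 else (r$obs - r$exp)^2 / r$sum_v
  })
  p_perm <- mean(perm >= chi_obs - 1e-12)
  expect_lt(abs(p_perm - p_chi), 0.05)
})

test_that("Dunnett adjustment reduces to the two-sided t-test for one treatment", {
  set.seed(21)
  df <- data.frame(g = rep(c("c", "t"), each = 8),
                   y = c(rnorm(8), rnorm(8, 1)))
  mine <- dunnett_many_to_one(df, y, g, control = "c",
                              mc_draws = 2e5, seed = 3)
  ref <- t.test(y ~ g, df, var.equal = TRUE)$p.value
  expect_equal(mine$p_adjusted, ref, tolerance = 0.01)
})

test_that("Dunnett adjusted p-values match the multivariate-t reference", {
  skip_if_not_installed("multcomp")
  set.seed(4)
  df <- data.frame(g = factor(rep(c("c", "t1", "t2", "t3"), each = 6)),
                   y = c(rnorm(6), rnorm(6, 0.8), rnorm(6, 0.2), rnorm(6, 1.5)))
  mine <- dunnett_many_to_one(df, y, g, control = "c",
                              mc_draws = 2e5, seed = 11)
  ref <- summary(multcomp::glht(stats::aov(y ~ g, df),
                                linfct = multcomp::mcp(g = "Dunnett")))
  expect_equal(mine$p_adjusted, as.numeric(ref$test$pvalues), tolerance = 0.02)
})

test_that("Dunnett family-wise p never undercuts the per-comparison p", {
  set.seed(9)
  df <- data.frame(g = rep(c("c", "t1", "t2", "t3"), each = 5),
                   y = rnorm(20))
  res <- dunnett_many_to_one(df, y, g, control = "c", mc_draws = 5e4, seed = 2)
  p_raw <- 2 * pt(-abs(res$statistic), res$df)
  expect_true(all(res$p_adjusted >= p_raw - 0.01))
  # identical treatment and control values -> p near 1
  df_id <- data.frame(g = rep(c("c", "t"), each = 4),
                      y = rep(c(1.2, 0.8, 1.1, 0.9), 2))
  res_id <- dunnett_many_to_one(df_id, y, g, control = "c",
                                mc_draws = 5e4, seed = 2)
  expect_gt(res_id$p_adjusted, 0.95)
  # zero pooled variance is an error
  df0 <- data.frame(g = rep(c("c", "t"), each = 3), y = rep(1, 6))
  expect_error(dunnett_many_to_one(df0, y, g, control = "c"), "variance")
})

test_that("Dunnett Monte-Carlo adjustment is seed-reproducible", {
  df <- data.frame(g = rep(c("c", "t1", "t2"), each = 5),
                   y = c(1:5, 2:6, 0:4) + 0.1 * (1:15))
  a <- dunnett_many_to_one(df, y, g, control = "c", mc_draws = 1e4, seed = 7)
  b <- dunnett_many_to_one(df, y, g, control = "c", mc_draws = 1e4, seed = 7)
  expect_identical(a, b)
})
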