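test_that("tumor volume formula and canonicalisation", {
  expect_equal(tumor_volume(10, 5), 125)
  expect_equal(tumor_volume(5, 10), 125)
  expect_equal(tumor_volume(7, 0), 0)
  expect_error(tumor_volume(-1, 2), "non-negative")
  # homogeneous of degree 3 under uniform scaling
  expect_equal(tumor_volume(2 * 8, 2 * 5), 8 * tumor_volume(8, 5))
})

test_that("relative series is 100% at day 0 and scales per animal", {
  rec <- animal_records(dplyr::bind_rows(
    make_animal("a1", 0, c(0, 7, 14), c(50, 100, 200), c(20, 21, 22)),
    make_animal("a2", 0, c(0, 7, 14), c(40, 40, 40), c(20, 20, 20))))
  rel <- relative_series(rec, "tumor_volume")
  expect_equal(rel$relative_pct[rel$animal_id == "a1"], c(100, 200, 400))
  expect_equal(rel$relative_pct[rel$animal_id == "a2"], c(100, 100, 100))
  relw <- relative_series(rec, "body_weight")
  expect_equal(relw$relative_pct[relw$animal_id == "a1"],
               100 * c(20, 21, 22) / 20)
  bad <- dplyr::bind_rows(make_animal("a3", 0, c(0, 7), c(0, 10), c(20, 20)))
  expect_error(relative_series(animal_records(bad)), "baseline")
})

test_that("percent change is the signed deviation from 100%", {
  expect_equal(percent_change(100), 0)
  expect_equal(percent_change(9.6), -90.4)
  expect_equal(percent_change(509.2), 409.2)
  expect_error(percent_change(-5), ">= 0")
})

test_that("group summary averages per-animal ratios and interpolates days", {
  rec <- animal_records(dplyr::bind_rows(
    make_animal("a1", 0.56, c(0, 20, 22), c(50, 3.5, 4.5), c(20, 20, 20)),
    make_animal("a2", 0.56, c(0, 20, 22), c(25, 2.5, 3.1), c(20, 20, 20))))
  gs <- group_summary(rec, day = 21, quantity = "tumor_volume")
  # day 21 interpolates the midpoint of days 20 and 22 per animal
  a1 <- 100 * mean(c(3.5, 4.5)) / 50
  a2 <- 100 * mean(c(2.5, 3.1)) / 25
  expect_equal(gs$mean_pct, mean(c(a1, a2)))
  expect_equal(gs$sd_pct, sd(c(a1, a2)))
  expect_equal(gs$n, 2L)
  expect_error(group_summary(rec, day = 30), "outside")
  # identical animals -> zero SD
  rec2 <- animal_records(dplyr::bind_rows(
    make_animal("b1", 0, c(0, 21), c(50, 100), c(20, 20)),
    make_animal("b2", 0, c(0, 21), c(80, 160), c(20, 20))))
  expect_equal(group_summary(rec2, 21)$sd_pct, 0)
  # mean of ratios, not ratio of means: two animals at 8% and 11.2% -> 9.6%
  rec3 <- animal_records(dplyr::bind_rows(
    make_animal("c1", 0.56, c(0, 21), c(50, 4), c(20, 20)),
    make_animal("c2", 0.56, c(0, 21), c(25, 2.8), c(20, 20))))
  expect_equal(group_summary(rec3, 21)$mean_pct, 9.6)
})

test_that("endpoint rules fire on first crossing with documented conventions", {
  rules <- endpoint_rules()
  # volume crosses 500 on day 18
  rec <- animal_records(
    make_animal("a1", 0, c(0, 7, 14, 18, 21), c(50, 150, 350, 520, 700),
                rep(20, 5)))
  ev <- apply_endpoints(rec, rules, mode = "analysis")
  expect_equal(ev$day, 18)
  expect_equal(ev$status, "event")
  expect_equal(ev$reason, "tumor_volume")
  # husbandry mode waits for 800
  evh <- apply_endpoints(rec, rules, mode = "husbandry")
  expect_equal(evh$status, "censored")
  # weight loss of exactly 20% is NOT an event (strict rule)
  rec2 <- animal_records(
    make_animal("a2", 1.11, c(0, 3, 7), c(50, 40, 30), c(20, 16, 18)))
  ev2 <- apply_endpoints(rec2, rules)
  expect_equal(ev2$status, "censored")
  # 20.5% loss is
  rec3 <- animal_records(
    make_animal("a3", 1.85, c(0, 3, 7), c(50, 40, 30), c(20, 15.9, 18)))
  ev3 <- apply_endpoints(rec3, rules)
  expect_equal(ev3$status, "event")
  expect_equal(ev3$day, 3)
  expect_equal(ev3$reason, "weight_loss")
  # no crossing through day 56 -> censored at study end / last observation
  rec4 <- animal_records(
    make_animal("a4", 0.56, c(0, 28, 56), c(50, 60, 70), c(20, 21, 22)))
  expect_equal(apply_endpoints(rec4, rules)$day, 56)
})

test_that("endpoint timing is monotone in the threshold", {
  rec <- animal_records(
    make_animal("a1", 0, c(0, 7, 14, 18, 21), c(50, 150, 350, 520, 830),
                rep(20, 5)))
  loose <- apply_endpoints(rec, endpoint_rules(analysis_volume = 500))
  tight <- apply_endpoints(rec, endpoint_rules(analysis_volume = 300))
  expect_lte(tight$day, loose$day)
})

test_that("MTD is the highest activity with no weight failure", {
  # encoded group outcomes: >20% loss in every animal at 1.85/3.70/5.55;
  # at 1.11 one animal reaches exactly 20% (not a failure); lower groups fine
  flags <- tibble::tibble(
    group_mbq = rep(c(0.28, 0.56, 1.11, 1.85, 3.70, 5.55), each = 5),
    weight_failure = rep(c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE), each = 5))
  expect_equal(determine_mtd(flags), 1.11)
  # no group triggers -> highest tested activity
  none <- dplyr::mutate(flags, weight_failure = FALSE)
  expect_equal(determine_mtd(none), 5.55)
  # all groups trigger -> no defined MTD
  all_fail <- dplyr::mutate(flags, weight_failure = TRUE)
  expect_true(is.na(determine_mtd(all_fail)))
  expect_error(determine_mtd(flags[flags$group_mbq == 0, ]), "non-control")
})

test_that("MTD from raw records matches the strict >20% rule and is monotone", {
  rec <- animal_records(dplyr::bind_rows(
    make_animal("l1", 0.56, c(0, 3, 10), c(50, 40, 30), c(20, 19.5, 20)),
    make_animal("m1", 1.11, c(0, 3, 10), c(50, 30, 20), c(20, 16, 19)),   # exactly 20%
    make_animal("h1", 1.85, c(0, 3, 10), c(50, 25, 15), c(20, 15.8, 17)))) # 21%
  expect_equal(determine_mtd(rec), 1.11)
  # adding a failure to the 1.11 group lowers the MTD
  worse <- dplyr::bind_rows(
    tibble::as_tibble(rec),
    make_animal("m2", 1.11, c(0, 3, 10), c(50, 30, 20), c(20, 15, 19)))
  expect_equal(determine_mtd(animal_records(worse)), 0.56)
})
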