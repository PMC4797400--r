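test_that("caliper volume follows the rotated-ellipsoid formula", {
  expect_equal(tumor_volume(10, 15), 750)
  d <- 7.3
  expect_equal(tumor_volume(d, d), 0.5 * d^3)
  expect_equal(tumor_volume(2 * 4, 9), 4 * tumor_volume(4, 9))  # quadratic in w
  expect_error(tumor_volume(0, 5), "> 0")
  expect_error(tumor_volume(5, -1), "> 0")
})

test_that("endpoint rule uses strict thresholds", {
  expect_true(evaluate_endpoint(10, 12, 23.9, 30))     # > 20 % weight loss
  expect_false(evaluate_endpoint(10, 12, 24.0, 30))    # exactly 20 %: no
  expect_false(evaluate_endpoint(10, 15.0, 30, 30))    # exactly 15 mm: no
  expect_true(evaluate_endpoint(10, 15.1, 30, 30))     # > 15 mm: yes
  expect_true(evaluate_endpoint(15.2, 15.2, 30, 30))   # width counts too
  expect_error(evaluate_endpoint(10, 12, 30, NULL), "baseline")
})

test_that("KM median equals the empirical median on complete data", {
  rec <- data.frame(group = "g", event_time = c(38, 38, 38, 40, 40), event = 1)
  km <- kaplan_meier(rec)
  expect_equal(unname(km$median_days["g"]), 38)
  # property: complete data, random event times
  set.seed(5)
  for (i in 1:20) {
    tt <- sample(10:100, 7, replace = TRUE)
    km2 <- kaplan_meier(data.frame(group = "g", event_time = tt, event = 1))
    emp <- sort(tt)[ceiling(length(tt) / 2)]  # earliest t with S(t) <= 0.5
    expect_equal(unname(km2$median_days["g"]), emp)
  }
})

test_that("KM median is undefined when the curve stays above one half", {
  rec <- data.frame(group = "hi", event_time = c(100, 120, 120, 120, 120),
                    event = c(1, 0, 0, 0, 0))
  km <- kaplan_meier(rec)
  expect_true(is.na(km$median_days["hi"]))
  allc <- kaplan_meier(data.frame(group = "c", event_time = rep(120, 4), event = 0))
  expect_true(is.na(allc$median_days["c"]))
  expect_true(all(allc$curves$surv == 1))
  expect_error(kaplan_meier(data.frame(group = character(), event_time = numeric(),
                                       event = integer())), "nrow")
})

test_that("KM curve is non-increasing and matches a hand product-limit oracle", {
  set.seed(17)
  tt <- sample(5:60, 10, replace = TRUE)
  ev <- rbinom(10, 1, 0.7)
  ev[which.max(tt)] <- 0   # ensure censoring present
  km <- kaplan_meier(data.frame(group = "g", event_time = tt, event = ev))
  expect_true(all(diff(km$curves$surv) <= 1e-12))
  expect_true(all(km$curves$surv <= 1))
  orc <- product_limit_oracle(tt, ev)
  got <- km$curves[match(orc$time, km$curves$time), "surv"]
  expect_equal(got, orc$surv, tolerance = 1e-12)
})

test_that("percent volume change normalises to day 0 and averages survivors", {
  m <- data.frame(
    animal_id = rep(c("a", "b"), each = 3),
    group = "g",
    day = rep(c(0, 15, 30), 2),
    width_mm = c(6.3, 5, 4.16, 6.3, 7, 0),     # b drops out (V = 0 remission)
    length_mm = c(10.08, 8, 5.78, 10.08, 11, 0))
  pv <- percent_volume_change(m)
  a30 <- pv$per_animal[pv$per_animal$animal_id == "a" & pv$per_animal$day == 30, ]
  expect_equal(a30$pct_of_baseline, 100 * tumor_volume(4.16, 5.78) /
                 tumor_volume(6.3, 10.08), tolerance = 1e-12)
  b30 <- pv$per_animal[pv$per_animal$animal_id == "b" & pv$per_animal$day == 30, ]
  expect_equal(b30$pct_of_baseline, 0)         # complete remission
  d0 <- pv$per_animal[pv$per_animal$day == 0, "pct_of_baseline"]
  expect_true(all(d0 == 100))
  bad <- m; bad$width_mm[1] <- 0
  expect_error(percent_volume_change(bad), "baseline")
})

test_that("survival records take the first endpoint crossing else censor at 120 d", {
  m <- data.frame(
    animal_id = rep(c("a", "b"), each = 4),
    group = "g",
    day = rep(c(0, 20, 40, 60), 2),
    width_mm = c(6, 8, 12, 15.5, 6, 6, 6, 6),
    length_mm = c(6, 9, 14, 16, 6, 6, 6, 6),
    weight_g = c(30, 30, 30, 30, 30, 30, 30, 30))
  rec <- survival_records(m, followup_days = 120)
  expect_equal(rec$event_time[rec$animal_id == "a"], 60)
  expect_equal(rec$event[rec$animal_id == "a"], 1L)
  expect_equal(rec$event_time[rec$animal_id == "b"], 120)
  expect_equal(rec$event[rec$animal_id == "b"], 0L)
})
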