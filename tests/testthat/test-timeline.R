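test_that("ICU start is approximated as 60 minutes before the first vital", {
  obs <- data.frame(time_h = c(5.0, 6.2), channel = c("heart_rate", "spo2"))
  expect_equal(infer_icu_start(obs), 4.0)
  expect_equal(infer_icu_start(obs, explicit_start = 2.5), 2.5)

  two <- data.frame(time_h = c(3.2, 2.8),
                    channel = c("heart_rate", "resp_rate"))
  expect_equal(infer_icu_start(two), 1.8)

  none <- data.frame(time_h = 1, channel = "platelets")
  expect_error(infer_icu_start(none), "empty stay")
})

test_that("hourly binning averages within half-open hour bins", {
  b <- bin_hourly(c(0.2, 0.7), c(80, 90), 3)
  expect_equal(b$values[1], 85)
  expect_true(b$mask[1])
  expect_true(all(is.na(b$values[2:3])))

  b <- bin_hourly(1.5, 37.0, 3)
  expect_equal(b$values, c(NA, 37, NA))

  b <- bin_hourly(c(0.5, 1.5), c(90, 100), 2)
  expect_equal(b$values, c(90, 100))

  # empty input: all-missing array, no error
  b <- bin_hourly(numeric(0), numeric(0), 4)
  expect_true(all(is.na(b$values)))
  expect_false(any(b$mask))
})

test_that("bin means match a brute-force assignment on random event sets", {
  withr::with_seed(404, {
    for (rep in 1:25) {
      n_hours <- sample(2:30, 1)
      n <- sample(0:60, 1)
      t <- runif(n, 0, n_hours)
      v <- rnorm(n, 100, 20)
      got <- bin_hourly(t, v, n_hours)
      want <- vapply(seq_len(n_hours), function(k) {
        inbin <- t >= (k - 1) & (t < k | (k == n_hours & t <= k))
        if (any(inbin)) mean(v[inbin]) else NA_real_
      }, numeric(1))
      expect_equal(got$values, want)
      expect_equal(got$mask, !is.na(want))
    }
  })
})

test_that("imputation carries forward, back-fills, and is idempotent", {
  expect_equal(impute_series(c(5, NA, NA)), c(5, 5, 5))
  expect_equal(impute_series(c(NA, NA, 7)), c(7, 7, 7))
  expect_equal(impute_series(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(impute_series(c(NA, 4, NA, 9, NA)), c(4, 4, 4, 9, 9))
  # all-missing stays all-missing
  expect_true(all(is.na(impute_series(c(NA_real_, NA_real_)))))

  withr::with_seed(11, {
    for (rep in 1:50) {
      x <- rnorm(20)
      x[sample(20, sample(0:19, 1))] <- NA
      once <- impute_series(x)
      expect_identical(impute_series(once), once)          # idempotent
      expect_identical(once[!is.na(x)], x[!is.na(x)])      # conservation
    }
  })
})

test_that("invasive blood pressure is preferred within a bin", {
  obs <- data.frame(
    time_h = c(0.5, 0.6, 1.5, 0.1),
    channel = c("sysabp", "nisysabp", "nisysabp", "heart_rate"),
    value = c(120, 110, 108, 70))
  tl <- build_stay_timeline(obs, 2)
  expect_equal(unname(tl$values[1, "sys_bp"]), 120)  # invasive wins
  expect_equal(unname(tl$values[2, "sys_bp"]), 108)  # cuff fills the gap

  cfg <- vs_config(prefer_invasive_bp = FALSE)
  tl2 <- build_stay_timeline(obs, 2, config = cfg)
  expect_equal(unname(tl2$values[1, "sys_bp"]), 110)
})

test_that("pulse pressure is systolic minus diastolic at every hour", {
  obs <- data.frame(
    time_h = c(0.5, 0.5, 2.5, 2.5, 0.2),
    channel = c("nisysabp", "nidiasabp", "nisysabp", "nidiasabp",
                "heart_rate"),
    value = c(120, 80, 110, 74, 70))
  tl <- build_stay_timeline(obs, 4)
  expect_equal(unname(tl$values[, "pulse_pressure"]),
               unname(tl$values[, "sys_bp"] - tl$values[, "dias_bp"]))
  expect_equal(unname(tl$values[1, "pulse_pressure"]), 40)
})

test_that("stay timelines are complete, deterministic, order-invariant", {
  obs <- data.frame(time_h = c(0.3, 1.1, 2.4), channel = "heart_rate",
                    value = c(70, 75, 80))
  tl <- build_stay_timeline(obs, 2.5)
  expect_equal(tl$n_hours, 3)
  expect_false(any(is.na(tl$values[, "heart_rate"])))
  expect_true(tl$all_missing[["spo2"]])   # flagged, not fabricated

  # input ordering must not matter
  perm <- obs[c(3, 1, 2), ]
  expect_identical(build_stay_timeline(perm, 2.5)$values, tl$values)
  # determinism
  expect_identical(build_stay_timeline(obs, 2.5)$values, tl$values)
})

test_that("cohort-wide timeline building equals the per-stay path", {
  fx <- labeled_cohort(60, 31)
  co <- fx$cohort
  per_stay <- lapply(split(as.data.frame(co$observations),
                           as.data.frame(co$observations)$stay_id),
                     function(df) {
    len <- co$stays$icu_length_h[co$stays$stay_id == df$stay_id[1]]
    build_stay_timeline(df, len, stay_id = df$stay_id[1])
  })
  for (sid in names(fx$timelines)) {
    expect_identical(fx$timelines[[sid]]$values, per_stay[[sid]]$values,
                     info = sid)
    expect_identical(fx$timelines[[sid]]$mask, per_stay[[sid]]$mask,
                     info = sid)
  }
})

test_that("implausible observations are rejected and counted", {
  stays <- data.frame(stay_id = "a", age_years = 50, icu_length_h = 4,
                      death_in_hospital = FALSE)
  obs <- data.frame(stay_id = "a",
                    time_h = c(0.5, 1.5, 2.5, 3.5),
                    channel = c("heart_rate", "heart_rate", "bogus",
                                "heart_rate"),
                    value = c(80, 500, 1, 90))
  ev <- data.frame(stay_id = character(0), time_h = numeric(0),
                   event_type = character(0))
  co <- vs_cohort(stays, obs, ev)
  expect_equal(nrow(co$observations), 2)
  expect_equal(co$rejected$n[co$rejected$reason == "out_of_range"], 1)
  expect_equal(co$rejected$n[co$rejected$reason == "unknown_channel"], 1)
})

test_that("Fahrenheit temperatures are normalized to Celsius", {
  stays <- data.frame(stay_id = "a", age_years = 50, icu_length_h = 2,
                      death_in_hospital = FALSE)
  obs <- data.frame(stay_id = "a", time_h = 0.5, channel = "temperature",
                    value = 98.6)
  ev <- data.frame(stay_id = character(0), time_h = numeric(0),
                   event_type = character(0))
  co <- vs_cohort(stays, obs, ev, config = vs_config(temperature_unit = "F"))
  expect_equal(co$observations$value, 37)
})
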