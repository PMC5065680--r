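test_that("suspicion pairing follows the 72 h / 24 h windows", {
  expect_equal(find_suspicion_hour(0, 71), 0L)      # culture within 72 h
  expect_true(is.na(find_suspicion_hour(25, 0)))    # abx 25 h after culture
  expect_equal(find_suspicion_hour(5, 4.5), 4L)     # abx within 24 h
  expect_true(is.na(find_suspicion_hour(numeric(0), 10)))
  expect_true(is.na(find_suspicion_hour(10, numeric(0))))
})

test_that("suspicion hour is never later than any qualifying pair's first event", {
  withr::with_seed(77, {
    for (rep in 1:40) {
      abx <- sort(runif(sample(0:4, 1), -10, 80))
      cult <- sort(runif(sample(0:4, 1), 0, 80))
      got <- find_suspicion_hour(abx, cult)
      # brute force over all pairs under both window rules
      firsts <- c()
      for (a in abx) for (cu in cult) {
        if (cu >= a && cu <= a + 72) firsts <- c(firsts, a)
        if (a >= cu && a <= cu + 24) firsts <- c(firsts, cu)
      }
      if (length(firsts) == 0) {
        expect_true(is.na(got))
      } else {
        expect_equal(got, as.integer(floor(min(firsts))))
      }
    }
  })
})

test_that("respiration subscore follows the SpO2/FiO2 thresholds", {
  expect_equal(respiration_subscore(99, 0.21), 0L)   # ratio ~471
  expect_equal(respiration_subscore(90, 0.60), 4L)   # ratio 150
  expect_equal(respiration_subscore(84, NA), 1L)     # room air, ratio 400
  expect_error(respiration_subscore(-10, 0.5), "positive")

  # monotone non-increasing in the ratio
  spo2 <- seq(60, 100, by = 0.5)
  sc <- respiration_subscore(spo2, 0.4)
  expect_true(all(diff(sc) <= 0))
  fio2 <- seq(0.21, 1, by = 0.01)
  sc2 <- respiration_subscore(92, fio2)
  expect_true(all(diff(sc2) >= 0))
})

test_that("hourly SOFA scores subscores from imputed values, 0 when absent", {
  tl <- flat_timeline(6)
  s <- hourly_sofa(tl)
  expect_equal(s$total, rep(0L, 6))

  # platelets 90 (coagulation 2) + GCS 12 (CNS 2), rest normal
  obs <- data.frame(
    time_h = rep(seq_len(6) - 0.5, 3),
    channel = rep(c("heart_rate", "platelets", "gcs"), each = 6),
    value = c(rep(80, 6), rep(90, 6), rep(12, 6)))
  tl2 <- build_stay_timeline(obs, 6)
  s2 <- hourly_sofa(tl2)
  expect_equal(s2$coagulation, rep(2L, 6))
  expect_equal(s2$cns, rep(2L, 6))
  expect_equal(s2$total, rep(4L, 6))

  # vitals-only stay: total = respiration + cardiovascular + CNS
  tl3 <- flat_timeline(6, override = list(gcs = 11, nidiasabp = 40,
                                          nisysabp = 85, spo2 = 80))
  s3 <- hourly_sofa(tl3)
  expect_equal(s3$total, s3$respiration + s3$cardiovascular + s3$cns)
  expect_equal(s3$coagulation + s3$liver + s3$renal, rep(0L, 6))
})

test_that("SOFA subscores match an independent band oracle", {
  withr::with_seed(501, {
    for (rep in 1:200) {
      spo2 <- runif(1, 60, 100)
      fio2 <- runif(1, 0.21, 1)
      plt <- runif(1, 5, 400)
      bili <- runif(1, 0.1, 20)
      sys <- runif(1, 60, 180)
      dias <- runif(1, 30, 100)
      gcs <- sample(3:15, 1)
      crea <- runif(1, 0.3, 8)
      obs <- data.frame(
        time_h = rep(0.5, 8),
        channel = c("spo2", "fio2", "platelets", "bilirubin", "nisysabp",
                    "nidiasabp", "gcs", "creatinine"),
        value = c(spo2, fio2, plt, bili, sys, dias, gcs, crea))
      s <- hourly_sofa(build_stay_timeline(obs, 1))
      want <- oracle_sofa_subscores(spo2 / fio2, plt, bili,
                                    dias + (sys - dias) / 3, gcs, crea)
      got <- unlist(s[1, c("respiration", "coagulation", "liver",
                           "cardiovascular", "cns", "renal")])
      expect_equal(unname(got), unname(want))
      expect_true(s$total[1] >= 0 && s$total[1] <= 24)
    }
  })
})

test_that("onset detection scans the clamped window for a +2 rise", {
  # flat series: never septic
  lab <- detect_onset(rep(3L, 40), suspicion_hour = 10L)
  expect_false(lab$is_septic)
  expect_equal(lab$baseline_sofa, 3L)

  # baseline 2 at window start, rises to 4 at the third window hour
  tot <- c(2, 2, 4, 5, rep(5, 30))
  lab <- detect_onset(tot, suspicion_hour = 0L)
  expect_true(lab$is_septic)
  expect_equal(lab$onset_hour, 2L)

  # rise only 30 h after suspicion: outside the +24 h window
  tot <- c(rep(2, 31), rep(4, 10))
  lab <- detect_onset(tot, suspicion_hour = 0L)
  expect_false(lab$is_septic)

  # no suspicion: nonseptic with empty fields
  lab <- detect_onset(rep(0L, 10), NA_integer_)
  expect_false(lab$is_septic)
  expect_true(is.na(lab$onset_hour))

  # window start clamped to data availability
  lab <- detect_onset(c(0, rep(2, 30)), suspicion_hour = 10L)
  expect_equal(lab$window_start_hour, 0L)
  expect_true(lab$is_septic)
  expect_equal(lab$onset_hour, 1L)
})

test_that("onset minimality: no earlier window hour satisfies the criterion", {
  withr::with_seed(88, {
    for (rep in 1:60) {
      n <- sample(20:120, 1)
      tot <- cumsum(sample(c(-1, 0, 0, 1), n, replace = TRUE))
      tot <- pmax(pmin(tot, 24), 0)
      susp <- sample(0:(n - 1), 1)
      lab <- detect_onset(tot, susp)
      if (lab$is_septic) {
        ws <- lab$window_start_hour
        base <- tot[ws + 1]
        before <- seq_len(lab$onset_hour - ws - 1) + ws
        if (length(before) > 0) {
          expect_true(all(tot[before + 1] < base + 2))
        }
        expect_gte(lab$onset_hour, lab$window_start_hour)
        expect_lte(lab$onset_hour, lab$window_end_hour)
      }
    }
  })
})

test_that("labels recompute identically from the full data", {
  # the gold standard is always derived from the full observation set, so a
  # fresh labeling pass is bit-identical no matter what thinning happened to
  # other copies of the data
  fx <- labeled_cohort(60, 31)
  labs2 <- label_cohort(fx$cohort, build_timelines(fx$cohort))
  expect_identical(labs2, fx$labels)
})

test_that("inclusion filters apply sequentially with counts", {
  fx <- labeled_cohort(120, 55)
  inc <- fx$include
  expect_equal(inc$exclusions$filter,
               c("age_under_15", "no_icu_measurements",
                 "predictor_never_recorded", "onset_outside_7_500h"))
  expect_equal(nrow(fx$cohort$stays) - sum(inc$exclusions$n_excluded),
               length(inc$stay_ids))
  # age filter catches the pediatric stays
  ped <- fx$cohort$stays$stay_id[fx$cohort$stays$age_years < 15]
  expect_true(all(!ped %in% inc$stay_ids))

  # a septic stay with onset before hour 7 is excluded
  labs <- fx$labels
  labs$onset_hour[match(inc$stay_ids[1], labs$stay_id)] <- 6L
  inc2 <- apply_inclusion_criteria(fx$cohort, labs)
  expect_false(inc$stay_ids[1] %in% inc2$stay_ids)

  # nonseptic adult with all channels observed passes through
  expect_true(length(inc$stay_ids) > 0)
})

test_that("pre-ICU antibiotic exclusion drops only flagged stays", {
  fx <- labeled_cohort(120, 55)
  inc_off <- fx$include
  inc_on <- apply_inclusion_criteria(fx$cohort, fx$labels,
                                     exclude_pre_icu_abx = TRUE)
  ev <- as.data.frame(fx$cohort$events)
  pre <- unique(ev$stay_id[ev$event_type == "antibiotic" & ev$time_h < 0])
  expect_setequal(setdiff(inc_off$stay_ids, inc_on$stay_ids),
                  intersect(pre, inc_off$stay_ids))
  # labels of retained stays are untouched by the option
  expect_identical(
    fx$labels[match(inc_on$stay_ids, fx$labels$stay_id), ],
    fx$labels[match(inc_on$stay_ids, fx$labels$stay_id), ])
})
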