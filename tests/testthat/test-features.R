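make_labels <- function(ids, septic, onset = NA) {
  data.frame(stay_id = ids, is_septic = septic, onset_hour = onset)
}

test_that("prediction hours anchor to onset for septic stays", {
  labs <- make_labels(c("a", "b"), c(TRUE, TRUE), c(10L, 10L))
  nh <- c(a = 20L, b = 20L)
  expect_equal(unname(select_sample_times(labs, nh, 4)), c(6L, 6L))
  expect_equal(unname(select_sample_times(labs, nh, 0)), c(10L, 10L))
})

test_that("nonseptic prediction hours are uniform, eligible, reproducible", {
  ids <- sprintf("s%02d", 1:40)
  labs <- make_labels(ids, rep(FALSE, 40))
  nh <- stats::setNames(rep(12L, 40), ids)
  t1 <- select_sample_times(labs, nh, 0, seed = 5)
  t2 <- select_sample_times(labs, nh, 0, seed = 5)
  expect_identical(t1, t2)                      # seeded replay
  expect_true(all(t1 >= 7 & t1 <= 12))          # horizon-0 floor is 7
  t3 <- select_sample_times(labs, nh, 4, seed = 5)
  expect_true(all(t3 >= 3 & t3 <= 12))          # floor max(2, 7 - 4) = 3
  expect_false(identical(unname(t1), unname(select_sample_times(
    labs, nh, 0, seed = 6))))                   # different seed, new draw
})

test_that("too-short stays are refused", {
  labs <- make_labels("a", FALSE)
  expect_error(select_sample_times(labs, c(a = 1L), 4),
               "insufficient history")
})

test_that("1-D posterior maps apply the shrinkage formula", {
  # one bin with n1 = 3, n0 = 1, prior 0.25, alpha 1: (3 + 0.25) / (4 + 1)
  values <- c(1, 1.1, 0.9, 1.05, rep(5, 12))
  labels <- c(1, 1, 1, 0, 1, rep(0, 11))
  map <- fit_posterior_1d(values, labels, n_bins = 2, alpha = 1)
  expect_equal(map$prior, 0.25)
  expect_equal(map$posterior[1], (3 + 1 * 0.25) / (4 + 1))

  # label-independent feature: every bin near the prior
  withr::with_seed(9, {
    v <- rnorm(4000)
    y <- rbinom(4000, 1, 0.3)
    m2 <- fit_posterior_1d(v, y, n_bins = 10, alpha = 10)
    expect_true(all(abs(m2$posterior - mean(y)) < 0.12))
  })

  # perfectly separated clusters: high posterior only in the class-1 region
  v <- c(rnorm(200, -5, 0.3), rnorm(200, 5, 0.3))
  y <- rep(c(0, 1), each = 200)
  m3 <- fit_posterior_1d(v, y, n_bins = 4, alpha = 1)
  expect_gt(eval_posterior_1d(m3, 5), 0.9)
  expect_lt(eval_posterior_1d(m3, -5), 0.1)
})

test_that("1-D posterior evaluation is continuous and inside (0,1)", {
  withr::with_seed(10, {
    v <- rt(500, df = 3)
    y <- rbinom(500, 1, plogis(v))
    map <- fit_posterior_1d(v, y)
    xs <- seq(min(v) - 1, max(v) + 1, length.out = 2000)
    p <- eval_posterior_1d(map, xs)
    expect_true(all(p > 0 & p < 1))
    # no jump exceeds what the linear interpolation slope allows
    expect_true(max(abs(diff(p))) <
                  max(abs(diff(map$posterior))) + 1e-12)
    # constant extrapolation beyond the outermost centers
    expect_equal(eval_posterior_1d(map, min(v) - 10),
                 eval_posterior_1d(map, min(v) - 100))
  })
})

test_that("single-class training degenerates to a warned prior map", {
  expect_warning(m <- fit_posterior_1d(rnorm(20), rep(0, 20)),
                 "single-class")
  expect_true(all(m$posterior > 0 & m$posterior < 1))
})

test_that("posterior tables match a brute-force per-cell count oracle", {
  withr::with_seed(12, {
    for (rep in 1:20) {
      n <- 300
      d <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
      y <- rbinom(n, 1, 0.3)
      combo <- if (rep %% 2 == 0) c("a", "b") else c("a", "b", "c")
      tab <- fit_posterior_table(d, y, combo, bins_per_var = 3, alpha = 2)
      got <- eval_posterior_table(tab, d)
      # brute force: assign each row to its joint cell by the stored breaks,
      # then recount
      key <- apply(vapply(combo, function(ch)
        findInterval(d[, ch], tab$breaks[[ch]]), numeric(n)), 1,
        paste, collapse = "/")
      pri <- mean(y)
      want <- vapply(seq_len(n), function(i) {
        sel <- key == key[i]
        (sum(y[sel]) + 2 * pri) / (sum(sel) + 2)
      }, numeric(1))
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("empty table cells equal the training prevalence exactly", {
  d <- matrix(c(rep(0, 50), rep(1, 50), rep(0, 100)), 100, 2,
              dimnames = list(NULL, c("a", "b")))
  y <- rep(c(0, 1), 50)
  tab <- fit_posterior_table(d, y, c("a", "b"), bins_per_var = 2, alpha = 5)
  occupied <- unique(vitalsep:::table_cell_index(d, tab$breaks, tab$dims))
  empty <- setdiff(seq_len(prod(tab$dims)), occupied)
  expect_true(length(empty) > 0)
  expect_true(all(tab$posterior[empty] == mean(y)))
})

test_that("a pure cell tends to 1 as the smoothing vanishes", {
  d <- matrix(rep(c(0, 10), each = 40), 80, 2,
              dimnames = list(NULL, c("a", "b")))
  y <- rep(c(0, 1), each = 40)
  tab <- fit_posterior_table(d, y, c("a", "b"), bins_per_var = 2,
                             alpha = 1e-9)
  expect_gt(max(tab$posterior), 1 - 1e-9)
})

test_that("the default feature vector has length 86 with age in x1 only", {
  fx <- labeled_cohort(60, 31)
  ids <- fx$include$stay_ids
  labs <- fx$labels[match(ids, fx$labels$stay_id), ]
  nh <- vapply(fx$timelines, function(tl) tl$n_hours, integer(1))
  t <- select_sample_times(labs, nh, 0, seed = 3)
  ages <- stats::setNames(fx$cohort$stays$age_years, fx$cohort$stays$stay_id)
  win <- extract_window(fx$timelines, t, ages)
  y <- as.integer(labs$is_septic)
  fm <- fit_feature_model(win$x1, win$x2, y)
  xi <- build_feature_matrix(fm, win$x1, win$x2)

  expect_equal(ncol(xi), 86)            # 8 + 7 + 8 + 7 + 21 + 35
  expect_equal(length(fm$layout), 86)
  expect_equal(sum(grepl("age", fm$layout)), 2)     # z_x1_age and p_x1_age
  expect_false(any(grepl("z_x2_age|dx_age", fm$layout)))

  # deltas are exact differences
  dyn <- win$x1[, colnames(win$x2)] - win$x2
  expect_identical(dim(dyn), dim(win$x2))
  # every posterior feature strictly inside (0,1)
  post <- xi[, grepl("^p_", colnames(xi))]
  expect_true(all(post > 0 & post < 1))
})

test_that("feature fitting uses training rows only", {
  fx <- labeled_cohort(60, 31)
  ids <- fx$include$stay_ids
  labs <- fx$labels[match(ids, fx$labels$stay_id), ]
  nh <- vapply(fx$timelines, function(tl) tl$n_hours, integer(1))
  t <- select_sample_times(labs, nh, 0, seed = 3)
  ages <- stats::setNames(fx$cohort$stays$age_years, fx$cohort$stays$stay_id)
  win <- extract_window(fx$timelines, t, ages)
  y <- as.integer(labs$is_septic)
  # stratified half-split so both halves contain both classes
  pos <- which(y == 1); neg <- which(y == 0)
  half <- sort(c(pos[seq(1, length(pos), 2)], neg[seq(1, length(neg), 2)]))
  fm_train <- fit_feature_model(win$x1[half, ], win$x2[half, ], y[half])
  fm_test <- fit_feature_model(win$x1[-half, ], win$x2[-half, ], y[-half])
  # refitting on the held-out rows yields different objects
  expect_false(identical(fm_train$std_x1, fm_test$std_x1))
  expect_false(identical(fm_train$maps_x1[["heart_rate"]]$posterior,
                         fm_test$maps_x1[["heart_rate"]]$posterior))
  # and evaluating the training-fold model is deterministic
  expect_identical(build_feature_matrix(fm_train, win$x1, win$x2),
                   build_feature_matrix(fm_train, win$x1, win$x2))
})

test_that("an all-missing required channel is refused", {
  tl <- flat_timeline(12, absent = "spo2")
  labs <- make_labels("flat", FALSE)
  expect_error(
    extract_window(list(flat = tl), c(flat = 5L), c(flat = 50)),
    "incomplete stay")
})
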