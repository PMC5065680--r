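# Shared fixtures, built lazily and memoized so expensive synthetic cohorts
# are generated (and labeled) once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

labeled_cohort <- function(n_stays, seed) {
  fixture(sprintf("cohort_%d_%d", n_stays, seed), function() {
    cohort <- generate_cohort(synth_config(n_stays = n_stays, seed = seed))
    timelines <- build_timelines(cohort)
    labels <- label_cohort(cohort, timelines)
    include <- apply_inclusion_criteria(cohort, labels)
    list(cohort = cohort, timelines = timelines, labels = labels,
         include = include)
  })
}

# A minimal hand-built timeline: every channel constant at a normal value
# over n_hours, with selected channels overridden (NULL = channel absent).
flat_timeline <- function(n_hours = 12,
                          override = list(),
                          absent = character(0)) {
  normal <- list(heart_rate = 80, resp_rate = 14, temperature = 37,
                 spo2 = 98, gcs = 15, nisysabp = 120, nidiasabp = 70)
  normal[absent] <- NULL
  for (ch in names(override)) normal[[ch]] <- override[[ch]]
  obs <- do.call(rbind, lapply(names(normal), function(ch) {
    v <- rep_len(normal[[ch]], n_hours)
    data.frame(time_h = seq_len(n_hours) - 0.5, channel = ch, value = v)
  }))
  build_stay_timeline(obs, n_hours, stay_id = "flat")
}

# Independent banded-lookup oracles for the comparator scores, written
# directly from the published tables (kept separate from the package's
# band_points machinery on purpose).
oracle_mews <- function(sbp, hr, rr, temp, gcs) {
  p <- 0
  p <- p + if (sbp < 71) 3 else if (sbp < 81) 2 else if (sbp < 101) 1
    else if (sbp < 200) 0 else 2
  p <- p + if (hr < 41) 2 else if (hr < 51) 1 else if (hr < 101) 0
    else if (hr < 111) 1 else if (hr < 130) 2 else 3
  p <- p + if (rr < 9) 2 else if (rr < 15) 0 else if (rr < 21) 1
    else if (rr < 30) 2 else 3
  p <- p + if (temp < 35) 2 else if (temp < 38.5) 0 else 2
  p <- p + if (gcs >= 15) 0 else if (gcs >= 9) 1 else if (gcs >= 4) 2 else 3
  p
}

oracle_saps2_physio <- function(hr, sbp, temp, gcs, age) {
  p_age <- if (age < 40) 0 else if (age < 60) 7 else if (age < 70) 12
    else if (age < 75) 15 else if (age < 80) 16 else 18
  p_hr <- if (hr < 40) 11 else if (hr < 70) 2 else if (hr < 120) 0
    else if (hr < 160) 4 else 7
  p_sbp <- if (sbp < 70) 13 else if (sbp < 100) 5 else if (sbp < 200) 0
    else 2
  p_temp <- if (temp < 39) 0 else 3
  p_gcs <- if (gcs < 6) 26 else if (gcs < 9) 13 else if (gcs < 11) 7
    else if (gcs < 14) 5 else 0
  p_age + p_hr + p_sbp + p_temp + p_gcs
}

oracle_sofa_subscores <- function(spo2_fio2, platelets, bilirubin, map,
                                  gcs, creatinine) {
  resp <- if (spo2_fio2 > 400) 0 else if (spo2_fio2 > 315) 1
    else if (spo2_fio2 > 235) 2 else if (spo2_fio2 > 150) 3 else 4
  coag <- if (platelets >= 150) 0 else if (platelets >= 100) 1
    else if (platelets >= 50) 2 else if (platelets >= 20) 3 else 4
  liver <- if (bilirubin < 1.2) 0 else if (bilirubin < 2) 1
    else if (bilirubin < 6) 2 else if (bilirubin < 12) 3 else 4
  cardio <- if (map < 70) 1 else 0
  cns <- if (gcs >= 15) 0 else if (gcs >= 13) 1 else if (gcs >= 10) 2
    else if (gcs >= 6) 3 else 4
  renal <- if (creatinine < 1.2) 0 else if (creatinine < 2) 1
    else if (creatinine < 3.5) 2 else if (creatinine < 5) 3 else 4
  c(respiration = resp, coagulation = coag, liver = liver,
    cardiovascular = cardio, cns = cns, renal = renal)
}

# Brute-force pairwise-concordance AUROC (rank statistic, ties = 1/2).
oracle_auc_concordance <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exhaustive average-precision: step over every distinct threshold.
oracle_apr <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0
  prev_recall <- 0
  for (t in thr) {
    sel <- scores >= t
    recall <- sum(labels[sel] == 1) / n_pos
    precision <- sum(labels[sel] == 1) / sum(sel)
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}
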