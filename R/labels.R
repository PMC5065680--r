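#' Qualifying suspicion-of-infection times
#'
#' Suspicion of infection is defined retrospectively by the co-occurrence of
#' a culture draw and an antibiotic administration: a pair qualifies when the
#' culture falls within 72 hours after the antibiotic, or the antibiotic
#' falls within 24 hours after the culture. Each qualifying pair contributes
#' the time of its first event; times are floored to their hourly bin.
#'
#' @param antibiotic_times_h,culture_times_h sorted event times in hours
#'   since ICU start (antibiotics may be negative: pre-ICU doses).
#' @return sorted unique integer hours of qualifying first events (empty if
#'   none qualify).
#' @export
suspicion_hours <- function(antibiotic_times_h, culture_times_h) {
  abx <- antibiotic_times_h
  cult <- culture_times_h
  cand <- numeric(0)
  for (a in abx) {
    if (any(cult >= a & cult <= a + 72)) cand <- c(cand, a)
  }
  for (cu in cult) {
    if (any(abx >= cu & abx <= cu + 24)) cand <- c(cand, cu)
  }
  sort(unique(as.integer(floor(cand))))
}

#' Earliest suspicion hour, or NA
#'
#' @inheritParams suspicion_hours
#' @return the earliest qualifying first-event hour, or `NA` if no
#'   culture/antibiotic pair qualifies.
#' @export
find_suspicion_hour <- function(antibiotic_times_h, culture_times_h) {
  h <- suspicion_hours(antibiotic_times_h, culture_times_h)
  if (length(h) == 0) NA_integer_ else h[1]
}

#' Detect sepsis onset around one suspicion time
#'
#' Scans a window from up to 48 hours before the suspicion time (clamped to
#' the first hour with data) to 24 hours after it (clamped to ICU
#' departure). The total SOFA at the window start is the baseline; the first
#' hour strictly after the window start whose total is at least baseline + 2
#' is the onset of sepsis.
#'
#' @param sofa_total integer vector of hourly total SOFA, element `h + 1`
#'   being hour `h` (0-based).
#' @param suspicion_hour integer suspicion hour, or `NA`.
#' @param data_start_hour first hour with data (0 unless truncated).
#' @param icu_end_hour last hour of the stay (0-based).
#' @return list with `is_septic`, `suspicion_hour`, `window_start_hour`,
#'   `window_end_hour`, `baseline_sofa`, `onset_hour` (the latter `NA` when
#'   nonseptic).
#' @export
detect_onset <- function(sofa_total, suspicion_hour,
                         data_start_hour = 0L,
                         icu_end_hour = length(sofa_total) - 1L) {
  empty <- list(is_septic = FALSE, suspicion_hour = NA_integer_,
                window_start_hour = NA_integer_, window_end_hour = NA_integer_,
                baseline_sofa = NA_integer_, onset_hour = NA_integer_)
  if (is.na(suspicion_hour)) return(empty)
  ws <- max(suspicion_hour - 48L, data_start_hour)
  we <- min(suspicion_hour + 24L, icu_end_hour)
  ws <- min(ws, icu_end_hour)
  baseline <- sofa_total[ws + 1L]
  onset <- NA_integer_
  hs <- if (we > ws) seq.int(ws + 1L, we) else integer(0)
  for (h in hs) {
    if (sofa_total[h + 1L] >= baseline + 2L) { onset <- h; break }
  }
  list(is_septic = !is.na(onset), suspicion_hour = as.integer(suspicion_hour),
       window_start_hour = as.integer(ws), window_end_hour = as.integer(we),
       baseline_sofa = as.integer(baseline), onset_hour = onset)
}

#' Label one stay under the Sepsis-3 gold standard
#'
#' Combines the suspicion rule and the onset scan. With
#' `try_later_suspicion_windows` (the default) qualifying suspicion times
#' are evaluated in chronological order and the first window that yields an
#' onset defines the label; otherwise only the earliest suspicion time is
#' used.
#'
#' @param timeline a `vs_timeline`.
#' @param antibiotic_times_h,culture_times_h event times for the stay.
#' @param config a [vs_config()].
#' @return one-row data.frame: `stay_id`, `is_septic`, `suspicion_hour`,
#'   `onset_hour`, `baseline_sofa`, `window_start_hour`, `window_end_hour`.
#' @export
label_stay <- function(timeline, antibiotic_times_h, culture_times_h,
                       config = vs_config()) {
  total <- hourly_sofa(timeline, config)$total
  cand <- suspicion_hours(antibiotic_times_h, culture_times_h)
  if (!config$try_later_suspicion_windows && length(cand) > 0) {
    cand <- cand[1]
  }
  lab <- detect_onset(total, NA_integer_)
  for (s in cand) {
    lab <- detect_onset(total, s, 0L, timeline$n_hours - 1L)
    if (lab$is_septic) break
  }
  data.frame(stay_id = timeline$stay_id, is_septic = lab$is_septic,
             suspicion_hour = lab$suspicion_hour, onset_hour = lab$onset_hour,
             baseline_sofa = lab$baseline_sofa,
             window_start_hour = lab$window_start_hour,
             window_end_hour = lab$window_end_hour)
}

#' Label every stay of a cohort
#'
#' The gold standard is always computed on the full observation set, never
#' on thinned (dropout) data, so labels are stable across robustness
#' experiments.
#'
#' @param cohort a [vs_cohort()].
#' @param timelines timelines from [build_timelines()] on the full data.
#' @param config a [vs_config()].
#' @return data.frame of per-stay labels (see [label_stay()]).
#' @export
label_cohort <- function(cohort, timelines, config = vs_config()) {
  ev <- cohort$events
  abx_by <- split(ev[ev$event_type == "antibiotic"]$time_h,
                  ev[ev$event_type == "antibiotic"]$stay_id)
  cult_by <- split(ev[ev$event_type == "culture"]$time_h,
                   ev[ev$event_type == "culture"]$stay_id)
  rows <- lapply(timelines, function(tl) {
    label_stay(tl, sort(abx_by[[tl$stay_id]] %||% numeric(0)),
               sort(cult_by[[tl$stay_id]] %||% numeric(0)), config)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the sequential cohort inclusion filters
#'
#' Mirrors the study inclusion flow: stays are excluded, in order, when the
#' patient is younger than 15 years; when no extended-vital measurement was
#' recorded in the ICU; when any of the eight predictor measurements was
#' never recorded during the stay; when the stay is septic with onset less
#' than 7 or more than 500 hours into the stay; and optionally when any
#' antibiotic was administered before ICU start.
#'
#' @param cohort a [vs_cohort()].
#' @param labels labels from [label_cohort()] (computed on full data).
#' @param exclude_pre_icu_abx also drop stays with a pre-ICU antibiotic
#'   event (time < 0).
#' @return list with `stay_ids` (included), `exclusions` (data.frame
#'   `filter`, `n_excluded`, `n_remaining` in application order), and
#'   `prevalence` among included stays.
#' @export
apply_inclusion_criteria <- function(cohort, labels,
                                     exclude_pre_icu_abx = FALSE) {
  stays <- cohort$stays
  obs <- cohort$observations
  keep <- stays$stay_id
  counts <- list()
  note <- function(name, excluded) {
    excluded <- intersect(excluded, keep)
    counts[[length(counts) + 1]] <<- data.frame(
      filter = name, n_excluded = length(excluded),
      n_remaining = length(keep) - length(excluded))
    keep <<- setdiff(keep, excluded)
  }

  note("age_under_15",
       stays$stay_id[stays$age_years < 15])

  vit <- obs[obs$channel %in% vital_channels()]
  has_any <- unique(vit$stay_id)
  note("no_icu_measurements", setdiff(keep, has_any))

  per <- function(chs) unique(vit$stay_id[vit$channel %in% chs])
  covered <- Reduce(intersect, list(
    per("heart_rate"), per("resp_rate"), per("temperature"),
    per("spo2"), per("gcs"),
    per(c("sysabp", "nisysabp")), per(c("diasabp", "nidiasabp"))))
  note("predictor_never_recorded", setdiff(keep, covered))

  lab <- labels[match(keep, labels$stay_id), ]
  bad_onset <- keep[!is.na(lab$onset_hour) &
                      (lab$onset_hour < 7 | lab$onset_hour > 500)]
  note("onset_outside_7_500h", bad_onset)

  if (exclude_pre_icu_abx) {
    ev <- cohort$events
    pre <- unique(ev[ev$event_type == "antibiotic" & ev$time_h < 0]$stay_id)
    note("pre_icu_antibiotics", intersect(keep, pre))
  }

  lab_keep <- labels[match(keep, labels$stay_id), ]
  list(stay_ids = keep,
       exclusions = do.call(rbind, counts),
       prevalence = mean(lab_keep$is_septic))
}
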