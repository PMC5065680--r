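#' Quick SOFA (qSOFA)
#'
#' One point each for respiration above 22/min, systolic blood pressure
#' below 100 mm Hg, and altered mentation (operationalized as GCS below 15,
#' the only mentation channel carried). A screen of 2 or more is positive.
#'
#' @param rr respiration rate, /min.
#' @param sbp systolic blood pressure, mm Hg.
#' @param gcs Glasgow Coma Score.
#' @return integer 0-3 (vectorized); missing inputs do not score.
#' @export
qsofa <- function(rr, sbp, gcs) {
  crit <- function(x) ifelse(is.na(x), 0L, as.integer(x))
  crit(rr > 22) + crit(sbp < 100) + crit(gcs < 15)
}

#' SIRS criteria count
#'
#' Canonical criteria: temperature above 38 or below 36 C; heart rate above
#' 90/min; respiration above 20/min or PaCO2 below 32 mm Hg; white cell
#' count above 12 or below 4 (10^3/uL). Missing inputs count as "criterion
#' not met".
#'
#' @param temp temperature, C.
#' @param hr heart rate, /min.
#' @param rr respiration rate, /min.
#' @param paco2 optional arterial CO2 tension, mm Hg.
#' @param wbc optional white cell count, 10^3/uL.
#' @return integer 0-4 (vectorized).
#' @export
sirs <- function(temp, hr, rr, paco2 = NA_real_, wbc = NA_real_) {
  tab <- score_table("sirs")
  crit <- function(x) ifelse(is.na(x), 0L, as.integer(x))
  crit(temp > tab$temp_hi | temp < tab$temp_lo) +
    crit(hr > tab$hr_hi) +
    crit(rr > tab$rr_hi | paco2 < tab$paco2_lo) +
    crit(wbc > tab$wbc_hi | wbc < tab$wbc_lo)
}

#' AVPU consciousness level from GCS
#'
#' Mapping: GCS 15 is Alert; 9-14 responds to Voice; 4-8 responds to Pain;
#' 3 is Unresponsive.
#'
#' @param gcs Glasgow Coma Score.
#' @return character vector of `"alert"`, `"voice"`, `"pain"`,
#'   `"unresponsive"`.
#' @export
avpu_from_gcs <- function(gcs) {
  out <- rep(NA_character_, length(gcs))
  out[gcs >= 15] <- "alert"
  out[gcs >= 9 & gcs < 15] <- "voice"
  out[gcs >= 4 & gcs < 9] <- "pain"
  out[gcs <= 3] <- "unresponsive"
  out
}

#' Modified Early Warning Score (MEWS)
#'
#' Sum of the five published component bands (systolic blood pressure, heart
#' rate, respiration rate, temperature, AVPU level derived from GCS).
#'
#' @param sbp systolic blood pressure, mm Hg.
#' @param hr heart rate, /min.
#' @param rr respiration rate, /min.
#' @param temp temperature, C.
#' @param gcs Glasgow Coma Score (converted to AVPU internally).
#' @return integer 0-14 (vectorized); missing inputs score 0.
#' @export
mews <- function(sbp, hr, rr, temp, gcs) {
  tab <- score_table("mews")
  avpu <- avpu_from_gcs(gcs)
  avpu_pts <- unlist(tab$avpu)[avpu]
  avpu_pts[is.na(avpu_pts)] <- 0
  as.integer(band_points(sbp, tab$sbp) + band_points(hr, tab$hr) +
               band_points(rr, tab$rr) + band_points(temp, tab$temp) +
               avpu_pts)
}

#' SAPS II at admission
#'
#' Applies the published SAPS II point bands to the worst hourly value of
#' each physiology variable inside the admission window (default first 24
#' hours), plus age points. "Worst" means the value attaining the highest
#' point total for that variable. Variables without a channel in the stay
#' score 0; chronic-disease and admission-type points default to 0.
#'
#' @param timeline a `vs_timeline`.
#' @param age_years patient age.
#' @param admission_window_h window length in hours.
#' @param chronic one of `"none"`, `"metastatic_cancer"`,
#'   `"hematologic_malignancy"`, `"aids"`.
#' @param admission one of `"scheduled_surgical"`, `"medical"`,
#'   `"unscheduled_surgical"`, or `NA` for 0 points.
#' @return integer score.
#' @export
saps2_at_admission <- function(timeline, age_years, admission_window_h = 24,
                               chronic = "none", admission = NA) {
  tab <- score_table("saps2")
  hours <- seq_len(min(timeline$n_hours, admission_window_h))
  v <- timeline$values[hours, , drop = FALSE]
  miss <- timeline$all_missing
  worst <- function(channel, band) {
    if (miss[[channel]]) return(0L)
    max(band_points(v[, channel], band))
  }
  pts <- band_points(age_years, tab$age) +
    worst("heart_rate", tab$hr) +
    worst("sys_bp", tab$sbp) +
    worst("temperature", tab$temp) +
    worst("gcs", tab$gcs) +
    worst("bilirubin", tab$bilirubin) +
    worst("wbc", tab$wbc)
  pts <- pts + (tab$chronic[[chronic]] %||% 0)
  if (!is.na(admission)) pts <- pts + (tab$admission[[admission]] %||% 0)
  as.integer(pts)
}

#' Total SOFA at admission
#'
#' The hourly total SOFA of the first bin of the imputed timeline.
#'
#' @param timeline a `vs_timeline`.
#' @param config a [vs_config()].
#' @return integer score.
#' @export
sofa_at_admission <- function(timeline, config = vs_config()) {
  hourly_sofa(timeline, config)$total[1]
}

#' Bedside scores of one stay at a given hour
#'
#' Evaluates qSOFA, SIRS and MEWS on the imputed values of hourly bin
#' `hour` (0-based). Channels never observed in the stay enter as missing.
#'
#' @param timeline a `vs_timeline`.
#' @param hour 0-based hour index.
#' @return named numeric vector with `qsofa`, `sirs`, `mews`.
#' @export
scores_at_hour <- function(timeline, hour) {
  stopifnot(hour >= 0, hour < timeline$n_hours)
  val <- function(ch) {
    if (timeline$all_missing[[ch]]) NA_real_
    else unname(timeline$values[hour + 1L, ch])
  }
  wbc <- val("wbc"); paco2 <- val("paco2")
  c(qsofa = qsofa(val("resp_rate"), val("sys_bp"), val("gcs")),
    sirs = sirs(val("temperature"), val("heart_rate"), val("resp_rate"),
                paco2, wbc),
    mews = mews(val("sys_bp"), val("heart_rate"), val("resp_rate"),
                val("temperature"), val("gcs")))
}

#' Comparator scores for a set of stays at per-stay hours
#'
#' Convenience wrapper used when benchmarking: evaluates the concurrent
#' bedside scores at each stay's sampled prediction hour (the score uses the
#' last fully elapsed hourly bin, the same bin that supplies the
#' classifier's most recent input) and the admission scores once per stay.
#'
#' @param timelines named list of `vs_timeline`.
#' @param sample_hours named integer vector: prediction hour `t` per stay.
#' @param ages named numeric vector of ages (for SAPS II).
#' @param config a [vs_config()].
#' @return data.frame: `stay_id`, `hour`, `qsofa`, `sirs`, `mews`,
#'   `sofa_admission`, `saps2_admission`.
#' @export
comparator_scores <- function(timelines, sample_hours, ages,
                              config = vs_config()) {
  rows <- lapply(names(sample_hours), function(sid) {
    tl <- timelines[[sid]]
    t <- sample_hours[[sid]]
    s <- scores_at_hour(tl, t - 1L)
    data.frame(stay_id = sid, hour = t, qsofa = s[["qsofa"]],
               sirs = s[["sirs"]], mews = s[["mews"]],
               sofa_admission = sofa_at_admission(tl, config),
               saps2_admission = saps2_at_admission(
                 tl, ages[[sid]], config$saps2_window_h))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
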