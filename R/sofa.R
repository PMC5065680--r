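score_table_env <- new.env(parent = emptyenv())

#' Load a published score banding table
#'
#' The banding tables for SOFA, MEWS, SAPS II and the SIRS thresholds are
#' shipped as versioned plain-text YAML files under
#' `inst/extdata/score_tables/` and cached after first load. Supplying
#' `path` overrides the shipped table (all cut-points are configurable).
#'
#' @param name one of `"sofa"`, `"mews"`, `"saps2"`, `"sirs"`.
#' @param path optional path to an alternative YAML table.
#' @return the parsed table as a list.
#' @export
score_table <- function(name = c("sofa", "mews", "saps2", "sirs"),
                        path = NULL) {
  name <- match.arg(name)
  if (!is.null(path)) return(yaml::read_yaml(path))
  if (is.null(score_table_env[[name]])) {
    f <- system.file("extdata", "score_tables", paste0(name, ".yaml"),
                     package = "vitalsep", mustWork = TRUE)
    score_table_env[[name]] <- yaml::read_yaml(f)
  }
  score_table_env[[name]]
}

# Banded lookup: value < breaks[1] -> points[1], ..., value >= breaks[last]
# -> points[last + 1]. NA values score 0 (missing criterion convention).
band_points <- function(value, band) {
  breaks <- as.numeric(band$breaks)
  points <- as.numeric(band$points)
  stopifnot(length(points) == length(breaks) + 1)
  p <- points[findInterval(value, breaks) + 1L]
  p[is.na(value)] <- 0
  p
}

#' Ventilation-free SOFA respiration subscore
#'
#' Scores respiratory failure from the SpO2/FiO2 ratio instead of
#' PaO2/FiO2, so no mechanical-ventilation information is needed. When FiO2
#' is unrecorded, room air (0.21) is assumed. The score is monotone
#' non-increasing in the ratio.
#'
#' @param spo2 peripheral oxygen saturation, percent, in `(0, 100]`.
#' @param fio2 inspired oxygen fraction in `[0.21, 1]`; `NA` means room air.
#' @param thresholds ratio cut-points, one per score 1-4 (score `k` when
#'   ratio `<= thresholds[k]`).
#' @return integer subscore 0-4 (vectorized).
#' @export
respiration_subscore <- function(spo2, fio2 = NA_real_,
                                 thresholds = vs_config()$spo2_fio2_thresholds) {
  fio2 <- ifelse(is.na(fio2), 0.21, fio2)
  ratio <- spo2 / fio2
  if (any(!is.na(ratio) & ratio <= 0)) stopf("SpO2/FiO2 ratio must be positive")
  score <- rowSums(outer(ratio, as.numeric(thresholds), `<=`))
  score[is.na(ratio)] <- 0
  as.integer(score)
}

# Effective mean arterial pressure for the cardiovascular subscore: measured
# MAP channel when the stay has one, otherwise the standard estimate
# diastolic + pulse pressure / 3 from the merged cuff/arterial channels.
effective_map <- function(timeline) {
  if (!timeline$all_missing[["map"]]) return(timeline$values[, "map"])
  if (!timeline$all_missing[["sys_bp"]] && !timeline$all_missing[["dias_bp"]]) {
    return(timeline$values[, "dias_bp"] +
             timeline$values[, "pulse_pressure"] / 3)
  }
  rep(NA_real_, timeline$n_hours)
}

#' Hourly SOFA breakdown for one stay
#'
#' Applies the six canonical SOFA organ subscores to the imputed hourly
#' timeline. Any subscore whose input channels were never observed during
#' the stay is set to 0 ("normal"), so a vitals-only stay is scored from
#' respiration, cardiovascular and CNS alone. Respiration uses the
#' ventilation-free SpO2/FiO2 subscore.
#'
#' @param timeline a `vs_timeline` from [build_stay_timeline()].
#' @param config a [vs_config()].
#' @return data.frame with `hour` (0-based), the six subscores, and `total`.
#' @export
hourly_sofa <- function(timeline, config = vs_config()) {
  tab <- score_table("sofa")
  v <- timeline$values
  miss <- timeline$all_missing
  n <- timeline$n_hours
  zero <- integer(n)

  resp <- if (miss[["spo2"]]) zero else {
    fio2 <- if (miss[["fio2"]]) NA_real_ else v[, "fio2"]
    respiration_subscore(v[, "spo2"], fio2, config$spo2_fio2_thresholds)
  }
  coag <- if (miss[["platelets"]]) zero else
    as.integer(band_points(v[, "platelets"], tab$coagulation))
  liver <- if (miss[["bilirubin"]]) zero else
    as.integer(band_points(v[, "bilirubin"], tab$liver))
  renal <- if (miss[["creatinine"]]) zero else
    as.integer(band_points(v[, "creatinine"], tab$renal))
  cns <- if (miss[["gcs"]]) zero else
    as.integer(band_points(v[, "gcs"], tab$cns))
  map <- effective_map(timeline)
  cardio <- ifelse(!is.na(map) & map < tab$cardiovascular$map_lo, 1L, 0L)

  data.frame(hour = seq_len(n) - 1L, respiration = resp, coagulation = coag,
             liver = liver, cardiovascular = cardio, cns = cns,
             renal = renal,
             total = resp + coag + liver + cardio + cns + renal)
}
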