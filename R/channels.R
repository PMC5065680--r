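#' Measurement channel registry
#'
#' Every raw observation carries a channel name from this registry. The nine
#' "extended vital" channels are the bedside measurements the predictor is
#' built on (invasive and noninvasive blood pressure are kept as separate
#' source channels and merged later); the lab channels are optional and only
#' feed the SOFA subscores and SAPS II.
#'
#' Plausibility bounds are physiological sanity limits used at parse time:
#' raw events outside `[lo, hi]` for their channel are rejected and counted,
#' never silently kept.
#'
#' @return A data.frame with columns `channel`, `kind`
#'   (`"vital"` or `"lab"`), `lo`, `hi`.
#' @export
channel_registry <- function() {
  reg <- rbind(
    data.frame(channel = "heart_rate",  kind = "vital", lo = 10,   hi = 300),
    data.frame(channel = "resp_rate",   kind = "vital", lo = 0,    hi = 80),
    data.frame(channel = "temperature", kind = "vital", lo = 25,   hi = 45),
    data.frame(channel = "spo2",        kind = "vital", lo = 10,   hi = 100),
    data.frame(channel = "gcs",         kind = "vital", lo = 3,    hi = 15),
    data.frame(channel = "sysabp",      kind = "vital", lo = 20,   hi = 300),
    data.frame(channel = "diasabp",     kind = "vital", lo = 5,    hi = 225),
    data.frame(channel = "nisysabp",    kind = "vital", lo = 20,   hi = 300),
    data.frame(channel = "nidiasabp",   kind = "vital", lo = 5,    hi = 225),
    data.frame(channel = "platelets",   kind = "lab",   lo = 1,    hi = 2000),
    data.frame(channel = "bilirubin",   kind = "lab",   lo = 0.05, hi = 80),
    data.frame(channel = "creatinine",  kind = "lab",   lo = 0.1,  hi = 40),
    data.frame(channel = "fio2",        kind = "lab",   lo = 0.21, hi = 1.0),
    data.frame(channel = "paco2",       kind = "lab",   lo = 5,    hi = 200),
    data.frame(channel = "wbc",         kind = "lab",   lo = 0.05, hi = 200),
    data.frame(channel = "map",         kind = "lab",   lo = 10,   hi = 250)
  )
  rownames(reg) <- NULL
  reg
}

#' Names of the extended-vital channels
#'
#' The raw bedside channels sampled at roughly hourly cadence: heart rate,
#' respiration rate, temperature, SpO2, GCS, and the four blood-pressure
#' source channels. These define "any ICU measurement" for inclusion
#' filtering, the ICU-start approximation, and the dropout experiment.
#'
#' @return character vector of channel names.
#' @export
vital_channels <- function() {
  c("heart_rate", "resp_rate", "temperature", "spo2", "gcs",
    "sysabp", "diasabp", "nisysabp", "nidiasabp")
}

# The seven dynamic predictor channels (hour-to-hour deltas are meaningful);
# age joins them as the eighth, static predictor.
dynamic_channels <- function() {
  c("sys_bp", "pulse_pressure", "heart_rate", "resp_rate",
    "temperature", "spo2", "gcs")
}

predictor_channels <- function() c(dynamic_channels(), "age")

#' Pipeline configuration
#'
#' Collects every tunable of the timeline, labeling, feature and model stages
#' in one list so that a run is fully described by (input data, config, seed).
#'
#' @param prefer_invasive_bp prefer the invasive arterial-line reading over
#'   the cuff reading when both fall in the same hourly bin.
#' @param temperature_unit `"C"` or `"F"`; Fahrenheit inputs are converted to
#'   Celsius at parse time.
#' @param try_later_suspicion_windows if the earliest qualifying
#'   culture/antibiotic pair yields no onset, evaluate later qualifying pairs
#'   in chronological order.
#' @param spo2_fio2_thresholds named numeric vector: ratio cut-points for the
#'   ventilation-free respiration subscore (score `k` is assigned when the
#'   SpO2/FiO2 ratio is at or below `thresholds[k]`).
#' @param n_bins_1d quantile bins for one-dimensional posterior maps.
#' @param n_bins_table per-variable quantile bins for 2-/3-way posterior
#'   tables.
#' @param alpha_1d,alpha_table pseudo-count strength of the shrinkage toward
#'   training prevalence in the posterior estimates.
#' @param pairs,triples either `"all"` or a list of channel-name vectors
#'   restricting which delta combinations get tabular posteriors.
#' @param enet_alpha candidate elastic-net mixing parameters for the inner
#'   hyperparameter search.
#' @param enet_nlambda number of penalty strengths on the automatic
#'   logarithmic path.
#' @param inner_folds folds of the inner cross-validation used to pick the
#'   penalty.
#' @param saps2_window_h length of the admission window over which SAPS II
#'   takes worst values.
#' @return a list of class `vs_config`.
#' @export
vs_config <- function(prefer_invasive_bp = TRUE,
                      temperature_unit = c("C", "F"),
                      try_later_suspicion_windows = TRUE,
                      spo2_fio2_thresholds = c(`1` = 400, `2` = 315,
                                               `3` = 235, `4` = 150),
                      n_bins_1d = 20,
                      n_bins_table = 5,
                      alpha_1d = 10,
                      alpha_table = 10,
                      pairs = "all",
                      triples = "all",
                      enet_alpha = c(0.1, 0.5, 0.9),
                      enet_nlambda = 20,
                      inner_folds = 3,
                      saps2_window_h = 24) {
  temperature_unit <- match.arg(temperature_unit)
  stopifnot(length(spo2_fio2_thresholds) == 4,
            all(diff(spo2_fio2_thresholds) < 0))
  structure(list(
    registry = channel_registry(),
    prefer_invasive_bp = prefer_invasive_bp,
    temperature_unit = temperature_unit,
    try_later_suspicion_windows = try_later_suspicion_windows,
    spo2_fio2_thresholds = spo2_fio2_thresholds,
    n_bins_1d = n_bins_1d,
    n_bins_table = n_bins_table,
    alpha_1d = alpha_1d,
    alpha_table = alpha_table,
    pairs = pairs,
    triples = triples,
    enet_alpha = enet_alpha,
    enet_nlambda = enet_nlambda,
    inner_folds = inner_folds,
    saps2_window_h = saps2_window_h
  ), class = "vs_config")
}
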