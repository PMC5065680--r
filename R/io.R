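#' Assemble and validate an ICU cohort
#'
#' A cohort bundles the three long-format tables the pipeline consumes:
#' per-stay metadata, timestamped observations, and culture/antibiotic
#' events. Times are in real hours relative to ICU start; antibiotic events
#' may be negative (administered before ICU admission, down to -24 h), all
#' observations must fall within `[0, icu_length_h]`.
#'
#' Observations with an unknown channel or a value outside the plausibility
#' range of its channel are rejected and tallied in the `rejected` element;
#' they never enter downstream computation. Temperatures are converted to
#' Celsius when `config$temperature_unit == "F"`.
#'
#' @param stays data.frame with columns `stay_id`, `age_years`,
#'   `icu_length_h`, `death_in_hospital`.
#' @param observations data.frame with columns `stay_id`, `time_h`,
#'   `channel`, `value`.
#' @param events data.frame with columns `stay_id`, `time_h`, `event_type`
#'   (`"antibiotic"` or `"culture"`).
#' @param truth optional designed-truth table (synthetic cohorts only;
#'   never read by the pipeline itself).
#' @param config a [vs_config()].
#' @return object of class `vs_cohort`: list with elements `stays`,
#'   `observations` (data.table), `events` (data.table), `truth`,
#'   `rejected` (per-channel rejection counts).
#' @export
vs_cohort <- function(stays, observations, events,
                      truth = NULL, config = vs_config()) {
  stopifnot(all(c("stay_id", "age_years", "icu_length_h") %in% names(stays)),
            all(c("stay_id", "time_h", "channel", "value") %in%
                  names(observations)),
            all(c("stay_id", "time_h", "event_type") %in% names(events)))
  stays <- as.data.frame(stays)
  if (is.null(stays$death_in_hospital)) stays$death_in_hospital <- FALSE
  if (any(stays$icu_length_h <= 0)) stopf("icu_length_h must be positive")

  obs <- data.table::as.data.table(observations)
  obs[, stay_id := as.character(stay_id)]
  ev <- data.table::as.data.table(events)
  ev[, stay_id := as.character(stay_id)]
  stays$stay_id <- as.character(stays$stay_id)

  if (config$temperature_unit == "F") {
    obs[channel == "temperature", value := (value - 32) * 5 / 9]
  }

  reg <- config$registry
  obs <- merge(obs, data.table::as.data.table(reg), by = "channel",
               all.x = TRUE, sort = FALSE)
  bad_channel <- is.na(obs$lo)
  bad_range <- !bad_channel & (obs$value < obs$lo | obs$value > obs$hi)
  len <- stays$icu_length_h[match(obs$stay_id, stays$stay_id)]
  bad_time <- !bad_channel & !bad_range &
    (is.na(len) | obs$time_h < 0 | obs$time_h > len)
  drop <- bad_channel | bad_range | bad_time
  rejected <- data.frame(
    reason = c("unknown_channel", "out_of_range", "out_of_window"),
    n = c(sum(bad_channel), sum(bad_range), sum(bad_time))
  )
  obs <- obs[!drop, c("stay_id", "time_h", "channel", "value")]
  data.table::setkey(obs, stay_id, channel, time_h)

  ev <- ev[event_type %in% c("antibiotic", "culture")]
  data.table::setkey(ev, stay_id, event_type, time_h)

  structure(list(stays = stays, observations = obs, events = ev,
                 truth = truth, rejected = rejected),
            class = "vs_cohort")
}

#' @export
print.vs_cohort <- function(x, ...) {
  cat(sprintf("<vs_cohort> %d stays, %d observations, %d events\n",
              nrow(x$stays), nrow(x$observations), nrow(x$events)))
  if (!is.null(x$truth)) {
    cat(sprintf("  designed truth attached (%d septic)\n",
                sum(x$truth$designed_septic)))
  }
  invisible(x)
}

#' Read a cohort from its CSV directory
#'
#' Expects `stays.csv`, `observations.csv` and `events.csv` (headers
#' required, UTF-8, `.` decimal separator) and optionally `truth.csv`.
#'
#' @param dir directory containing the files.
#' @param config a [vs_config()].
#' @return a [vs_cohort()].
#' @export
read_cohort <- function(dir, config = vs_config()) {
  path <- function(f) file.path(dir, f)
  for (f in c("stays.csv", "observations.csv", "events.csv")) {
    if (!file.exists(path(f))) stopf("missing input file: %s", path(f))
  }
  truth <- NULL
  if (file.exists(path("truth.csv"))) {
    truth <- utils::read.csv(path("truth.csv"))
    truth$stay_id <- as.character(truth$stay_id)
  }
  vs_cohort(
    stays = utils::read.csv(path("stays.csv")),
    observations = utils::read.csv(path("observations.csv")),
    events = utils::read.csv(path("events.csv")),
    truth = truth, config = config
  )
}

#' Write a cohort to a CSV directory
#'
#' Inverse of [read_cohort()]; writes `stays.csv`, `observations.csv`,
#' `events.csv` and, when present, `truth.csv`.
#'
#' @param cohort a [vs_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$stays, file.path(dir, "stays.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$observations, file.path(dir, "observations.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$truth)) {
    utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

# Antibiotic / culture times for one stay, sorted.
stay_event_times <- function(cohort, stay_id, type) {
  ev <- cohort$events
  sort(ev[ev$stay_id == stay_id & ev$event_type == type, ]$time_h)
}
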