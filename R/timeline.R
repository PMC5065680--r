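timeline_channels <- function(config = vs_config()) {
  c(config$registry$channel, "sys_bp", "dias_bp", "pulse_pressure")
}

#' Approximate the ICU start time of a stay
#'
#' When no explicit ICU admission timestamp is available, the start of the
#' stay is approximated as 60 minutes before the first recorded
#' extended-vital measurement.
#'
#' @param observations data.frame with `time_h` (absolute hours) and
#'   `channel`; only extended-vital channels are considered.
#' @param explicit_start optional known ICU start; returned unchanged when
#'   supplied.
#' @return the time origin in the same units as `time_h`.
#' @export
infer_icu_start <- function(observations, explicit_start = NULL) {
  if (!is.null(explicit_start)) return(explicit_start)
  t <- observations$time_h[observations$channel %in% vital_channels()]
  if (length(t) == 0) stopf("empty stay: no extended-vital observations")
  min(t) - 1.0
}

#' Bin one channel's raw observations into hourly values
#'
#' Bins are half-open hours `[k, k+1)` anchored at ICU start; each nonempty
#' bin takes the arithmetic mean of the raw values it contains. An
#' observation at exactly the stay end falls into the last bin.
#'
#' @param time_h observation times in hours since ICU start, in `[0,
#'   n_hours]`.
#' @param value observation values.
#' @param n_hours number of hourly bins.
#' @return list with `values` (length `n_hours`, `NA` where empty) and
#'   `mask` (`TRUE` where the bin contained at least one raw observation).
#' @export
bin_hourly <- function(time_h, value, n_hours) {
  stopifnot(n_hours >= 1, length(time_h) == length(value))
  values <- rep(NA_real_, n_hours)
  if (length(time_h) > 0) {
    if (any(time_h < 0 | time_h > n_hours)) {
      stopf("observation time outside [0, n_hours]")
    }
    bin <- pmin(floor(time_h) + 1L, n_hours)
    sums <- tapply(value, bin, mean)
    values[as.integer(names(sums))] <- as.numeric(sums)
  }
  list(values = values, mask = !is.na(values))
}

#' Impute an hourly series by carry-forward and back-fill
#'
#' Empty bins after the first observed bin take the most recent observed
#' bin's value (carry-forward); bins before the first observed bin take the
#' first observed value (back-fill), so data availability is uniform across
#' the stay. A series with no observed bin at all is returned unchanged.
#'
#' @param x numeric vector with `NA` in empty bins.
#' @return numeric vector of the same length.
#' @export
impute_series <- function(x) {
  if (all(is.na(x))) return(x)
  x <- data.table::nafill(x, type = "locf")
  data.table::nafill(x, type = "nocb")
}

# Merge invasive and cuff blood-pressure bins into a single systolic /
# diastolic pair. Within each hour the preferred source's observed value
# wins; the other source fills hours the preferred one missed.
resolve_bp_bins <- function(inv_values, inv_mask, ni_values, ni_mask,
                            prefer_invasive = TRUE) {
  if (!prefer_invasive) {
    tmp <- list(inv_values, inv_mask)
    inv_values <- ni_values; inv_mask <- ni_mask
    ni_values <- tmp[[1]]; ni_mask <- tmp[[2]]
  }
  values <- ifelse(inv_mask, inv_values, ifelse(ni_mask, ni_values, NA_real_))
  list(values = values, mask = inv_mask | ni_mask)
}

new_timeline <- function(stay_id, values, mask) {
  structure(list(stay_id = stay_id, n_hours = nrow(values),
                 values = values, mask = mask,
                 all_missing = apply(mask, 2, function(m) !any(m))),
            class = "vs_timeline")
}

#' @export
print.vs_timeline <- function(x, ...) {
  cat(sprintf("<vs_timeline> stay %s, %d h, %d/%d channels observed\n",
              x$stay_id, x$n_hours, sum(!x$all_missing),
              length(x$all_missing)))
  invisible(x)
}

# Shared post-processing: given a raw binned matrix (hours x channels, NA in
# empty bins), derive merged blood pressure and pulse pressure, impute every
# channel, and wrap as a timeline.
finish_timeline <- function(stay_id, raw, mask, config) {
  bp_s <- resolve_bp_bins(raw[, "sysabp"], mask[, "sysabp"],
                          raw[, "nisysabp"], mask[, "nisysabp"],
                          config$prefer_invasive_bp)
  bp_d <- resolve_bp_bins(raw[, "diasabp"], mask[, "diasabp"],
                          raw[, "nidiasabp"], mask[, "nidiasabp"],
                          config$prefer_invasive_bp)
  raw[, "sys_bp"] <- bp_s$values;  mask[, "sys_bp"] <- bp_s$mask
  raw[, "dias_bp"] <- bp_d$values; mask[, "dias_bp"] <- bp_d$mask

  imp <- raw
  for (j in seq_len(ncol(imp))) imp[, j] <- impute_series(imp[, j])
  imp[, "pulse_pressure"] <- imp[, "sys_bp"] - imp[, "dias_bp"]
  mask[, "pulse_pressure"] <- mask[, "sys_bp"] & mask[, "dias_bp"]
  tl <- new_timeline(stay_id, imp, mask)
  # pulse pressure is defined whenever both sources were ever observed,
  # even if never inside the same bin
  tl$all_missing[["pulse_pressure"]] <-
    tl$all_missing[["sys_bp"]] || tl$all_missing[["dias_bp"]]
  tl
}

#' Build the hourly timeline of a single stay
#'
#' Bins every channel's raw observations into hourly means, merges invasive
#' and noninvasive blood pressure into `sys_bp`/`dias_bp`, derives pulse
#' pressure, and imputes each channel by carry-forward/back-fill. Channels
#' with no observation anywhere in the stay remain all-missing and are
#' flagged, never fabricated.
#'
#' @param observations data.frame of this stay's observations (`time_h`,
#'   `channel`, `value`), times relative to ICU start.
#' @param icu_length_h stay length in hours; the timeline has
#'   `ceiling(icu_length_h)` bins.
#' @param stay_id identifier stored on the result.
#' @param config a [vs_config()].
#' @return a `vs_timeline`: hours-by-channels `values` and observed-bin
#'   `mask` matrices plus an `all_missing` flag per channel.
#' @export
build_stay_timeline <- function(observations, icu_length_h,
                                stay_id = "stay", config = vs_config()) {
  if (!any(observations$channel %in% vital_channels())) {
    stopf("empty stay: no extended-vital observations")
  }
  n_hours <- as.integer(ceiling(icu_length_h))
  chans <- timeline_channels(config)
  raw <- matrix(NA_real_, n_hours, length(chans),
                dimnames = list(NULL, chans))
  for (ch in intersect(unique(observations$channel), config$registry$channel)) {
    sel <- observations$channel == ch
    b <- bin_hourly(observations$time_h[sel], observations$value[sel], n_hours)
    raw[, ch] <- b$values
  }
  finish_timeline(stay_id, raw, !is.na(raw), config)
}

#' Build timelines for every stay of a cohort
#'
#' Cohort-wide vectorized equivalent of calling [build_stay_timeline()] per
#' stay (the two paths produce identical results).
#'
#' @param cohort a [vs_cohort()].
#' @param config a [vs_config()].
#' @return named list of `vs_timeline`, one per stay with at least one
#'   extended-vital observation.
#' @export
build_timelines <- function(cohort, config = vs_config()) {
  obs <- cohort$observations
  stays <- cohort$stays
  n_hours_all <- as.integer(ceiling(stays$icu_length_h))
  names(n_hours_all) <- stays$stay_id

  tmp <- data.table::copy(obs)
  tmp[, bin := pmin(floor(time_h) + 1L, n_hours_all[stay_id])]
  agg <- tmp[, list(value = mean(value)), by = list(stay_id, channel, bin)]

  chans <- timeline_channels(config)
  split_idx <- split(seq_len(nrow(agg)), agg$stay_id)
  out <- list()
  for (sid in stays$stay_id) {
    idx <- split_idx[[sid]]
    if (is.null(idx)) next
    rows <- agg[idx]
    if (!any(rows$channel %in% vital_channels())) next
    n_hours <- n_hours_all[[sid]]
    raw <- matrix(NA_real_, n_hours, length(chans),
                  dimnames = list(NULL, chans))
    raw[cbind(rows$bin, match(rows$channel, chans))] <- rows$value
    out[[sid]] <- finish_timeline(sid, raw, !is.na(raw), config)
  }
  out
}

#' Export timelines as one wide CSV
#'
#' One row per stay-hour with a value column and an observed-mask column per
#' channel (all-missing channels export as `NA`).
#'
#' @param timelines named list from [build_timelines()].
#' @param path output CSV path.
#' @param channels channels to export; defaults to the predictor channels
#'   less age.
#' @return `path`, invisibly.
#' @export
write_timelines <- function(timelines, path,
                            channels = dynamic_channels()) {
  rows <- lapply(timelines, function(tl) {
    df <- data.frame(stay_id = tl$stay_id, hour = seq_len(tl$n_hours) - 1L)
    for (ch in channels) {
      df[[ch]] <- tl$values[, ch]
      df[[paste0(ch, "_observed")]] <- tl$mask[, ch]
    }
    df
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
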