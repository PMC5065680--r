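default_synth_channels <- function() {
  list(
    heart_rate  = list(rate = 1.07, mean = 85,  sd = 7,   between_sd = 9,
                       theta = 0.20, digits = 0, clamp = c(20, 220)),
    resp_rate   = list(rate = 1.06, mean = 16,  sd = 2.2, between_sd = 2.5,
                       theta = 0.20, digits = 0, clamp = c(4, 60)),
    spo2        = list(rate = 1.06, mean = 97,  sd = 1.2, between_sd = 1.0,
                       theta = 0.25, digits = 0, clamp = c(60, 100)),
    temperature = list(rate = 0.27, mean = 37,  sd = 0.35, between_sd = 0.25,
                       theta = 0.10, digits = 1, clamp = c(33, 42)),
    gcs         = list(rate = 0.25, mean = 15,  sd = 0.12, between_sd = 0,
                       theta = 0.15, digits = 0, clamp = c(3, 15)),
    nisysabp    = list(rate = 0.88, mean = 122, sd = 9,   between_sd = 11,
                       theta = 0.15, digits = 0, clamp = c(40, 250)),
    nidiasabp   = list(rate = 0.88, mean = 65,  sd = 6,   between_sd = 6,
                       theta = 0.15, digits = 0, clamp = c(20, 150)),
    sysabp      = list(rate = 0.90, mean = 120, sd = 9,   between_sd = 11,
                       theta = 0.15, digits = 0, clamp = c(40, 250)),
    diasabp     = list(rate = 0.90, mean = 64,  sd = 6,   between_sd = 6,
                       theta = 0.15, digits = 0, clamp = c(20, 150))
  )
}

#' Synthetic cohort configuration
#'
#' Defines the study conditions the generator emulates: per-hour observation
#' cadences near the real-data medians (heart rate, respiration and SpO2
#' about hourly; temperature and GCS every 3-4 hours; cuff pressure about
#' every 70 minutes, with an arterial line in 43 percent of stays), a
#' sepsis prevalence of 11.3 percent, a stay-length distribution with median
#' 2 days and a long tail, ages with median about 65 years, and a
#' physiologic deterioration ramp for septic stays (tachycardia +25/min,
#' tachypnea +8/min, systolic drop -25 mm Hg, diastolic drop -15 mm Hg,
#' desaturation -6 percent, fever +1.5 C, GCS -3) that completes at the
#' designed onset and is severe enough to raise the vitals-only SOFA by at
#' least 2 points over the pre-ramp baseline.
#'
#' @param n_stays number of stays.
#' @param prevalence probability a stay is designed septic.
#' @param seed master seed; every stay derives its own stream from it.
#' @param channels per-channel list: `rate` (events/h), `mean`, `sd`,
#'   `theta` (mean-reversion rate /h of the autocorrelated residual),
#'   `digits`, `clamp`.
#' @param effects named deterioration deltas added linearly over the ramp.
#' @param ramp_range_h ramp duration range (uniform draw).
#' @param effect_scale_sdlog spread (log scale) of the per-stay severity
#'   multiplier applied to the ramped deterioration effects: septic patients
#'   differ in how floridly their vitals deteriorate, so some stays present
#'   only a subtle prodrome. The multiplier is lognormal with median 1,
#'   clamped to `[0.3, 1.6]`, and never applied to the step channels that
#'   define the SOFA crossing.
#' @param step_channels channels whose deterioration is applied as a step at
#'   the designed onset instead of a ramp. Default: the GCS drop (mentation
#'   collapses acutely at onset, so the SOFA-visible CNS deterioration
#'   crosses its band exactly at the designed hour) and the diastolic
#'   channels (so the mean arterial pressure keeps a margin above the
#'   cardiovascular band until onset while systolic pressure still falls
#'   gradually through the ramp).
#' @param obs_boost observation-rate multiplier while the patient is
#'   deteriorating (clinically, deteriorating patients are reassessed more
#'   often).
#' @param onset_range_h designed onset hour range (uniform integer draw).
#' @param stay_meanlog,stay_sdlog,stay_min_h,stay_max_h lognormal stay
#'   length parameters and clamps (hours).
#' @param arterial_line_prob fraction of stays with invasive pressure.
#' @param decoy_frac fraction of nonseptic stays given a lone antibiotic
#'   event (no qualifying culture) to exercise the suspicion-window logic.
#' @param pre_icu_abx_frac fraction of stays given an additional antibiotic
#'   dose before ICU start (time < 0).
#' @param pediatric_frac fraction of stays aged under 15 (exercises the age
#'   filter).
#' @param age_mean,age_sd adult age distribution (normal, clamped 16-95).
#' @param death_prob in-hospital death probability (bookkeeping only).
#' @return list of class `vs_synth_config`.
#' @export
synth_config <- function(n_stays = 500, prevalence = 0.113, seed = 1L,
                         channels = default_synth_channels(),
                         effects = c(heart_rate = 25, resp_rate = 8,
                                     sysabp = -25, nisysabp = -25,
                                     diasabp = -15, nidiasabp = -15,
                                     spo2 = -6, temperature = 1.5,
                                     gcs = -3),
                         ramp_range_h = c(6, 12),
                         effect_scale_sdlog = 0.5,
                         step_channels = c("gcs", "diasabp", "nidiasabp"),
                         obs_boost = 2,
                         onset_range_h = c(8, 60),
                         stay_meanlog = log(48), stay_sdlog = 0.85,
                         stay_min_h = 10, stay_max_h = 590,
                         arterial_line_prob = 0.43,
                         decoy_frac = 0.10,
                         pre_icu_abx_frac = 0.05,
                         pediatric_frac = 0.02,
                         age_mean = 66, age_sd = 16,
                         death_prob = 0.07) {
  stopifnot(prevalence > 0, prevalence < 1,
            all(vapply(channels, function(ch) ch$rate > 0, logical(1))),
            ramp_range_h[1] >= 1)
  structure(as.list(environment()), class = "vs_synth_config")
}

# Autocorrelated (mean-reverting) residual sampled at irregular times.
ou_residual <- function(times, sd, theta) {
  n <- length(times)
  if (n == 0) return(numeric(0))
  r <- numeric(n)
  r[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    dt <- diff(times)
    decay <- exp(-theta * dt)
    innov_sd <- sd * sqrt(1 - decay^2)
    eps <- stats::rnorm(n - 1)
    for (k in 2:n) r[k] <- r[k - 1] * decay[k - 1] + innov_sd[k - 1] * eps[k - 1]
  }
  r
}

# Linear deterioration ramp: 0 before ramp_start, 1 from onset onward.
ramp_frac <- function(times, ramp_start, onset) {
  pmin(pmax((times - ramp_start) / (onset - ramp_start), 0), 1)
}

gen_obs_times <- function(par, len, septic, ramp_start, onset, boost,
                          extra_times = numeric(0)) {
  times <- sort(stats::runif(stats::rpois(1, par$rate * len), 0, len))
  if (septic) {
    w0 <- max(ramp_start, 0)
    w1 <- min(onset + 2, len)
    if (w1 > w0 && boost > 1) {
      n_extra <- stats::rpois(1, (boost - 1) * par$rate * (w1 - w0))
      times <- c(times, stats::runif(n_extra, w0, w1))
    }
    times <- sort(c(times, extra_times[extra_times <= len]))
  }
  times
}

gen_channel <- function(ch, par, len, septic, ramp_start, onset, effect,
                        boost, extra_times = numeric(0), step = FALSE,
                        times = NULL) {
  if (is.null(times)) {
    times <- gen_obs_times(par, len, septic, ramp_start, onset, boost,
                           extra_times)
  }
  if (length(times) == 0) return(NULL)
  baseline <- par$mean + stats::rnorm(1, 0, par$between_sd %||% 0)
  v <- baseline + ou_residual(times, par$sd, par$theta)
  if (septic && !is.na(effect)) {
    frac <- if (step) as.numeric(times >= onset)
            else ramp_frac(times, ramp_start, onset)
    v <- v + effect * frac
  }
  v <- pmin(pmax(round(v, par$digits), par$clamp[1]), par$clamp[2])
  data.frame(time_h = times, channel = ch, value = v)
}

#' Generate one synthetic ICU stay
#'
#' Vitals are mean-reverting noisy processes sampled at Poisson event times.
#' A designed-septic stay additionally gets a deterioration ramp completing
#' at the designed onset hour (with a guaranteed GCS and cuff-pressure
#' reassessment just after onset), plus a culture draw shortly before onset
#' and an antibiotic dose within the qualifying window. Nonseptic stays get
#' no sustained deterioration and no qualifying event pair; a configurable
#' fraction receives a lone decoy antibiotic.
#'
#' @param config a [synth_config()].
#' @param septic design this stay septic.
#' @param stay_id identifier.
#' @param seed per-stay seed.
#' @return list with `stay` (one-row data.frame), `observations`, `events`,
#'   `truth` (designed class and onset hour).
#' @export
generate_stay <- function(config, septic, stay_id, seed) {
  with_seed(seed, {
    len <- exp(stats::rnorm(1, config$stay_meanlog, config$stay_sdlog))
    len <- min(max(len, config$stay_min_h), config$stay_max_h)
    onset <- NA_integer_
    ramp_start <- NA_real_
    if (septic) {
      onset <- sample(seq(config$onset_range_h[1], config$onset_range_h[2]),
                      1)
      len <- max(len, onset + 6)
      ramp_start <- onset - stats::runif(1, config$ramp_range_h[1],
                                         config$ramp_range_h[2])
    }
    len <- round(len, 1)

    pediatric <- stats::runif(1) < config$pediatric_frac
    age <- if (pediatric) stats::runif(1, 1, 14) else
      min(max(stats::rnorm(1, config$age_mean, config$age_sd), 16), 95)
    has_line <- stats::runif(1) < config$arterial_line_prob

    chans <- config$channels
    active <- names(chans)
    if (!has_line) active <- setdiff(active, c("sysabp", "diasabp"))
    # systolic/diastolic pairs share measurement times: one cuff inflation
    # (noninvasive) or one transducer read-off (arterial line)
    pair_of <- c(nidiasabp = "nisysabp", diasabp = "sysabp")
    severity <- min(max(stats::rlnorm(1, 0, config$effect_scale_sdlog),
                        0.3), 1.6)
    shared_times <- list()
    obs <- list()
    for (ch in active) {
      extra <- if (septic && ch %in% c("gcs", "nisysabp")) {
        onset + c(0.3, 0.8)
      } else numeric(0)
      times <- if (ch %in% names(pair_of)) shared_times[[pair_of[[ch]]]]
               else {
                 tt <- gen_obs_times(chans[[ch]], len, septic, ramp_start,
                                     onset, config$obs_boost, extra)
                 shared_times[[ch]] <- tt
                 tt
               }
      is_step <- ch %in% config$step_channels
      obs[[ch]] <- gen_channel(ch, chans[[ch]], len, septic, ramp_start,
                               onset,
                               unname(config$effects[ch]) *
                                 (if (is_step) 1 else severity),
                               config$obs_boost, step = is_step,
                               times = times)
    }
    observations <- do.call(rbind, obs)

    events <- data.frame(time_h = numeric(0), event_type = character(0))
    if (septic) {
      culture <- onset - stats::runif(1, 1, 6)
      abx <- min(culture + stats::runif(1, 1, 12), len)
      events <- data.frame(time_h = c(abx, culture),
                           event_type = c("antibiotic", "culture"))
    } else if (stats::runif(1) < config$decoy_frac) {
      events <- data.frame(time_h = stats::runif(1, 0, len),
                           event_type = "antibiotic")
    }
    if (stats::runif(1) < config$pre_icu_abx_frac) {
      events <- rbind(events,
                      data.frame(time_h = stats::runif(1, -24, -1),
                                 event_type = "antibiotic"))
    }
    events$stay_id <- rep(stay_id, nrow(events))
    if (!is.null(observations)) observations$stay_id <- stay_id

    list(
      stay = data.frame(stay_id = stay_id, age_years = round(age, 1),
                        icu_length_h = len,
                        death_in_hospital =
                          stats::runif(1) < config$death_prob),
      observations = observations,
      events = events,
      truth = data.frame(stay_id = stay_id, designed_septic = septic,
                         designed_onset_hour = onset)
    )
  })
}

#' Generate a synthetic ICU cohort
#'
#' Draws each stay's designed class from the configured prevalence and
#' generates stays independently (each from a seed derived from the master
#' seed, so any subset is reproducible). The designed truth is attached for
#' testing only; the labeling pipeline never reads it.
#'
#' @param config a [synth_config()].
#' @param vs_cfg a [vs_config()] used to validate the assembled cohort.
#' @return a [vs_cohort()] with a `truth` table.
#' @export
generate_cohort <- function(config = synth_config(), vs_cfg = vs_config()) {
  n <- config$n_stays
  septic <- with_seed(derive_seed(config$seed, 0L),
                      stats::runif(n) < config$prevalence)
  ids <- sprintf("stay%05d", seq_len(n))
  stays <- list(); obs <- list(); ev <- list(); truth <- list()
  for (i in seq_len(n)) {
    g <- generate_stay(config, septic[i], ids[i],
                       derive_seed(config$seed, i))
    stays[[i]] <- g$stay
    obs[[i]] <- g$observations
    ev[[i]] <- g$events
    truth[[i]] <- g$truth
  }
  empty_obs <- data.frame(stay_id = character(0), time_h = numeric(0),
                          channel = character(0), value = numeric(0))
  empty_ev <- data.frame(stay_id = character(0), time_h = numeric(0),
                         event_type = character(0))
  vs_cohort(
    stays = if (n == 0) data.frame(stay_id = character(0),
                                   age_years = numeric(0),
                                   icu_length_h = numeric(0),
                                   death_in_hospital = logical(0))
            else do.call(rbind, stays),
    observations = if (length(obs) == 0) empty_obs else
      do.call(rbind, obs[!vapply(obs, is.null, logical(1))]),
    events = if (length(ev) == 0) empty_ev else do.call(rbind, ev),
    truth = if (n == 0) NULL else do.call(rbind, truth),
    config = vs_cfg
  )
}
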