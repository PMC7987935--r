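# Seeded synthetic one-week actigraphy with ground-truth sleep schedules,
# sleep diaries and questionnaire totals. The generator emulates the study
# protocol: recording from Monday 17:00 to the next Monday 08:00 at 1-min
# epochs, one consolidated nocturnal sleep bout per night, weekday sleep
# restricted by a work alarm with weekend rebound, an optional day-of-week
# work-habit perturbation, and explicit non-wear gaps.

#' Default synthetic subject profile
#'
#' Parameters of one synthetic subject. Times are minutes after midnight;
#' sleep-onset values may exceed 1,440 to mean past the following midnight.
#' Activity counts are rounded Gamma draws: wake counts follow a diurnal
#' sinusoid around `wake_activity_mean`, sleep counts a small-mean regime
#' that rounds to zero almost always. Setting `activity_shape = Inf` makes
#' counts deterministic (equal to the regime mean), which together with
#' `weekday_onset_sd = 0` gives a zero-noise subject.
#'
#' @param chronotype_offset signed minutes added to every preferred
#'   sleep-onset time (later = eveningness).
#' @param weekday_onset_mean mean weekday sleep-onset time, minutes after
#'   midnight.
#' @param weekday_onset_sd night-to-night onset jitter (minutes).
#' @param workday_wake_time alarm-driven weekday wake-up time, minutes after
#'   midnight.
#' @param weekend_rebound_true target weekend sleep rebound SRW (minutes):
#'   each weekend night sleeps this much longer than the realized weekday
#'   mean.
#' @param weekend_onset_delay extra onset delay on weekend nights (minutes).
#' @param dow_effect list with `day` (0 = Mon ... 6 = Sun), `onset_shift`
#'   (minutes added to that night's onset) and `activity_scale`
#'   (multiplier on that calendar day's wake counts).
#' @param wake_activity_mean,sleep_activity_mean mean counts/min of the wake
#'   and sleep regimes.
#' @param activity_shape Gamma shape of the count regimes (`Inf` =
#'   deterministic).
#' @param diurnal_amplitude relative amplitude of the diurnal modulation of
#'   wake counts (peak mid-afternoon).
#' @param illuminance_day,illuminance_night mean lux while awake / asleep.
#' @param nonwear_gaps list of `c(start, duration)` pairs, minutes from the
#'   recording start, flagged `wear = FALSE` with zero counts.
#' @param diary_noise_sd sd (minutes) of the Gaussian diary error,
#'   truncated to +/- 3 h.
#' @param questionnaire_tie if `TRUE`, the MEQ total decreases linearly
#'   with `chronotype_offset`; other totals are uniform in their printed
#'   ranges.
#' @return A validated profile list of class `subject_profile`.
#' @export
subject_profile <- function(chronotype_offset = 0,
                            weekday_onset_mean = 1415,
                            weekday_onset_sd = 20,
                            workday_wake_time = 345,
                            weekend_rebound_true = 60,
                            weekend_onset_delay = 30,
                            dow_effect = list(
                              day = 3L, onset_shift = 0, activity_scale = 1
                            ),
                            wake_activity_mean = 500,
                            sleep_activity_mean = 0.05,
                            activity_shape = 2,
                            diurnal_amplitude = 0.4,
                            illuminance_day = 200,
                            illuminance_night = 0.5,
                            nonwear_gaps = list(),
                            diary_noise_sd = 15,
                            questionnaire_tie = TRUE) {
  profile <- list(
    chronotype_offset = chronotype_offset,
    weekday_onset_mean = weekday_onset_mean,
    weekday_onset_sd = weekday_onset_sd,
    workday_wake_time = workday_wake_time,
    weekend_rebound_true = weekend_rebound_true,
    weekend_onset_delay = weekend_onset_delay,
    dow_effect = dow_effect,
    wake_activity_mean = wake_activity_mean,
    sleep_activity_mean = sleep_activity_mean,
    activity_shape = activity_shape,
    diurnal_amplitude = diurnal_amplitude,
    illuminance_day = illuminance_day,
    illuminance_night = illuminance_night,
    nonwear_gaps = nonwear_gaps,
    diary_noise_sd = diary_noise_sd,
    questionnaire_tie = questionnaire_tie
  )
  validate_profile(profile)
  class(profile) <- "subject_profile"
  profile
}

validate_profile <- function(p) {
  nonneg <- c(
    "weekday_onset_sd", "wake_activity_mean", "sleep_activity_mean",
    "illuminance_day", "illuminance_night", "diary_noise_sd",
    "diurnal_amplitude"
  )
  for (f in nonneg) {
    if (is.na(p[[f]]) || p[[f]] < 0) {
      stop("invalid profile: `", f, "` must be non-negative", call. = FALSE)
    }
  }
  if (p$workday_wake_time <= 0 || p$workday_wake_time >= 480) {
    stop(
      "invalid profile: `workday_wake_time` must fall inside the recorded ",
      "morning (0, 480) so the final Monday wake-up is observable",
      call. = FALSE
    )
  }
  invisible(p)
}

# evaluate a deterministic or Gamma count regime
draw_counts <- function(n, mean, shape) {
  if (n == 0L) {
    return(numeric(0))
  }
  if (mean == 0) {
    return(rep(0, n))
  }
  if (is.infinite(shape)) {
    return(rep(round(mean), n))
  }
  round(stats::rgamma(n, shape = shape, scale = mean / shape))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate one synthetic subject
#'
#' Simulates one protocol week (Monday 17:00 to next Monday 08:00, 1-min
#' epochs) for a [subject_profile()]: seven nocturnal sleep bouts with
#' night-level jitter, weekday wake fixed by the work alarm, Friday/Saturday
#' night sleeps extended so the realized weekend rebound matches
#' `weekend_rebound_true` on average, rounded-Gamma activity counts and
#' illuminance per regime, explicit non-wear gaps, a noisy sleep diary and
#' questionnaire totals. The same `(profile, seed)` pair reproduces the
#' identical recording.
#'
#' @param profile a [subject_profile()].
#' @param seed integer seed for this subject.
#' @param start_date calendar date of the first Monday.
#' @param pad_start_min,pad_end_min extra recorded minutes before Monday
#'   17:00 / after next Monday 08:00 (awake, used to exercise protocol
#'   trimming).
#' @return A list with elements `series` ([epoch_series()]), `truth` (list:
#'   `nights` data frame with per-night true `SO`/`WU`/`SD`, `SRW`,
#'   `wsd_label`, `wsd_threshold`), `diary` (per-night self-reported times)
#'   and `questionnaires` (named totals).
#' @export
generate_subject <- function(profile, seed, start_date = "2004-01-26",
                             pad_start_min = 0, pad_end_min = 0) {
  stopifnot(inherits(profile, "subject_profile"))
  validate_profile(profile)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  with_seed(seed, generate_subject_impl(
    profile, start_date, pad_start_min, pad_end_min
  ))
}

generate_subject_impl <- function(profile, start_date, pad_start_min,
                                  pad_end_min) {
  p <- profile
  monday0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  if (weekday_index(monday0) != 0L) {
    stop("`start_date` must be a Monday", call. = FALSE)
  }

  # --- true sleep schedule -------------------------------------------------
  # nights indexed by onset day 0 (Mon) .. 6 (Sun); weekday nights 0-3,
  # weekend nights 4-5, Sunday night 6 ends at the work alarm on the final
  # (partial) Monday.
  onset_base <- p$weekday_onset_mean + p$chronotype_offset
  so <- onset_base + stats::rnorm(7, 0, p$weekday_onset_sd)
  dow <- p$dow_effect
  if (!is.null(dow) && dow$onset_shift != 0) {
    so[dow$day + 1L] <- so[dow$day + 1L] + dow$onset_shift
  }
  so[5:6] <- so[5:6] + p$weekend_onset_delay
  wu <- rep(p$workday_wake_time, 7)
  sd_true <- sleep_duration(so, wu)
  sdw <- mean(sd_true[1:4])
  # extend the two weekend sleeps to hit the target rebound
  sd_true[5:6] <- sdw + p$weekend_rebound_true
  wu[5:6] <- sd_true[5:6] + so[5:6] - 1440
  nights <- data.frame(
    night = 0:6,
    SO = so, WU = wu, SD = sd_true,
    MS = mid_sleep(so, wu)
  )
  srw <- mean(sd_true[5:6]) - mean(sd_true[1:4])
  truth <- list(
    nights = nights,
    SRW = srw,
    wsd_label = srw >= WSD_THRESHOLD_MIN,
    wsd_threshold = WSD_THRESHOLD_MIN
  )

  # --- epoch grid ----------------------------------------------------------
  start_abs <- 17 * 60 - pad_start_min # minutes from Monday 00:00
  end_abs <- 7 * 1440 + 8 * 60 + pad_end_min # exclusive
  abs_min <- seq.int(start_abs, end_abs - 1L)
  n <- length(abs_min)
  asleep <- rep(FALSE, n)
  for (k in 1:7) {
    on_abs <- (k - 1L) * 1440 + nights$SO[k]
    off_abs <- k * 1440 + nights$WU[k]
    asleep <- asleep | (abs_min >= on_abs & abs_min < off_abs)
  }

  minute_of_day <- abs_min %% 1440
  day_of_week <- (abs_min %/% 1440) %% 7L
  diurnal <- 1 + p$diurnal_amplitude * cos(2 * pi * (minute_of_day - 900) / 1440)
  wake_mean <- p$wake_activity_mean * diurnal
  if (!is.null(dow) && dow$activity_scale != 1) {
    wake_mean[day_of_week == dow$day] <-
      wake_mean[day_of_week == dow$day] * dow$activity_scale
  }

  activity <- numeric(n)
  if (is.infinite(p$activity_shape)) {
    activity[!asleep] <- round(wake_mean[!asleep])
    activity[asleep] <- round(p$sleep_activity_mean)
  } else {
    nw <- sum(!asleep)
    activity[!asleep] <- round(stats::rgamma(
      nw,
      shape = p$activity_shape,
      scale = wake_mean[!asleep] / p$activity_shape
    ))
    activity[asleep] <- draw_counts(
      sum(asleep), p$sleep_activity_mean, p$activity_shape
    )
  }

  lux <- ifelse(asleep, p$illuminance_night, p$illuminance_day)
  if (!is.infinite(p$activity_shape)) {
    lux <- lux * exp(stats::rnorm(n, 0, 0.5))
  }

  wear <- rep(TRUE, n)
  for (gap in p$nonwear_gaps) {
    idx <- which(abs_min - start_abs >= gap[1] &
      abs_min - start_abs < gap[1] + gap[2])
    wear[idx] <- FALSE
    activity[idx] <- 0
    lux[idx] <- 0
  }

  series <- epoch_series(
    monday0 + 60 * abs_min,
    activity = activity, lux = lux, wear = wear
  )

  # --- diary ---------------------------------------------------------------
  diary_err <- function() {
    e <- stats::rnorm(7, 0, p$diary_noise_sd)
    pmin(pmax(e, -180), 180)
  }
  diary <- data.frame(
    night = 0:6,
    SO = nights$SO + diary_err(),
    WU = nights$WU + diary_err()
  )
  diary$SD <- sleep_duration(diary$SO, diary$WU)

  # --- questionnaire totals ------------------------------------------------
  q <- c(
    PSQI = round(stats::runif(1, 0, 21)),
    ESS = round(stats::runif(1, 0, 24)),
    SDS = round(stats::runif(1, 20, 80)),
    SRM = round(stats::runif(1, 0, 7), 1),
    MEQ = if (p$questionnaire_tie) {
      round(min(max(54 - 0.1 * p$chronotype_offset + stats::rnorm(1, 0, 5), 16), 86))
    } else {
      round(stats::runif(1, 16, 86))
    },
    SF36_PF = round(stats::runif(1, 30, 70)),
    SF36_RP = round(stats::runif(1, 30, 70)),
    SF36_BP = round(stats::runif(1, 30, 70)),
    SF36_GH = round(stats::runif(1, 30, 70)),
    SF36_VT = round(stats::runif(1, 30, 70)),
    SF36_SF = round(stats::runif(1, 30, 70)),
    SF36_RE = round(stats::runif(1, 30, 70)),
    SF36_MH = round(stats::runif(1, 30, 70))
  )

  list(series = series, truth = truth, diary = diary, questionnaires = q)
}

#' Cohort generation settings
#'
#' Settings for [generate_cohort()]: cohort size, the fraction of subjects
#' generated with a weekend rebound at or above the weekday-sleep-debt
#' threshold, the rebound regimes of the two classes (draws are kept on
#' their class's side of the threshold with a small margin), between-subject
#' chronotype spread, and an optional day-of-week onset shift applied to
#' the WSD class only (a work-habit effect).
#'
#' @param n number of subjects (>= 2).
#' @param wsd_fraction fraction of subjects in the high-rebound (WSD) class;
#'   `round(n * wsd_fraction)` subjects are generated above threshold.
#' @param rebound_wsd_mean,rebound_wsd_sd rebound regime (minutes) of the
#'   WSD class, truncated below at `wsd_threshold + margin`.
#' @param rebound_nonwsd_mean,rebound_nonwsd_sd rebound regime of the
#'   non-WSD class, truncated above at `wsd_threshold - margin`.
#' @param margin truncation margin (minutes) keeping class rebounds off the
#'   threshold.
#' @param chronotype_sd between-subject sd (minutes) of chronotype offsets.
#' @param wake_time_mean,wake_time_sd between-subject mean and sd (minutes)
#'   of the alarm-driven weekday wake-up time.
#' @param weekend_delay_wsd extra weekend sleep-onset delay (minutes) of the
#'   WSD class: subjects with weekday sleep debt shift their free-day sleep
#'   later (the social-jetlag construct), moving MSF and SJL without
#'   touching the weekday features or the rebound itself.
#' @param chronotype_shift_wsd extra mean chronotype offset (minutes) of the
#'   WSD class: an evening tendency among sleep-debt subjects, shifting all
#'   their sleep times and hence MSF.
#' @param activity_level_sd between-subject sd of the mean wake activity
#'   (counts/min, truncated at 150).
#' @param amplitude_range,lux_day_range per-subject uniform ranges of the
#'   diurnal modulation amplitude and the daytime illuminance level.
#' @param dow_day,dow_onset_shift_wsd day-of-week (0 = Mon) and onset shift
#'   (minutes) applied to that night for WSD-class subjects only; 0 disables
#'   the work-habit effect.
#' @param onset_sd,diary_noise_sd per-night onset jitter and diary noise
#'   (minutes), passed to every profile.
#' @param wsd_threshold rebound threshold (minutes) defining the label.
#' @param profile_args named list of further [subject_profile()] overrides
#'   shared by all subjects.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n, wsd_fraction = 0.5,
                          rebound_wsd_mean = 180, rebound_wsd_sd = 45,
                          rebound_nonwsd_mean = 45, rebound_nonwsd_sd = 45,
                          margin = 10,
                          chronotype_sd = 55,
                          wake_time_mean = 345, wake_time_sd = 40,
                          weekend_delay_wsd = 0,
                          chronotype_shift_wsd = 45,
                          activity_level_sd = 150,
                          amplitude_range = c(0.2, 0.6),
                          lux_day_range = c(80, 400),
                          dow_day = 3L, dow_onset_shift_wsd = 0,
                          onset_sd = 45, diary_noise_sd = 15,
                          wsd_threshold = WSD_THRESHOLD_MIN,
                          profile_args = list()) {
  if (n < 2) stop("a cohort needs n >= 2 subjects", call. = FALSE)
  if (wsd_fraction < 0 || wsd_fraction > 1) {
    stop("`wsd_fraction` must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      n = as.integer(n), wsd_fraction = wsd_fraction,
      rebound_wsd_mean = rebound_wsd_mean, rebound_wsd_sd = rebound_wsd_sd,
      rebound_nonwsd_mean = rebound_nonwsd_mean,
      rebound_nonwsd_sd = rebound_nonwsd_sd,
      margin = margin,
      chronotype_sd = chronotype_sd,
      wake_time_mean = wake_time_mean, wake_time_sd = wake_time_sd,
      weekend_delay_wsd = weekend_delay_wsd,
      chronotype_shift_wsd = chronotype_shift_wsd,
      activity_level_sd = activity_level_sd,
      amplitude_range = amplitude_range,
      lux_day_range = lux_day_range,
      dow_day = as.integer(dow_day),
      dow_onset_shift_wsd = dow_onset_shift_wsd,
      onset_sd = onset_sd, diary_noise_sd = diary_noise_sd,
      wsd_threshold = wsd_threshold,
      profile_args = profile_args
    ),
    class = "cohort_config"
  )
}

#' Generate a synthetic cohort
#'
#' Draws per-subject profiles from a [cohort_config()] and generates every
#' subject with a deterministic per-subject seed derived from `seed`, so the
#' identical `(config, seed)` pair reproduces the identical cohort. The
#' truth table records each subject's assigned class, realized rebound and
#' label; the features the configuration ties to the label are reported in
#' the `informative` element (the rebound contrast always marks `MSF` and
#' `SJL`; a day-of-week onset shift additionally marks that night's onset
#' and duration).
#'
#' @param config a [cohort_config()].
#' @param seed master seed.
#' @return A list with `subjects` (list of [generate_subject()] bundles),
#'   `truth` (data frame: `subject`, `class_wsd`, `true_SRW`, `true_label`,
#'   `chronotype_offset`, `seed`), `informative` (character vector of
#'   feature names carrying label signal by construction) and `config`.
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  cfg <- config
  n_wsd <- round(cfg$n * cfg$wsd_fraction)
  class_wsd <- rep(c(TRUE, FALSE), c(n_wsd, cfg$n - n_wsd))

  draws <- with_seed(seed, {
    list(
      chronotype = stats::rnorm(cfg$n, 0, cfg$chronotype_sd) +
        ifelse(class_wsd, cfg$chronotype_shift_wsd, 0),
      wake_time = round(pmin(460, pmax(240, stats::rnorm(cfg$n, cfg$wake_time_mean, cfg$wake_time_sd)))),
      rebound_raw = stats::rnorm(cfg$n),
      activity_level = pmax(150, stats::rnorm(cfg$n, 500, cfg$activity_level_sd)),
      amplitude = stats::runif(cfg$n, cfg$amplitude_range[1], cfg$amplitude_range[2]),
      lux_day = stats::runif(cfg$n, cfg$lux_day_range[1], cfg$lux_day_range[2]),
      subject_seed = sample.int(2147483646L, cfg$n)
    )
  })
  rebound <- ifelse(
    class_wsd,
    pmax(
      cfg$wsd_threshold + cfg$margin,
      cfg$rebound_wsd_mean + cfg$rebound_wsd_sd * draws$rebound_raw
    ),
    pmin(
      cfg$wsd_threshold - cfg$margin,
      cfg$rebound_nonwsd_mean + cfg$rebound_nonwsd_sd * draws$rebound_raw
    )
  )

  subjects <- vector("list", cfg$n)
  truth <- data.frame(
    subject = seq_len(cfg$n),
    class_wsd = class_wsd,
    true_SRW = NA_real_,
    true_label = NA,
    chronotype_offset = draws$chronotype,
    seed = draws$subject_seed
  )
  for (i in seq_len(cfg$n)) {
    args <- utils::modifyList(
      list(
        chronotype_offset = draws$chronotype[i],
        weekend_rebound_true = rebound[i],
        workday_wake_time = draws$wake_time[i],
        weekday_onset_sd = cfg$onset_sd,
        weekend_onset_delay = 30 + if (class_wsd[i]) cfg$weekend_delay_wsd else 0,
        wake_activity_mean = draws$activity_level[i],
        diurnal_amplitude = draws$amplitude[i],
        illuminance_day = draws$lux_day[i],
        diary_noise_sd = cfg$diary_noise_sd,
        dow_effect = list(
          day = cfg$dow_day,
          onset_shift = if (class_wsd[i]) cfg$dow_onset_shift_wsd else 0,
          activity_scale = 1
        )
      ),
      cfg$profile_args
    )
    profile <- do.call(subject_profile, args)
    subjects[[i]] <- generate_subject(profile, draws$subject_seed[i])
    truth$true_SRW[i] <- subjects[[i]]$truth$SRW
    truth$true_label[i] <- subjects[[i]]$truth$wsd_label
  }

  informative <- c("MSF", "SJL")
  if (cfg$dow_onset_shift_wsd != 0) {
    lbl <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")[cfg$dow_day + 1L]
    informative <- c(informative, paste0(c("SO_", "SD_"), lbl))
  }

  list(
    subjects = subjects, truth = truth,
    informative = informative, config = cfg, seed = seed
  )
}
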