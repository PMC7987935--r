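# The 40-feature circadian battery: sleep-habit times, sleep regularity and
# timing, nonparametric activity-rhythm statistics, rest-activity windows,
# and the biological-clock features (MSF, SJL), plus the weekend sleep
# rebound (SRW) that defines the weekday-sleep-debt label.

WSD_THRESHOLD_MIN <- 120

# Reshape per-epoch values into a complete-day matrix (rows = calendar days
# fully covered by the recording, columns = epoch of day).
complete_day_matrix <- function(values, timestamp, epochs_per_day = 1440L) {
  day <- day_floor(timestamp)
  counts <- table(as.numeric(day))
  full <- as.numeric(names(counts))[counts == epochs_per_day]
  keep <- as.numeric(day) %in% full
  n_days <- length(full)
  if (n_days == 0L) {
    stop("no complete recorded day", call. = FALSE)
  }
  ord <- order(timestamp[keep])
  mat <- matrix(values[keep][ord], nrow = n_days, ncol = epochs_per_day,
    byrow = TRUE
  )
  days <- as.POSIXct(sort(full), tz = "UTC")
  list(mat = mat, day_index = weekday_index(days), date = as.Date(days))
}

as_binary_day_matrix <- function(states, epochs_per_day = 1440L) {
  if (is.matrix(states)) {
    if (!all(states %in% c(0, 1))) {
      stop("state matrix must be binary (1 = sleep, 0 = wake)", call. = FALSE)
    }
    return(states)
  }
  ts <- attr(states, "timestamp")
  if (is.null(ts)) {
    stop(
      "`states` must be a binary day matrix or carry epoch timestamps",
      call. = FALSE
    )
  }
  complete_day_matrix(as.integer(states) == 1L, ts, epochs_per_day)$mat * 1L
}

#' Sleep regularity index
#'
#' Agreement between sleep/wake states at the same clock time on consecutive
#' days, scaled so that a perfectly repeating schedule scores 100 and a
#' schedule that inverts every day scores -100:
#' `SRI = -100 + 200 / (p (N - 1)) * sum_j sum_k [s_(k,j) == s_(k+1,j)]`.
#'
#' @param states a `sleep_wake` vector with timestamps (complete recorded
#'   days are used), or an `N x p` binary matrix (rows = days, 1 = sleep).
#' @param epochs_per_day epochs per day when reshaping a timestamped series.
#' @return SRI in \[-100, 100\].
#' @export
sri <- function(states, epochs_per_day = 1440L) {
  s <- as_binary_day_matrix(states, epochs_per_day)
  n <- nrow(s)
  if (n < 2L) stop("SRI needs at least 2 complete days", call. = FALSE)
  agree <- s[-n, , drop = FALSE] == s[-1L, , drop = FALSE]
  -100 + 200 * sum(agree) / (ncol(s) * (n - 1L))
}

#' Sleep timing index
#'
#' The circular mean clock time of all sleep-scored epochs: each epoch of
#' day `j` maps to the angle `2 pi j / p` on the 24-h circle, the unit
#' vectors of the sleep epochs are summed, and the argument of the resultant
#' is mapped back to minutes after midnight.
#'
#' @inheritParams sri
#' @return STI in minutes after midnight, in \[0, 1440).
#' @export
sti <- function(states, epochs_per_day = 1440L) {
  s <- as_binary_day_matrix(states, epochs_per_day)
  p <- ncol(s)
  if (sum(s) == 0) stop("STI needs at least one sleep epoch", call. = FALSE)
  theta <- 2 * pi * (seq_len(p) - 1L) / p
  mass <- colSums(s)
  x <- sum(mass * cos(theta))
  y <- sum(mass * sin(theta))
  if (sqrt(x^2 + y^2) < sqrt(.Machine$double.eps) * sum(mass)) {
    stop("STI undefined: sleep is uniform over the 24-h circle",
      call. = FALSE
    )
  }
  (1440 * (atan2(y, x) %% (2 * pi)) / (2 * pi)) %% 1440
}

#' Interdaily stability and intradaily variability
#'
#' Nonparametric activity-rhythm statistics over `N` complete days of `p`
#' epochs (`M = N p` values `A_i`):
#' `IS = M * sum_j (Abar_j - Abar)^2 / (p * sum_i (A_i - Abar)^2)` measures
#' day-to-day synchrony of the 24-h profile (1 for a perfectly repeating
#' profile, about `1/N` for white noise);
#' `IV = M * sum_(i>=2) (A_i - A_(i-1))^2 / ((M - 1) * sum_i (A_i - Abar)^2)`
#' measures epoch-to-epoch fragmentation (about 2 for white noise).
#'
#' @param x an `N x p` matrix (rows = days) or a numeric vector of length
#'   `N * p` in time order (then `p` must be given).
#' @param p epochs per day when `x` is a vector.
#' @param bin_minutes optional pre-binning: values are averaged within
#'   consecutive bins of this many epochs before the statistics are
#'   computed. Default 1 (raw epochs); 60 gives the common hourly-bin
#'   convention.
#' @return A named vector `c(IS = , IV = )`.
#' @export
is_iv <- function(x, p = NULL, bin_minutes = 1L) {
  if (is.matrix(x)) {
    mat <- x
  } else {
    if (is.null(p)) stop("`p` is required for vector input", call. = FALSE)
    if (length(x) %% p != 0) {
      stop("series length must be a multiple of p", call. = FALSE)
    }
    mat <- matrix(as.numeric(x), ncol = p, byrow = TRUE)
  }
  if (nrow(mat) < 2L) stop("IS/IV need at least 2 complete days", call. = FALSE)
  if (bin_minutes > 1L) {
    if (ncol(mat) %% bin_minutes != 0) {
      stop("epochs per day must be a multiple of bin_minutes", call. = FALSE)
    }
    groups <- rep(seq_len(ncol(mat) / bin_minutes), each = bin_minutes)
    mat <- t(apply(mat, 1L, function(row) tapply(row, groups, mean)))
  }
  a <- as.vector(t(mat)) # time order
  m <- length(a)
  abar <- mean(a)
  ss <- sum((a - abar)^2)
  if (ss == 0) {
    stop("IS/IV undefined for a constant series", call. = FALSE)
  }
  hourly_profile <- colMeans(mat)
  is_val <- m * sum((hourly_profile - abar)^2) / (ncol(mat) * ss)
  iv_val <- m * sum(diff(a)^2) / ((m - 1L) * ss)
  c(IS = is_val, IV = iv_val)
}

#' Most-active 10-hour and least-active 5-hour activity levels
#'
#' For a single complete day, `M10` is the highest mean activity over any
#' contiguous 10-h (600-epoch) window and `L5` the lowest mean over any
#' contiguous 5-h (300-epoch) window, both constrained within the calendar
#' day (midnight to midnight).
#'
#' @param day_activity numeric activity counts for one complete day.
#' @param m10_epochs,l5_epochs window lengths in epochs.
#' @return A named vector `c(M10 = , L5 = )`.
#' @export
m10_l5 <- function(day_activity, m10_epochs = 600L, l5_epochs = 300L) {
  a <- as.numeric(day_activity)
  if (anyNA(a)) stop("incomplete day: missing activity values", call. = FALSE)
  if (length(a) < m10_epochs) {
    stop("day shorter than the M10 window", call. = FALSE)
  }
  window_means <- function(x, w) {
    cs <- cumsum(c(0, x))
    (cs[(w + 1L):length(cs)] - cs[seq_len(length(cs) - w)]) / w
  }
  c(
    M10 = max(window_means(a, m10_epochs)),
    L5 = min(window_means(a, l5_epochs))
  )
}

#' Chronotype, social jetlag and the weekday-sleep-debt label
#'
#' From per-night summaries ([summarize_days()]): weekend (Friday and
#' Saturday night) mean onset `SOF` and wake `WUF`; mid-sleep on free days
#' `MSF = mid_sleep(SOF, WUF)`; weekday (Monday-Thursday night) mean
#' mid-sleep `MSW` and duration `SDW`; social jetlag `SJL = MSF - MSW`;
#' weekend sleep rebound `SRW = SDF - SDW`; and the weekday-sleep-debt label
#' `wsd = (SRW >= wsd_threshold)`. Chronotype class follows the MSF
#' thresholds: morning < 03:00, intermediate 03:00-04:00, evening > 04:00.
#'
#' @param nights per-night summaries from [summarize_days()].
#' @param wsd_threshold rebound (minutes) at or above which a subject is
#'   labelled as having weekday sleep debt; default 120.
#' @return A list with `SOF`, `WUF`, `MSF`, `MSW`, `SJL`, `SDF`, `SDW`,
#'   `SRW`, `wsd_label` and `chronotype_class`.
#' @export
chronotype_features <- function(nights, wsd_threshold = WSD_THRESHOLD_MIN) {
  wk <- nights[nights$night %in% 0:3, , drop = FALSE]
  we <- nights[nights$weekend, , drop = FALSE]
  if (nrow(we) < 2L || anyNA(we$SO) || anyNA(we$WU)) {
    stop("missing weekend night: chronotype features unavailable",
      call. = FALSE
    )
  }
  sof <- mean(we$SO)
  wuf <- mean(we$WU)
  msf <- mid_sleep(sof, wuf)
  msw <- mean(wk$MS)
  sdw <- mean(wk$SD)
  sdf <- mean(we$SD)
  srw <- sdf - sdw
  cls <- if (is.na(msf)) {
    NA_character_
  } else if (msf < 180) {
    "morning"
  } else if (msf <= 240) {
    "intermediate"
  } else {
    "evening"
  }
  list(
    SOF = sof, WUF = wuf, MSF = msf, MSW = msw, SJL = msf - msw,
    SDF = sdf, SDW = sdw, SRW = srw,
    wsd_label = if (is.na(srw)) NA else srw >= wsd_threshold,
    chronotype_class = cls
  )
}

#' Canonical names of the 40-feature battery
#'
#' @return Character vector of the 40 feature names, in battery order.
#' @export
feature_names <- function() {
  c(
    paste0("WU_", c("Tue", "Wed", "Thu", "Fri", "mean", "std")),
    paste0("SO_", c("Mon", "Tue", "Wed", "Thu", "mean", "std")),
    paste0("MS_", c("Mon", "Tue", "Wed", "Thu", "mean", "std")),
    paste0("SD_", c("Mon", "Tue", "Wed", "Thu", "mean", "std")),
    paste0("M10_", c("Tue", "Wed", "Thu", "Fri")),
    paste0("L5_", c("Tue", "Wed", "Thu", "Fri")),
    "SRI", "STI", "IS_act", "IS_light", "IV_act", "IV_light", "MSF", "SJL"
  )
}

#' Build the 40-feature vector for one subject
#'
#' Computes the full battery for a protocol-trimmed recording: per-night
#' wake-up/onset/mid-sleep/duration for the weekday nights with their means
#' and sample standard deviations, per-day M10/L5 for Tuesday-Friday, sleep
#' regularity and timing indices, interdaily stability and intradaily
#' variability for both activity and illuminance, and the biological-clock
#' features MSF and SJL. Weekday-night features use the onset-day naming
#' (SO/MS/SD for Monday-Thursday nights, WU for Tuesday-Friday mornings).
#'
#' @param series a protocol-trimmed [epoch_series()].
#' @param scored optional result of [score_subject()] on `series` (computed
#'   if omitted).
#' @param wsd_threshold rebound threshold passed to [chronotype_features()].
#' @param iv_bin_minutes IS/IV pre-binning ([is_iv()]).
#' @return A list with `features` (named numeric vector of length 40) and
#'   `chronotype` (the [chronotype_features()] list, including `SRW` and
#'   `wsd_label`).
#' @export
build_feature_vector <- function(series, scored = NULL,
                                 wsd_threshold = WSD_THRESHOLD_MIN,
                                 iv_bin_minutes = 1L) {
  stopifnot(inherits(series, "epoch_series"))
  if (is.null(scored)) scored <- score_subject(series)
  nights <- scored$nights
  chron <- chronotype_features(nights, wsd_threshold = wsd_threshold)

  night_val <- function(col, idx) {
    v <- nights[[col]][match(idx, nights$night)]
    v
  }
  wk_block <- function(col) {
    v <- night_val(col, 0:3)
    c(v, mean(v), stats::sd(v))
  }

  act_days <- complete_day_matrix(series$activity, series$timestamp)
  lux_days <- complete_day_matrix(series$lux, series$timestamp)
  tue_fri <- match(1:4, act_days$day_index)
  if (anyNA(tue_fri)) {
    stop("missing complete Tuesday-Friday day for M10/L5", call. = FALSE)
  }
  ml <- vapply(tue_fri, function(i) m10_l5(act_days$mat[i, ]), numeric(2))

  smat <- as_binary_day_matrix(scored$states)
  isiv_act <- is_iv(act_days$mat, bin_minutes = iv_bin_minutes)
  isiv_lux <- is_iv(lux_days$mat, bin_minutes = iv_bin_minutes)

  features <- c(
    wk_block("WU"), wk_block("SO"), wk_block("MS"), wk_block("SD"),
    ml["M10", ], ml["L5", ],
    sri(smat), sti(smat),
    isiv_act[["IS"]], isiv_lux[["IS"]], isiv_act[["IV"]], isiv_lux[["IV"]],
    chron$MSF, chron$SJL
  )
  names(features) <- feature_names()
  list(features = features, chronotype = chron)
}
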