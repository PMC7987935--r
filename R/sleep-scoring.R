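# Sleep/wake scoring and nightly sleep-time extraction.
#
# Per-epoch states are +1 (sleep) / -1 (wake). The cumulative sleep/wake
# function r(i) = sum_{j<=i} x_j rises during sleep and falls during wake;
# its local maxima/minima within fixed morning/evening search windows mark
# wake-up and sleep-onset times, taking the latest extremum when a day has
# several.

#' Cole-Kripke scoring coefficients for 1-minute epochs
#'
#' The published 1-minute-epoch coefficient set: an epoch is scored sleep
#' when `D = P * sum_k W_k * A_(i+k) < 1`, with the seven window weights
#' applying to lags -4 ... +2 around the epoch.
#'
#' @param P scale factor.
#' @param W weights for activity counts at lags -4 ... +2.
#' @return A list with elements `P`, `W` and `lags`.
#' @export
cole_kripke_weights <- function(P = 0.001,
                                W = c(404, 598, 326, 441, 1408, 508, 350)) {
  stopifnot(length(W) == 7, P > 0, all(W >= 0))
  list(P = P, W = W, lags = -4:2)
}

#' Score sleep/wake per epoch with the Cole-Kripke rule
#'
#' Epoch `i` is scored sleep iff
#' `D_i = P * (W_-4 A_(i-4) + ... + W_+2 A_(i+2)) < 1`. Missing neighbours at
#' the series boundaries are zero-padded. Counts must be on a 1-minute grid.
#'
#' @param activity an [epoch_series()] or a numeric vector of per-minute
#'   activity counts.
#' @param coefficients a coefficient set from [cole_kripke_weights()].
#' @return An integer vector of class `sleep_wake` with values `+1` (sleep)
#'   and `-1` (wake), carrying the epoch timestamps (attribute `timestamp`)
#'   when `activity` is an `epoch_series`.
#' @examples
#' cole_kripke(rep(0, 10)) # all sleep
#' cole_kripke(rep(10, 10)) # all wake
#' @export
cole_kripke <- function(activity, coefficients = cole_kripke_weights()) {
  ts <- NULL
  if (inherits(activity, "epoch_series")) {
    ts <- activity$timestamp
    a <- activity$activity
  } else {
    a <- as.numeric(activity)
    if (anyNA(a) || any(a < 0)) {
      stop("activity counts must be non-negative and non-missing",
        call. = FALSE
      )
    }
  }
  n <- length(a)
  if (n < 1L) stop("empty activity series", call. = FALSE)
  pad <- c(rep(0, 4), a, rep(0, 2))
  d <- numeric(n)
  for (k in 0:6) {
    d <- d + coefficients$W[k + 1L] * pad[(1:n) + k]
  }
  d <- coefficients$P * d
  state <- ifelse(d < 1, 1L, -1L)
  structure(as.integer(state),
    class = "sleep_wake", timestamp = ts, D = d
  )
}

#' Cumulative sleep/wake function
#'
#' `r(i)` is the running sum of the +1/-1 sleep/wake states from the first
#' recorded epoch. It trends upward while asleep and downward while awake,
#' so state changes appear as local extrema.
#'
#' @param states a `sleep_wake` vector from [cole_kripke()] (or any +1/-1
#'   integer vector).
#' @return A numeric vector of the same length; the timestamp attribute of
#'   `states` is propagated.
#' @examples
#' sleep_wake_function(c(1L, 1L, -1L, -1L, -1L)) # 1 2 1 0 -1
#' @export
sleep_wake_function <- function(states) {
  x <- as.integer(states)
  if (length(x) == 0L) stop("empty state series", call. = FALSE)
  if (!all(x %in% c(-1L, 1L))) {
    stop("states must be +1 (sleep) or -1 (wake)", call. = FALSE)
  }
  structure(cumsum(x), timestamp = attr(states, "timestamp"))
}

# indices of local maxima (sign = +1) or minima (sign = -1) of a numeric
# series, where a tied extremal plateau contributes its last index; series
# boundaries are treated one-sidedly (an endpoint can be an extremum).
local_extrema <- function(r, sign = 1) {
  v <- as.vector(sign * r)
  runs <- rle(v)
  ends <- cumsum(runs$lengths)
  m <- length(runs$values)
  if (m == 1L) {
    return(integer(0))
  }
  left_ok <- c(TRUE, runs$values[-1L] > runs$values[-m])
  right_ok <- c(runs$values[-m] > runs$values[-1L], TRUE)
  ends[left_ok & right_ok]
}

#' Nightly wake-up and sleep-onset times from r(i)
#'
#' Wake-up time (WU) of a calendar day is the time of the latest local
#' maximum of `r(i)` within that day's morning search window
#' (00:00-12:00); sleep-onset time (SO) of a day is the latest local
#' minimum within its evening window (12:00 to 06:00 of the next day),
#' expressed in minutes after the onset day's midnight (post-midnight onsets
#' therefore exceed 1,440). When a tied extremal plateau occurs, its last
#' epoch is taken. Because the extremum of `r` sits on the last epoch before
#' the state change, the reported time is the transition boundary one epoch
#' later (sleep scored through the 05:59 epoch gives WU = 360).
#'
#' @param states a `sleep_wake` vector with timestamps (from scoring an
#'   [epoch_series()]).
#' @param wu_window morning search window for WU, minutes after midnight.
#' @param so_window evening search window for SO, minutes after midnight
#'   (upper bound may exceed 1,440).
#' @return A `data.frame` with one row per calendar day in the recording:
#'   `date`, `day_index` (Mon = 0 ... Sun = 6), `WU` and `SO` in minutes
#'   after that day's midnight (`NA` when no extremum falls in a window).
#' @export
nightly_times <- function(states, wu_window = c(0, 720),
                          so_window = c(720, 1800)) {
  ts <- attr(states, "timestamp")
  if (is.null(ts)) {
    stop("`states` must carry epoch timestamps; score an epoch_series",
      call. = FALSE
    )
  }
  r <- sleep_wake_function(states)
  tnum <- as.numeric(ts)
  maxima <- tnum[local_extrema(r, sign = 1)]
  minima <- tnum[local_extrema(r, sign = -1)]

  days <- unique(day_floor(ts))
  out <- data.frame(
    date = as.Date(days),
    day_index = weekday_index(days),
    WU = NA_real_, SO = NA_real_
  )
  for (i in seq_along(days)) {
    mid <- as.numeric(days[i])
    wu_hits <- maxima[maxima >= mid + 60 * wu_window[1] &
      maxima < mid + 60 * wu_window[2]]
    # the extremum sits on the last epoch before the state change; the
    # reported time is the transition boundary, one epoch later
    if (length(wu_hits)) out$WU[i] <- (max(wu_hits) - mid) / 60 + 1
    so_hits <- minima[minima >= mid + 60 * so_window[1] &
      minima < mid + 60 * so_window[2]]
    if (length(so_hits)) out$SO[i] <- (max(so_hits) - mid) / 60 + 1
  }
  out
}

#' Overnight sleep midpoint
#'
#' Mid-sleep of a night, in minutes after midnight within \[0, 1440), from
#' the night's sleep-onset time `so` (minutes after the onset day's
#' midnight; values > 1,440 mean past the following midnight) and next
#' morning's wake-up time `wu` (minutes after that morning's midnight):
#' `MS = ((so + wu + 1440) / 2) mod 1440`.
#'
#' @param so sleep-onset time(s), minutes after the onset day's midnight.
#' @param wu wake-up time(s), minutes after the wake day's midnight.
#' @return Mid-sleep in minutes after midnight, in \[0, 1440).
#' @examples
#' mid_sleep(1446, 334) # 170
#' mid_sleep(1410, 348) # 159
#' @export
mid_sleep <- function(so, wu) {
  ((so + wu + 1440) / 2) %% 1440
}

#' Overnight sleep duration
#'
#' Duration of a night's sleep interval, `SD = wu + 1440 - so`, in minutes,
#' with `so`/`wu` on the scales described in [mid_sleep()].
#'
#' @inheritParams mid_sleep
#' @return Sleep duration in minutes.
#' @examples
#' sleep_duration(1434, 338) # 344
#' @export
sleep_duration <- function(so, wu) {
  wu + 1440 - so
}

#' Per-night sleep summaries with day-assignment conventions
#'
#' Pairs each day's sleep-onset time with the following morning's wake-up
#' time to form per-night summaries. A night is indexed by its onset day
#' (Mon = 0 ... Sun = 6): weekday nights are Monday-Thursday, weekend nights
#' are Friday and Saturday (Friday-night sleep belongs to the weekend).
#' The first Monday of the protocol contributes only its onset; the final
#' Monday morning contributes only the Sunday night's wake-up.
#'
#' @param times output of [nightly_times()].
#' @return A `data.frame` with one row per night: `night` (onset-day index,
#'   Mon = 0), `SO`, `WU`, `MS` ([mid_sleep()]), `SD` ([sleep_duration()])
#'   and `weekend` (`TRUE` for Friday/Saturday nights). Nights with a
#'   missing onset or wake-up carry `NA`s.
#' @export
summarize_days <- function(times) {
  stopifnot(all(c("date", "day_index", "WU", "SO") %in% names(times)))
  times <- times[order(times$date), , drop = FALSE]
  n <- nrow(times)
  if (n < 2L) stop("need at least two calendar days", call. = FALSE)
  onset_rows <- seq_len(n - 1L)
  so <- times$SO[onset_rows]
  wu <- times$WU[onset_rows + 1L]
  night <- times$day_index[onset_rows]
  data.frame(
    night = night,
    night_label = c(
      "Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"
    )[night + 1L],
    SO = so,
    WU = wu,
    MS = mid_sleep(so, wu),
    SD = sleep_duration(so, wu),
    weekend = night %in% c(4L, 5L)
  )
}

#' Score a subject end-to-end
#'
#' Convenience wrapper: Cole-Kripke scoring, cumulative sleep/wake function,
#' nightly wake-up/sleep-onset detection and per-night summaries for one
#' protocol-trimmed recording.
#'
#' @param series a protocol-trimmed [epoch_series()].
#' @param coefficients scoring coefficients ([cole_kripke_weights()]).
#' @param wu_window,so_window search windows passed to [nightly_times()].
#' @return A list with elements `states`, `r`, `times` and `nights`.
#' @export
score_subject <- function(series, coefficients = cole_kripke_weights(),
                          wu_window = c(0, 720), so_window = c(720, 1800)) {
  states <- cole_kripke(series, coefficients)
  times <- nightly_times(states, wu_window, so_window)
  list(
    states = states,
    r = sleep_wake_function(states),
    times = times,
    nights = summarize_days(times)
  )
}
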