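# Epoch-level actigraphy containers and I/O.
#
# An epoch series is a gapless 1-min grid: gaps in a recording must be
# represented as wear = FALSE rows, never as missing rows.

EPOCHS_PER_DAY <- 1440L

#' Construct and validate an epoch series
#'
#' An `epoch_series` holds one subject's wrist-actigraph recording on a
#' gapless 1-minute grid: per-epoch activity counts, illuminance (lux) and a
#' wear flag. Non-wear periods are flagged, never dropped, so the grid stays
#' contiguous.
#'
#' @param timestamp `POSIXct` vector, strictly increasing, 1-minute spacing.
#'   Timestamps are naive local times (stored in UTC to avoid DST
#'   arithmetic).
#' @param activity non-negative integer activity counts, one per epoch.
#' @param lux non-negative illuminance values, one per epoch.
#' @param wear logical wear flags, one per epoch (default all `TRUE`).
#' @return A `data.frame` of class `epoch_series` with columns `timestamp`,
#'   `activity`, `lux`, `wear`.
#' @examples
#' t0 <- as.POSIXct("2004-01-26 17:00:00", tz = "UTC")
#' es <- epoch_series(t0 + 60 * (0:59), activity = rpois(60, 200), lux = 100)
#' nrow(es)
#' @export
epoch_series <- function(timestamp, activity, lux = 0, wear = TRUE) {
  if (!inherits(timestamp, "POSIXct")) {
    stop("`timestamp` must be POSIXct", call. = FALSE)
  }
  n <- length(timestamp)
  if (n < 2L) stop("an epoch series needs at least 2 epochs", call. = FALSE)
  activity <- as.numeric(activity)
  lux <- rep_len(as.numeric(lux), n)
  wear <- rep_len(as.logical(wear), n)
  if (length(activity) != n) {
    stop("`activity` must have one value per epoch", call. = FALSE)
  }
  if (anyNA(activity) || any(activity < 0)) {
    stop("activity counts must be non-negative and non-missing", call. = FALSE)
  }
  if (anyNA(lux) || any(lux < 0)) {
    stop("illuminance must be non-negative and non-missing", call. = FALSE)
  }
  steps <- diff(as.numeric(timestamp))
  if (any(steps == 0)) {
    stop("duplicated timestamps in epoch grid", call. = FALSE)
  }
  if (any(steps < 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(steps != 60)) {
    stop(
      "timestamps must form a gapless 1-min grid; represent gaps as ",
      "wear = FALSE epochs, never as missing rows",
      call. = FALSE
    )
  }
  structure(
    data.frame(
      timestamp = timestamp, activity = activity, lux = lux, wear = wear
    ),
    class = c("epoch_series", "data.frame")
  )
}

#' Read a 1-minute epoch recording from CSV
#'
#' Reads the plain epoch dialect: header `timestamp,activity,lux,wear`,
#' ISO-8601 local timestamps (`YYYY-MM-DDTHH:MM:SS`, a space separator is
#' also accepted), one row per minute. Out-of-order or duplicated timestamps
#' and row-level gaps are rejected; a recording gap must be written as
#' `wear = FALSE` rows.
#'
#' @param path path to a CSV file.
#' @param dialect dialect name; only `"plain"` is implemented.
#' @return An [epoch_series()].
#' @seealso [write_epochs()]
#' @export
read_epochs <- function(path, dialect = "plain") {
  dialect <- match.arg(dialect, "plain")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("timestamp", "activity", "lux", "wear")
  if (!all(required %in% names(raw))) {
    stop(
      "header must contain columns: ", paste(required, collapse = ", "),
      call. = FALSE
    )
  }
  ts <- as.POSIXct(sub("T", " ", raw$timestamp),
    tz = "UTC", format = "%Y-%m-%d %H:%M:%S"
  )
  bad <- which(is.na(ts))
  if (length(bad)) {
    stop(
      "unparseable timestamp at data line ", bad[1L], ": ",
      raw$timestamp[bad[1L]],
      call. = FALSE
    )
  }
  act <- suppressWarnings(as.numeric(raw$activity))
  bad <- which(is.na(act) | act < 0)
  if (length(bad)) {
    stop("malformed activity count at data line ", bad[1L], call. = FALSE)
  }
  steps <- diff(as.numeric(ts))
  if (any(steps <= 0)) {
    i <- which(steps <= 0)[1L]
    stop(
      "duplicated or out-of-order timestamp at data line ", i + 1L,
      call. = FALSE
    )
  }
  if (any(steps != 60)) {
    i <- which(steps != 60)[1L]
    stop(
      "non-1-min spacing (", steps[i] / 60, " min) at data line ", i + 1L,
      "; gaps must be represented as wear = FALSE epochs, not missing rows",
      call. = FALSE
    )
  }
  epoch_series(ts, act, as.numeric(raw$lux), as.logical(raw$wear))
}

#' Write an epoch series to CSV
#'
#' @param series an [epoch_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(series, path) {
  stopifnot(inherits(series, "epoch_series"))
  out <- data.frame(
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    activity = series$activity,
    lux = series$lux,
    wear = series$wear
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Trim a recording to the study protocol window
#'
#' The protocol has subjects wear the device from Monday around 17:00 to the
#' next Monday around 08:00. This clips a recording to the fixed window
#' \[first Monday 17:00, next Monday 08:00), i.e. 6 days 15 h = 9,540 epochs,
#' and attaches day-index metadata (Mon = 0 ... Sun = 6) used downstream for
#' day assignment. The first (partial) Monday is retained only for wake-up
#' and sleep-onset estimation; day-complete statistics use Tuesday-Sunday.
#'
#' @param series an [epoch_series()] spanning the full protocol window.
#' @return The clipped `epoch_series`, with attributes `protocol_start`
#'   (Monday 00:00 of the first day) and `day0` (weekday index of the first
#'   calendar day, always 0 = Monday).
#' @export
trim_to_protocol <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  ts <- series$timestamp
  wd <- weekday_index(ts[1L])
  # first Monday 17:00 at or after the start of the recording
  first_day <- as.POSIXct(trunc(ts[1L], "days"), tz = "UTC")
  days_to_mon <- (0L - wd) %% 7L
  start <- first_day + days_to_mon * 86400 + 17 * 3600
  if (start < ts[1L]) start <- start + 7 * 86400
  end <- start + 6 * 86400 + 15 * 3600 # next Monday 08:00, exclusive
  if (ts[1L] > start || ts[length(ts)] < end - 60) {
    stop(
      "recording does not cover the protocol window ",
      format(start, "%Y-%m-%d %H:%M"), " -- ", format(end, "%Y-%m-%d %H:%M"),
      call. = FALSE
    )
  }
  keep <- ts >= start & ts < end
  out <- series[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("epoch_series", "data.frame")
  attr(out, "protocol_start") <- start - 17 * 3600 # Monday 00:00
  attr(out, "day0") <- 0L
  out
}

#' Apply the non-wear subject-exclusion rule
#'
#' A subject is excluded when the device was removed for more than
#' `max_nonwear_min` consecutive minutes (default 30) at any point of the
#' recording; a run of exactly `max_nonwear_min` minutes is still included.
#'
#' @param series an [epoch_series()] with wear flags set.
#' @param max_nonwear_min longest tolerated non-wear run, in minutes.
#' @return `TRUE` if the subject is to be included, `FALSE` if excluded.
#' @export
apply_exclusion <- function(series, max_nonwear_min = 30) {
  stopifnot(inherits(series, "epoch_series"))
  r <- rle(!series$wear)
  longest <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  longest <= max_nonwear_min
}

#' Flag non-wear from runs of zero counts
#'
#' Heuristic for real recordings whose wear flags are unknown: mark every
#' maximal run of at least `min_run` consecutive zero-count epochs as
#' non-wear. Off by default in the pipeline; synthetic data carries explicit
#' wear flags.
#'
#' @param series an [epoch_series()].
#' @param min_run minimum zero-count run length (minutes) to call non-wear.
#' @return The series with updated `wear` flags.
#' @export
flag_nonwear_zeros <- function(series, min_run = 90) {
  stopifnot(inherits(series, "epoch_series"))
  r <- rle(series$activity == 0)
  nonwear <- rep(r$values & r$lengths >= min_run, r$lengths)
  series$wear <- series$wear & !nonwear
  series
}

# Mon = 0 ... Sun = 6 for a POSIXct
weekday_index <- function(t) {
  (as.POSIXlt(t, tz = "UTC")$wday + 6L) %% 7L
}

# midnight of the calendar day containing t
day_floor <- function(t) {
  as.POSIXct(trunc(t, "days"), tz = "UTC")
}
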