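# Shared fixtures: tiny hand-built series and cached synthetic subjects.

MON0 <- as.POSIXct("2004-01-26 00:00:00", tz = "UTC") # a Monday

# epoch series of n minutes starting at `start`
make_series <- function(activity, start = MON0 + 17 * 3600, lux = 10,
                        wear = TRUE) {
  epoch_series(start + 60 * (seq_along(activity) - 1L),
    activity = activity, lux = lux, wear = wear
  )
}

# hand-built sleep/wake state vector with timestamps, from sleep intervals
# given in absolute minutes from the Monday-00:00 origin
make_states <- function(sleep_intervals, start_min = 17 * 60,
                        end_min = 7 * 1440 + 8 * 60) {
  mins <- seq.int(start_min, end_min - 1L)
  asleep <- rep(FALSE, length(mins))
  for (iv in sleep_intervals) {
    asleep <- asleep | (mins >= iv[1] & mins < iv[2])
  }
  structure(ifelse(asleep, 1L, -1L),
    class = "sleep_wake",
    timestamp = MON0 + 60 * mins
  )
}

# nightly sleep 23:30 -> 06:00 every night of the protocol week
square_schedule <- function(onset = 1410, wake = 360) {
  lapply(0:6, function(d) c(d * 1440 + onset, (d + 1) * 1440 + wake))
}

zero_noise_profile <- function(diary_noise_sd = 0, ...) {
  subject_profile(
    weekday_onset_sd = 0, activity_shape = Inf, sleep_activity_mean = 0,
    diary_noise_sd = diary_noise_sd, ...
  )
}

# one cached noisy subject reused across tests
cached_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_subject(subject_profile(), seed = 424242)
    }
    cache
  }
})

cached_trimmed <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- trim_to_protocol(cached_subject()$series)
    cache
  }
})
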