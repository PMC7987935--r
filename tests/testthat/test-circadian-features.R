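# The 40-feature battery: SRI, STI, IS/IV, M10/L5, chronotype features.

test_that("SRI hits its closed-form extremes and bounds", {
  day <- rep(c(1, 0), c(400, 1040))
  identical6 <- matrix(rep(day, 6), nrow = 6, byrow = TRUE)
  expect_equal(sri(identical6), 100)

  flip <- rbind(day, 1 - day, day, 1 - day)
  expect_equal(sri(flip), -100)

  set.seed(21)
  for (i in 1:25) {
    m <- matrix(rbinom(5 * 48, 1, runif(1, 0.1, 0.9)), nrow = 5)
    s <- sri(m)
    expect_gte(s, -100)
    expect_lte(s, 100)
  }
})

test_that("SRI of independent fair-coin days is centred at zero", {
  set.seed(42)
  vals <- replicate(1000, sri(matrix(rbinom(6 * 144, 1, 0.5), nrow = 6)))
  expect_lt(abs(mean(vals)), 1)
})

test_that("STI is the circular mean time of sleep epochs", {
  m <- matrix(0L, nrow = 3, ncol = 1440)
  m[, 161] <- 1L # all sleep mass at 02:40
  expect_equal(sti(m), 160)

  m2 <- matrix(0L, nrow = 1, ncol = 1440)
  m2[, c(121, 241)] <- 1L # equal mass at 02:00 and 04:00
  expect_equal(sti(m2), 180)

  # mass on both sides of midnight averages to midnight, not noon
  m3 <- matrix(0L, nrow = 1, ncol = 1440)
  m3[, c(1381, 61)] <- 1L # 23:00 and 01:00
  expect_equal(sti(m3), 0, tolerance = 1e-9)

  expect_error(sti(matrix(1L, nrow = 2, ncol = 1440)), "uniform")
})

test_that("IS/IV match their closed forms on structured series", {
  day <- sin(2 * pi * (1:48) / 48) + 2
  expect_equal(
    unname(is_iv(matrix(rep(day, 5), nrow = 5, byrow = TRUE))["IS"]),
    1
  )

  alternating <- rep(c(5, -5), 72) # 3 days of 48, even M
  expect_equal(unname(is_iv(alternating, p = 48)["IV"]), 4)

  expect_error(is_iv(matrix(7, nrow = 3, ncol = 24)), "constant")
})

test_that("IS/IV equal brute-force summation of their definitions", {
  brute <- function(mat) {
    a <- as.vector(t(mat))
    m <- length(a)
    p <- ncol(mat)
    abar <- mean(a)
    num_is <- 0
    for (j in seq_len(p)) {
      num_is <- num_is + (mean(mat[, j]) - abar)^2
    }
    num_iv <- 0
    for (i in 2:m) num_iv <- num_iv + (a[i] - a[i - 1])^2
    c(
      IS = m * num_is / (p * sum((a - abar)^2)),
      IV = m * num_iv / ((m - 1) * sum((a - abar)^2))
    )
  }
  set.seed(5)
  for (i in 1:10) {
    mat <- matrix(rgamma(8 * 24, 1.5, 0.1), nrow = 8)
    expect_equal(is_iv(mat), brute(mat), tolerance = 1e-12)
  }
})

test_that("IS/IV of white noise sit at their expectations", {
  set.seed(11)
  vals <- replicate(500, {
    is_iv(matrix(rnorm(6 * 144, 100, 10), nrow = 6))
  })
  expect_equal(mean(vals["IS", ]), 1 / 6, tolerance = 0.05)
  expect_equal(mean(vals["IV", ]), 2, tolerance = 0.05)
})

test_that("hourly binning changes the IS/IV scale as configured", {
  set.seed(12)
  profile <- 200 + 150 * sin(2 * pi * (1:1440) / 1440)
  mat <- matrix(rep(profile, 6), nrow = 6, byrow = TRUE) +
    matrix(rnorm(6 * 1440, 0, 150), nrow = 6)
  raw <- is_iv(mat)
  binned <- is_iv(mat, bin_minutes = 60L)
  expect_gt(binned[["IS"]], raw[["IS"]]) # binning averages out epoch noise
})

test_that("M10/L5 match canonical patterns and a brute-force search", {
  day <- rep(0, 1440)
  day[481:1080] <- 1000 # active 08:00-18:00
  expect_equal(m10_l5(day), c(M10 = 1000, L5 = 0))
  expect_equal(m10_l5(rep(100, 1440)), c(M10 = 100, L5 = 100))

  brute <- function(a, w) {
    vapply(seq_len(length(a) - w + 1), function(i) mean(a[i:(i + w - 1)]),
      numeric(1)
    )
  }
  set.seed(8)
  for (i in 1:10) {
    a <- rpois(24, 50) # hour-bin toy day, windows 10 h and 5 h
    got <- m10_l5(a, m10_epochs = 10L, l5_epochs = 5L)
    expect_equal(unname(got["M10"]), max(brute(a, 10)))
    expect_equal(unname(got["L5"]), min(brute(a, 5)))
  }
})

test_that("chronotype features reproduce the printed-mean identities", {
  # weekday nights at the WSD group means, weekend nights fixed so that
  # MSF = 255: MSW = 166 and SJL = MSF - MSW = 89
  nights <- data.frame(
    night = 0:5,
    SO = c(rep(1434, 4), 1441, 1441),
    WU = c(rep(338, 4), 509, 509),
    weekend = c(rep(FALSE, 4), TRUE, TRUE)
  )
  nights$MS <- mid_sleep(nights$SO, nights$WU)
  nights$SD <- sleep_duration(nights$SO, nights$WU)
  ch <- chronotype_features(nights)
  expect_equal(ch$MSW, 166)
  expect_equal(ch$MSF, 255)
  expect_equal(ch$SJL, 89)

  # SRW and the 120-min label rule
  expect_equal(ch$SDF, 508)
  expect_equal(ch$SDW, 344)
  expect_equal(ch$SRW, 164)
  expect_true(ch$wsd_label)

  nights$SD[5:6] <- nights$SD[5:6] - 60 # SRW drops to 104 < 120
  nights$SO[5:6] <- nights$SO[5:6] + 60
  ch2 <- chronotype_features(nights)
  expect_false(ch2$wsd_label)

  expect_error(
    chronotype_features(nights[1:5, ]),
    "missing weekend"
  )
})

test_that("chronotype classes follow the 03:00/04:00 MSF thresholds", {
  mk <- function(msf_target) {
    # symmetric weekend sleep around the target midpoint
    so <- 1440 + msf_target - 240
    wu <- msf_target + 240
    nights <- data.frame(
      night = 0:5,
      SO = c(rep(1410, 4), so, so),
      WU = c(rep(345, 4), wu, wu),
      weekend = c(rep(FALSE, 4), TRUE, TRUE)
    )
    nights$MS <- mid_sleep(nights$SO, nights$WU)
    nights$SD <- sleep_duration(nights$SO, nights$WU)
    chronotype_features(nights)$chronotype_class
  }
  expect_equal(mk(170), "morning")
  expect_equal(mk(180), "intermediate")
  expect_equal(mk(240), "intermediate")
  expect_equal(mk(250), "evening")
})

test_that("the battery has exactly 40 named features and is deterministic", {
  fv1 <- build_feature_vector(cached_trimmed())
  fv2 <- build_feature_vector(cached_trimmed())
  expect_named(fv1$features, feature_names())
  expect_length(fv1$features, 40)
  expect_false(anyNA(fv1$features))
  expect_identical(fv1$features, fv2$features)
  expect_true(all(
    fv1$features[paste0("L5_", c("Tue", "Wed", "Thu", "Fri"))] <=
      fv1$features[paste0("M10_", c("Tue", "Wed", "Thu", "Fri"))]
  ))
  expect_gte(fv1$features[["SRI"]], -100)
  expect_lte(fv1$features[["SRI"]], 100)
})

test_that("a subject without a measurable weekend night errors out", {
  sc <- score_subject(cached_trimmed())
  sc$nights$SO[sc$nights$night == 5] <- NA # Saturday onset unmeasurable
  expect_error(
    build_feature_vector(cached_trimmed(), scored = sc),
    "weekend"
  )
})

test_that("lengthening weekend sleep strictly increases measured SRW", {
  srw <- vapply(c(30, 90, 150, 210), function(reb) {
    b <- generate_subject(zero_noise_profile(weekend_rebound_true = reb),
      seed = 77
    )
    fv <- build_feature_vector(trim_to_protocol(b$series))
    fv$chronotype$SRW
  }, numeric(1))
  expect_true(all(diff(srw) > 0))
})
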