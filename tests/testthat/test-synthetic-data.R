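# The seeded synthetic actigraphy generator.

test_that("the same (profile, seed) pair reproduces the identical subject", {
  p <- subject_profile()
  a <- generate_subject(p, seed = 31)
  b <- generate_subject(p, seed = 31)
  expect_identical(a$series, b$series)
  expect_identical(a$truth, b$truth)
  expect_identical(a$diary, b$diary)
  expect_identical(a$questionnaires, b$questionnaires)

  c <- generate_subject(p, seed = 32)
  expect_false(identical(a$series$activity, c$series$activity))
})

test_that("invalid profiles are rejected", {
  expect_error(subject_profile(weekday_onset_sd = -1), "non-negative")
  expect_error(subject_profile(wake_activity_mean = -5), "non-negative")
  expect_error(subject_profile(workday_wake_time = 600), "morning")
  expect_error(generate_subject(subject_profile()), "seed")
})

test_that("the recording grid matches the protocol", {
  b <- generate_subject(subject_profile(), seed = 2)
  s <- b$series
  expect_identical(nrow(s), 9540L)
  expect_true(all(diff(as.numeric(s$timestamp)) == 60))
  expect_true(all(s$activity >= 0))
  expect_true(all(s$lux >= 0))
})

test_that("rebound at or past the threshold sets the true label", {
  hi <- generate_subject(
    subject_profile(weekend_rebound_true = 180),
    seed = 3
  )
  lo <- generate_subject(
    subject_profile(weekend_rebound_true = 60),
    seed = 3
  )
  expect_true(hi$truth$wsd_label)
  expect_false(lo$truth$wsd_label)
  expect_equal(hi$truth$SRW, 180)
})

test_that("diary stays within 3 h of truth and tracks it", {
  b <- generate_subject(subject_profile(diary_noise_sd = 30), seed = 4)
  expect_true(all(abs(b$diary$SO - b$truth$nights$SO) <= 180))
  expect_true(all(abs(b$diary$WU - b$truth$nights$WU) <= 180))
})

test_that("questionnaire totals stay inside their instrument ranges", {
  for (seed in 1:5) {
    q <- generate_subject(subject_profile(), seed = seed)$questionnaires
    expect_gte(q[["MEQ"]], 16)
    expect_lte(q[["MEQ"]], 86)
    expect_gte(q[["PSQI"]], 0)
    expect_lte(q[["PSQI"]], 21)
    expect_gte(q[["ESS"]], 0)
    expect_lte(q[["ESS"]], 24)
    expect_gte(q[["SDS"]], 20)
    expect_lte(q[["SDS"]], 80)
  }
})

test_that("non-wear gaps are flagged with silenced sensors", {
  p <- subject_profile(nonwear_gaps = list(c(1000, 45)))
  b <- generate_subject(p, seed = 6)
  gap <- 1001:1045
  expect_true(all(!b$series$wear[gap]))
  expect_true(all(b$series$activity[gap] == 0))
  expect_false(apply_exclusion(b$series))
})

test_that("cohort class mix and determinism follow the config", {
  cfg <- cohort_config(n = 10, wsd_fraction = 0.5)
  co <- generate_cohort(cfg, seed = 9)
  expect_length(co$subjects, 10)
  expect_equal(sum(co$truth$true_label), 5)
  expect_true(all(co$truth$true_SRW[co$truth$class_wsd] >= 120))
  expect_true(all(co$truth$true_SRW[!co$truth$class_wsd] < 120))

  co2 <- generate_cohort(cfg, seed = 9)
  expect_identical(co$truth, co2$truth)
  expect_identical(
    co$subjects[[3]]$series$activity,
    co2$subjects[[3]]$series$activity
  )

  expect_error(cohort_config(n = 0), "n >= 2")
  expect_error(cohort_config(n = 1), "n >= 2")
})

test_that("a class-specific Thursday shift separates the class onsets", {
  cfg <- cohort_config(
    n = 40, dow_onset_shift_wsd = 60,
    chronotype_shift_wsd = 0, weekend_delay_wsd = 0
  )
  co <- generate_cohort(cfg, seed = 10)
  so_thu <- vapply(
    co$subjects,
    function(b) b$truth$nights$SO[b$truth$nights$night == 3],
    numeric(1)
  )
  gap <- mean(so_thu[co$truth$class_wsd]) - mean(so_thu[!co$truth$class_wsd])
  expect_gt(gap, 20)
  expect_lt(gap, 100)
  expect_true(all(c("SO_Thu", "SD_Thu", "MSF", "SJL") %in% co$informative))
})

test_that("measured SRW grows with the generated rebound level", {
  msrw <- vapply(c(40, 180), function(reb) {
    vals <- vapply(1:50, function(i) {
      p <- subject_profile(
        weekend_rebound_true = reb, weekday_onset_sd = 30
      )
      b <- generate_subject(p, seed = 5000 + i)
      build_feature_vector(
        trim_to_protocol(b$series)
      )$chronotype$SRW
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_gt(msrw[2], msrw[1] + 70)
})
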