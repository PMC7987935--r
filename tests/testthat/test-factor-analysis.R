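# Under-sampling, gamma tuning, permutation importance and the repeated
# experiment.

# small synthetic feature table: f1 carries the label, the rest are noise
toy_cohort <- function(n = 120, p_noise = 4, signal = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), length.out = n)
  x <- matrix(rnorm(n * (p_noise + 1)), nrow = n)
  x[, 1] <- x[, 1] + signal * y
  colnames(x) <- c("f1", paste0("noise", seq_len(p_noise)))
  out <- data.frame(x)
  out$wsd_label <- y
  out
}

test_that("under-sampling balances the classes without duplication", {
  co <- data.frame(
    id = 1:218,
    wsd_label = rep(c(TRUE, FALSE), c(89, 129))
  )
  bal <- undersample(co, seed = 1)
  expect_equal(sum(bal$wsd_label), 89)
  expect_equal(sum(!bal$wsd_label), 89)
  expect_false(any(duplicated(bal$id)))

  even <- data.frame(id = 1:100, wsd_label = rep(c(TRUE, FALSE), 50))
  expect_setequal(undersample(even, seed = 2)$id, even$id)

  none <- data.frame(id = 1:10, wsd_label = rep(FALSE, 10))
  expect_error(undersample(none, seed = 3), "both classes")
})

test_that("gamma tuning returns the grid value that cross-validates best", {
  x <- as.matrix(toy_cohort(n = 60)[, 1:3])
  y <- toy_cohort(n = 60)$wsd_label

  expect_equal(tune_gamma(x, y, gamma_grid = 0.5), 0.5)
  expect_error(tune_gamma(x, y, gamma_grid = numeric(0)), "empty")

  # XOR layout: a near-linear kernel (tiny gamma) cannot separate it, a
  # unit-width Gaussian can, so tuning must pick the larger gamma
  set.seed(13)
  n <- 80
  a <- matrix(rnorm(2 * n, sd = 0.15), ncol = 2) +
    cbind(rep(c(0, 1, 0, 1), n / 4), rep(c(0, 1, 1, 0), n / 4))
  y_xor <- rep(c(TRUE, TRUE, FALSE, FALSE), n / 4)
  set.seed(14)
  got <- tune_gamma(a, y_xor, gamma_grid = c(1e-3, 1), folds = 5)
  expect_equal(got, 1)
})

test_that("too few samples per class reduces the fold count with a warning", {
  co <- toy_cohort(n = 12)
  x <- as.matrix(co[, 1:3])
  set.seed(1)
  expect_warning(
    tune_gamma(x, co$wsd_label, gamma_grid = c(0.01, 1), folds = 10),
    "fold"
  )
})

test_that("permutation importance is zero for constants, positive for signal", {
  co <- toy_cohort(n = 240, signal = 3)
  x <- as.matrix(co[, 1:5])
  y <- factor(co$wsd_label)
  fit <- e1071::svm(x, y, kernel = "radial", gamma = 0.1, cost = 1)

  x_const <- cbind(x, flat = rep(1, nrow(x)))
  fit_const <- e1071::svm(x_const, y,
    kernel = "radial", gamma = 0.1, cost = 1, scale = FALSE
  )
  expect_equal(
    permutation_importance(fit_const, x_const, y, "flat", seed = 5),
    0
  )
  expect_error(
    permutation_importance(fit, x, y, "nope", seed = 1),
    "unknown feature"
  )

  p_signal <- mean(vapply(
    1:100,
    function(s) permutation_importance(fit, x, y, "f1", seed = s),
    numeric(1)
  ))
  p_noise <- mean(vapply(
    1:100,
    function(s) permutation_importance(fit, x, y, "noise1", seed = s),
    numeric(1)
  ))
  expect_gt(p_signal, 0.1)
  expect_lt(abs(p_noise), 0.02)
})

test_that("the experiment is reproducible and recovers the signal feature", {
  co <- toy_cohort(n = 160, signal = 2.5)
  cfg <- experiment_config(
    n_repeats = 20, gamma_grid = c(0.01, 0.1, 1),
    cv_folds = 5, master_seed = 7
  )
  r1 <- run_experiment(co, cfg, feature_cols = setdiff(names(co), "wsd_label"))
  r2 <- run_experiment(co, cfg, feature_cols = setdiff(names(co), "wsd_label"))
  expect_identical(r1$importance, r2$importance)
  expect_identical(r1$top_set, r2$top_set)
  expect_equal(r1$importance$feature[1], "f1")
  expect_gt(mean(r1$E), 0.8)

  # noise features stay near zero importance
  noise_rows <- grepl("^noise", r1$importance$feature)
  expect_true(all(abs(r1$importance$mean_pimp[noise_rows]) < 0.03))
})

test_that("a single-repeat report equals that repeat's raw importances", {
  co <- toy_cohort(n = 80)
  cfg <- experiment_config(
    n_repeats = 1, gamma_grid = 0.1, master_seed = 3
  )
  r <- run_experiment(co, cfg, feature_cols = setdiff(names(co), "wsd_label"))
  expect_equal(nrow(r$pimp_matrix), 1)
  expect_equal(
    r$importance$mean_pimp,
    unname(r$pimp_matrix[1, r$importance$feature])
  )
})

test_that("top-set selection follows the cumulative positive-sum rule", {
  mk <- function(v) list(importance = data.frame(
    feature = paste0("f", seq_along(v)), mean_pimp = v
  ))
  expect_equal(select_top(mk(c(0.5, 0.3, 0.1, 0.1)), 0.2), "f1")
  expect_equal(select_top(mk(rep(0.1, 10)), 0.2), c("f1", "f2"))
  expect_warning(
    out <- select_top(mk(c(-0.1, -0.2))),
    "positive"
  )
  expect_length(out, 0)
  # negative importances inflate nothing: positive sum only
  expect_equal(select_top(mk(c(0.6, 0.3, -0.5)), 0.5), "f1")
})

test_that("null labels give every feature importance near zero", {
  set.seed(77)
  n <- 120
  x <- matrix(rnorm(n * 6), nrow = n)
  colnames(x) <- paste0("f", 1:6)
  co <- data.frame(x)
  co$wsd_label <- rep(c(TRUE, FALSE), n / 2) # independent of features
  cfg <- experiment_config(
    n_repeats = 40, gamma_grid = c(0.01, 0.1), cv_folds = 5,
    master_seed = 11
  )
  r <- run_experiment(co, cfg, feature_cols = paste0("f", 1:6))
  se <- r$importance$sd_pimp / sqrt(nrow(r$pimp_matrix))
  expect_true(all(abs(r$importance$mean_pimp) <= pmax(2.5 * se, 0.02)))
})
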