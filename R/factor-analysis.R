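# Machine-learning factor identification: balance the WSD / non-WSD classes
# by random under-sampling, train a Gaussian-kernel SVM with 10-fold
# cross-validation-tuned gamma on repeated stratified 7:3 splits, score each
# feature by permutation importance Pimp(x_j) = E - E_j, average over
# repeats, and keep the features holding the top 20% of the summed
# importance.

#' Experiment settings for WSD factor identification
#'
#' @param n_repeats number of independent under-sample / split / train /
#'   importance repeats.
#' @param split_ratio training fraction of each stratified split.
#' @param cv_folds folds for the gamma cross-validation.
#' @param gamma_grid candidate Gaussian-kernel gamma values.
#' @param svm_cost SVM cost parameter C (fixed, not tuned).
#' @param top_fraction fraction of the summed positive importance kept by
#'   [select_top()].
#' @param master_seed seed driving every stochastic stage.
#' @return A validated list of class `experiment_config`.
#' @export
experiment_config <- function(n_repeats = 100L, split_ratio = 0.7,
                              cv_folds = 10L, gamma_grid = 10^(-3:2),
                              svm_cost = 1, top_fraction = 0.2,
                              master_seed = 1L) {
  if (split_ratio <= 0 || split_ratio >= 1) {
    stop("`split_ratio` must be in (0, 1)", call. = FALSE)
  }
  if (length(gamma_grid) == 0) {
    stop("`gamma_grid` must be non-empty", call. = FALSE)
  }
  if (any(gamma_grid <= 0) || svm_cost <= 0) {
    stop("gamma values and cost must be positive", call. = FALSE)
  }
  structure(
    list(
      n_repeats = as.integer(n_repeats), split_ratio = split_ratio,
      cv_folds = as.integer(cv_folds), gamma_grid = sort(gamma_grid),
      svm_cost = svm_cost, top_fraction = top_fraction,
      master_seed = as.integer(master_seed)
    ),
    class = "experiment_config"
  )
}

#' Balance classes by random under-sampling
#'
#' Randomly discards majority-class rows (without replacement) until both
#' classes have the minority-class size.
#'
#' @param cohort data frame with a logical/two-level label column.
#' @param seed seed for the subsample.
#' @param label name of the label column.
#' @return The balanced data frame (row order: as drawn).
#' @export
undersample <- function(cohort, seed, label = "wsd_label") {
  y <- cohort[[label]]
  if (is.null(y)) stop("label column `", label, "` not found", call. = FALSE)
  pos <- which(y)
  neg <- which(!y)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes must be non-empty for under-sampling", call. = FALSE)
  }
  k <- min(length(pos), length(neg))
  keep <- with_seed(seed, c(
    if (length(pos) > k) sample(pos, k) else pos,
    if (length(neg) > k) sample(neg, k) else neg
  ))
  cohort[keep, , drop = FALSE]
}

# stratified fold assignment: within each class, folds are dealt round-robin
# after a seeded shuffle
stratified_folds <- function(y, folds) {
  assignment <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

#' Tune the Gaussian-kernel width by cross-validation
#'
#' Evaluates each gamma on stratified k-fold cross-validated accuracy and
#' returns the best one, preferring the smallest gamma on ties. When a class
#' has fewer members than `folds`, the fold count is reduced to that size
#' with a warning.
#'
#' @param x numeric feature matrix (training split, already standardized).
#' @param y logical or factor labels.
#' @param gamma_grid candidate gamma values.
#' @param folds number of cross-validation folds.
#' @param cost SVM cost parameter.
#' @return The selected gamma.
#' @export
tune_gamma <- function(x, y, gamma_grid = 10^(-3:2), folds = 10L, cost = 1) {
  if (length(gamma_grid) == 0) stop("empty gamma grid", call. = FALSE)
  gamma_grid <- sort(gamma_grid)
  if (length(gamma_grid) == 1L) {
    return(gamma_grid)
  }
  y <- factor(y)
  min_class <- min(table(y))
  if (min_class < folds) {
    folds <- max(2L, min_class)
    warning("too few samples per class; using ", folds, "-fold CV",
      call. = FALSE
    )
  }
  fold_of <- stratified_folds(y, folds)
  score <- vapply(gamma_grid, function(g) {
    correct <- 0L
    for (f in seq_len(folds)) {
      hold <- fold_of == f
      fit <- e1071::svm(x[!hold, , drop = FALSE], y[!hold],
        kernel = "radial", gamma = g, cost = cost, scale = FALSE
      )
      pred <- stats::predict(fit, x[hold, , drop = FALSE])
      correct <- correct + sum(pred == y[hold])
    }
    correct / length(y)
  }, numeric(1))
  gamma_grid[which.max(score)] # which.max takes the first (smallest) tie
}

#' Permutation importance of one feature
#'
#' `Pimp(x_j) = E - E_j`, where `E` is the model's accuracy on the intact
#' test set and `E_j` its accuracy after one random shuffle of feature `j`
#' within the test set. Negative values mean the shuffle accidentally
#' helped; a constant column shuffles to itself and scores 0.
#'
#' @param model a fitted classifier accepted by [stats::predict()].
#' @param x_test numeric test feature matrix (standardized like training).
#' @param y_test test labels.
#' @param feature column name or index to shuffle.
#' @param seed seed for the shuffle.
#' @return The importance `E - E_j`.
#' @export
permutation_importance <- function(model, x_test, y_test, feature, seed = 1L) {
  if (is.character(feature) && !(feature %in% colnames(x_test))) {
    stop("unknown feature: ", feature, call. = FALSE)
  }
  y_test <- factor(y_test)
  e_full <- mean(stats::predict(model, x_test) == y_test)
  x_perm <- x_test
  x_perm[, feature] <- with_seed(seed, sample(x_perm[, feature]))
  e_perm <- mean(stats::predict(model, x_perm) == y_test)
  e_full - e_perm
}

# one experiment repeat; returns list(E, pimp (named), gamma)
run_repeat <- function(features, labels, cfg) {
  cohort <- data.frame(features, check.names = FALSE)
  cohort$..y <- labels
  seed_inner <- sample.int(2147483646L, 1L)
  balanced <- undersample(cohort, seed_inner, label = "..y")
  y <- factor(balanced$..y, levels = c(FALSE, TRUE))
  x <- as.matrix(balanced[, setdiff(names(balanced), "..y"), drop = FALSE])

  # stratified 7:3 split
  train_idx <- unlist(lapply(levels(y), function(cls) {
    idx <- which(y == cls)
    sample(idx, floor(cfg$split_ratio * length(idx)))
  }))
  x_tr <- x[train_idx, , drop = FALSE]
  y_tr <- y[train_idx]
  x_te <- x[-train_idx, , drop = FALSE]
  y_te <- y[-train_idx]

  # z-score with training-split statistics; constant features pass through
  mu <- colMeans(x_tr)
  sg <- apply(x_tr, 2L, stats::sd)
  sg[sg == 0 | is.na(sg)] <- 1
  x_tr <- sweep(sweep(x_tr, 2L, mu), 2L, sg, "/")
  x_te <- sweep(sweep(x_te, 2L, mu), 2L, sg, "/")

  gamma <- tune_gamma(x_tr, y_tr, cfg$gamma_grid, cfg$cv_folds, cfg$svm_cost)
  fit <- e1071::svm(x_tr, y_tr,
    kernel = "radial", gamma = gamma, cost = cfg$svm_cost, scale = FALSE
  )
  e_full <- mean(stats::predict(fit, x_te) == y_te)

  # one shuffle per feature, evaluated in a single stacked predict call
  n_te <- nrow(x_te)
  d <- ncol(x_te)
  stacked <- x_te[rep(seq_len(n_te), d), , drop = FALSE]
  for (j in seq_len(d)) {
    rows <- (j - 1L) * n_te + seq_len(n_te)
    stacked[rows, j] <- x_te[sample(n_te), j]
  }
  pred <- stats::predict(fit, stacked)
  e_j <- vapply(seq_len(d), function(j) {
    rows <- (j - 1L) * n_te + seq_len(n_te)
    mean(pred[rows] == y_te)
  }, numeric(1))
  names(e_j) <- colnames(x_te)

  list(E = e_full, pimp = e_full - e_j, gamma = gamma)
}

#' Run the repeated SVM permutation-importance experiment
#'
#' For each repeat: a fresh random under-sample, a stratified
#' `split_ratio` train/test split, z-score standardization fitted on the
#' training split, gamma tuning by stratified cross-validation, a
#' Gaussian-kernel SVM fit, and one permutation of every feature on the
#' test split. Mean importances over repeats are ranked and the top set
#' selected with [select_top()]. The whole experiment is deterministic
#' given `config$master_seed`.
#'
#' @param cohort data frame holding the feature columns and the label.
#' @param config an [experiment_config()].
#' @param feature_cols feature column names (default: the 40-feature
#'   battery, [feature_names()]).
#' @param label name of the logical label column.
#' @return A list of class `importance_report`: `importance` (data frame
#'   ranked by mean importance: `feature`, `mean_pimp`, `sd_pimp`),
#'   `top_set` (character), `E` and `gamma` per repeat, `pimp_matrix`
#'   (repeats x features), `n_failed`, and the `config`.
#' @export
run_experiment <- function(cohort, config = experiment_config(),
                           feature_cols = intersect(
                             feature_names(), names(cohort)
                           ),
                           label = "wsd_label") {
  if (!length(feature_cols)) stop("no feature columns found", call. = FALSE)
  if (is.null(cohort[[label]])) {
    stop("label column `", label, "` not found", call. = FALSE)
  }
  complete <- stats::complete.cases(cohort[, feature_cols, drop = FALSE]) &
    !is.na(cohort[[label]])
  dropped <- sum(!complete)
  cohort <- cohort[complete, , drop = FALSE]
  features <- as.matrix(cohort[, feature_cols, drop = FALSE])
  storage.mode(features) <- "double"
  labels <- as.logical(cohort[[label]])

  results <- with_seed(config$master_seed, {
    out <- vector("list", config$n_repeats)
    for (r in seq_len(config$n_repeats)) {
      out[[r]] <- tryCatch(
        run_repeat(features, labels, config),
        error = function(e) e
      )
    }
    out
  })
  failed <- vapply(results, inherits, logical(1), "error")
  if (mean(failed) > 0.1) {
    stop(
      "experiment aborted: ", sum(failed), "/", length(failed),
      " repeats failed; first error: ",
      conditionMessage(results[[which(failed)[1L]]]),
      call. = FALSE
    )
  }
  results <- results[!failed]

  pimp <- do.call(rbind, lapply(results, `[[`, "pimp"))
  mean_pimp <- colMeans(pimp)
  importance <- data.frame(
    feature = colnames(pimp),
    mean_pimp = mean_pimp,
    sd_pimp = apply(pimp, 2L, stats::sd),
    row.names = NULL
  )
  importance <- importance[order(-importance$mean_pimp), , drop = FALSE]
  rownames(importance) <- NULL

  report <- list(
    importance = importance,
    top_set = character(0),
    E = vapply(results, `[[`, numeric(1), "E"),
    gamma = vapply(results, `[[`, numeric(1), "gamma"),
    pimp_matrix = pimp,
    n_failed = sum(failed),
    n_dropped = dropped,
    config = config
  )
  report$top_set <- select_top(report, config$top_fraction)
  class(report) <- "importance_report"
  report
}

#' Select the features holding the top share of summed importance
#'
#' Features are ranked by mean permutation importance; the smallest prefix
#' whose cumulative importance reaches `top_fraction` of the summed
#' positive importances is returned. When no feature has positive mean
#' importance the set is empty, with a warning.
#'
#' @param report an `importance_report` from [run_experiment()], or any
#'   list with an `importance` data frame.
#' @param top_fraction fraction of the positive importance sum to cover.
#' @return Character vector of selected feature names.
#' @export
select_top <- function(report, top_fraction = 0.2) {
  imp <- report$importance
  imp <- imp[order(-imp$mean_pimp), , drop = FALSE]
  total <- sum(imp$mean_pimp[imp$mean_pimp > 0])
  if (total <= 0) {
    warning("no feature has positive mean importance", call. = FALSE)
    return(character(0))
  }
  cum <- cumsum(imp$mean_pimp)
  k <- which(cum >= top_fraction * total)[1L]
  imp$feature[seq_len(k)]
}

#' @export
print.importance_report <- function(x, n = 10L, ...) {
  cat(
    "WSD factor-identification report:",
    length(x$E), "repeats,",
    "mean test accuracy", sprintf("%.3f", mean(x$E)), "\n"
  )
  cat(
    "top importance set (", sprintf("%.0f%%", 100 * x$config$top_fraction),
    " of summed positive importance): ",
    paste(x$top_set, collapse = ", "), "\n",
    sep = ""
  )
  print(utils::head(x$importance, n), ...)
  invisible(x)
}
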