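#' Log-power feature matrix for hemifield decoding
#'
#' Takes the window-averaged alpha power per trial and sensor, restricts
#' it to a sensor subset, and applies the natural logarithm elementwise.
#' A global power rescaling therefore only shifts every feature by a
#' constant, which a linear classifier absorbs in its bias.
#'
#' @param summary An `alpha_summary` from [window_average()].
#' @param sensor_subset Integer sensor indices (default: all sensors).
#' @param rows Optional row (trial) filter.
#' @return A `feature_matrix`: list with `x` (trials x selected sensors),
#'   `y` (factor hemifield labels), `trials` (metadata) and `sensors_used`.
#' @export
log_power_features <- function(summary, sensor_subset = NULL, rows = NULL) {
  rows <- rows %||% seq_len(nrow(summary$power))
  sensor_subset <- sensor_subset %||% seq_len(ncol(summary$power))
  p <- summary$power[rows, sensor_subset, drop = FALSE]
  if (any(p <= 0)) {
    bad <- which(p <= 0, arr.ind = TRUE)[1L, ]
    abort(sprintf("nonpositive power at trial %d, sensor %d; cannot log-transform.",
                  bad[1L], sensor_subset[bad[2L]]))
  }
  structure(
    list(x = log(p),
         y = factor(summary$trials$hemifield[rows], levels = c("left", "right")),
         trials = summary$trials[rows, , drop = FALSE],
         sensors_used = sensor_subset),
    class = "feature_matrix"
  )
}

#' Leave-subject-out ROI sensor selection
#'
#' Defines the two hemispheric ROIs from the condition-averaged
#' modulation maps of all subjects except the held-out one (so the
#' held-out subject's own data never influences their feature selection)
#' and returns the union of the two ROIs. If the reduced cohort yields no
#' significant cluster, the selection falls back to all non-midline
#' sensors, flagged in the result.
#'
#' @param maps Subjects x sensors modulation matrix (see
#'   [condition_average_maps()]); rows in subject order.
#' @param held_out Row index of the held-out subject.
#' @param sensors A `sensor_array`.
#' @param ... Passed to [define_rois()].
#' @return A list with `sensors` (integer indices), `fallback` (logical)
#'   and the `roi_pair` in `rois`.
#' @export
loso_sensor_selection <- function(maps, held_out, sensors, ...) {
  if (nrow(maps) < 3L) abort("leave-subject-out selection needs >= 3 subjects.")
  rois <- define_rois(maps[-held_out, , drop = FALSE], sensors, ...)
  sel <- sort(c(rois$left, rois$right))
  fallback <- length(sel) == 0L
  if (fallback) sel <- which(sensors$hemisphere != "midline")
  list(sensors = sel, fallback = fallback, rois = rois)
}

#' Nested cross-validated linear max-margin decoding accuracy
#'
#' Splits the trials into `outer_folds` sequential contiguous folds (the
#' trial stream is label-interleaved by design, so every fold contains
#' both classes). For each outer fold, an inner sequential
#' cross-validation on the training 90% picks the regularization
#' parameter (SVM cost) from `cost_grid` maximizing inner accuracy —
#' ties resolved toward stronger regularization (smaller cost) — after
#' which a linear support-vector machine is refit on the whole training
#' set and scored on the held-out fold.
#'
#' @param features A `feature_matrix`.
#' @param outer_folds,inner_folds Fold counts.
#' @param cost_grid Candidate SVM cost values (ascending).
#' @return A `cv_result`: list with `folds` (tibble: `fold`, `n_test`,
#'   `n_correct`, `accuracy`, `cost`) and `mean_accuracy` (mean over
#'   folds). `glance()` summarises; `tidy()` returns the fold table.
#' @export
nested_cv_accuracy <- function(features, outer_folds = 10, inner_folds = 5,
                               cost_grid = 10^seq(-3, 3)) {
  x <- features$x
  y <- features$y
  n <- nrow(x)
  if (min(table(y)) < 10L) abort("need at least 10 trials per class.")
  cost_grid <- sort(cost_grid)
  fold_id <- sequential_folds(n, outer_folds)
  folds <- lapply(seq_len(outer_folds), function(f) {
    test <- which(fold_id == f)
    train <- which(fold_id != f)
    if (nlevels(droplevels(y[train])) < 2L) {
      abort("a training fold lost one of the classes.")
    }
    inner_id <- sequential_folds(length(train), inner_folds)
    inner_acc <- vapply(cost_grid, function(cc) {
      mean(vapply(seq_len(inner_folds), function(g) {
        itr <- train[inner_id != g]
        ite <- train[inner_id == g]
        if (nlevels(droplevels(y[itr])) < 2L) return(NA_real_)
        fit <- svm_linear(x[itr, , drop = FALSE], y[itr], cc)
        mean(predict(fit, x[ite, , drop = FALSE]) == y[ite])
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    best <- cost_grid[which.max(inner_acc)]  # first max = smallest cost
    fit <- svm_linear(x[train, , drop = FALSE], y[train], best)
    pred <- predict(fit, x[test, , drop = FALSE])
    tibble::tibble(fold = f, n_test = length(test),
                   n_correct = sum(pred == y[test]),
                   accuracy = mean(pred == y[test]), cost = best)
  })
  folds <- dplyr::bind_rows(folds)
  structure(
    list(folds = folds, mean_accuracy = mean(folds$accuracy), n_trials = n),
    class = "cv_result"
  )
}

# contiguous near-equal blocks, in presentation order
sequential_folds <- function(n, k) {
  ((seq_len(n) - 1L) * k) %/% n + 1L
}

#' Linear maximum-margin classifier
#'
#' Binary linear support-vector machine (hinge loss, cost `C`
#' regularization), solved by dual coordinate descent with the bias
#' absorbed as an augmented constant feature. Features are standardized
#' using the training data only; the stored scaling is re-applied at
#' prediction time.
#'
#' @param x Numeric feature matrix (trials x features).
#' @param y Two-level factor of class labels.
#' @param cost SVM cost parameter (> 0).
#' @param eps Convergence tolerance on the projected-gradient range.
#' @param max_passes Maximum coordinate-descent sweeps.
#' @return An `svm_linear` fit with a `predict()` method.
#' @export
svm_linear <- function(x, y, cost, eps = 0.05, max_passes = 1000) {
  y <- droplevels(factor(y))
  if (nlevels(y) != 2L) abort("`y` must have exactly two classes.")
  ys <- ifelse(as.integer(y) == 1L, 1, -1)
  center <- colMeans(x)
  scale <- apply(x, 2L, sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale, `/`)
  w <- dcd_svm_cpp(cbind(xs, 1), ys, cost, eps, as.integer(max_passes))
  structure(
    list(w = w[-length(w)], b = w[length(w)], center = center,
         scale = scale, levels = levels(y), cost = cost),
    class = "svm_linear"
  )
}

#' @export
predict.svm_linear <- function(object, newdata, ...) {
  xs <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, `/`)
  score <- as.numeric(xs %*% object$w + object$b)
  factor(ifelse(score >= 0, object$levels[1L], object$levels[2L]),
         levels = object$levels)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: mean accuracy %.3f over %d folds (%d trials)>\n",
              x$mean_accuracy, nrow(x$folds), x$n_trials))
  invisible(x)
}

#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy,
                 n_folds = nrow(x$folds), n_trials = x$n_trials)
}

#' Decode left vs right attention for every subject and condition
#'
#' For each subject, selects sensors with the leave-subject-out ROI
#' procedure, then runs the nested cross-validated decoder per condition
#' on (a) the selected-sensor features and (b) all non-midline sensors as
#' separate features. Per-subject significance against the 50% chance
#' level is assessed with a Clopper-Pearson interval on the fold-pooled
#' correct counts.
#'
#' @param summary An `alpha_summary` of the combined planar alpha power.
#' @param maps Subjects x sensors condition-averaged modulation matrix.
#' @param sensors A `sensor_array`.
#' @param feature_sets Character subset of `c("roi", "all")`.
#' @param outer_folds,inner_folds,cost_grid Passed to
#'   [nested_cv_accuracy()].
#' @param ... Passed to [loso_sensor_selection()] (e.g. `n_perm`, `seed`).
#' @return A tibble with one row per subject x condition x feature set:
#'   `subject`, `difficulty`, `eccentricity`, `feature_set`, `accuracy`,
#'   `n_trials`, `n_correct`, `fallback`, `significant`.
#' @export
classify_all <- function(summary, maps, sensors,
                         feature_sets = c("roi", "all"),
                         outer_folds = 10, inner_folds = 5,
                         cost_grid = 10^seq(-3, 3), ...) {
  feature_sets <- match.arg(feature_sets, several.ok = TRUE)
  meta <- summary$trials
  subjects <- sort(unique(meta$subject))
  all_idx <- which(sensors$hemisphere != "midline")
  out <- list()
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    sel <- if ("roi" %in% feature_sets) {
      loso_sensor_selection(maps, si, sensors, ...)
    }
    cells <- dplyr::distinct(meta[meta$subject == s,
                                  c("difficulty", "eccentricity")])
    for (ci in seq_len(nrow(cells))) {
      rows <- which(meta$subject == s &
                      meta$difficulty == cells$difficulty[ci] &
                      meta$eccentricity == cells$eccentricity[ci])
      for (fset in feature_sets) {
        idx <- if (fset == "roi") sel$sensors else all_idx
        feats <- log_power_features(summary, idx, rows)
        cv <- nested_cv_accuracy(feats, outer_folds, inner_folds, cost_grid)
        ci95 <- binomial_ci(sum(cv$folds$n_correct), sum(cv$folds$n_test))
        out[[length(out) + 1L]] <- tibble::tibble(
          subject = s,
          difficulty = cells$difficulty[ci],
          eccentricity = cells$eccentricity[ci],
          feature_set = fset,
          accuracy = cv$mean_accuracy,
          n_trials = cv$n_trials,
          n_correct = sum(cv$folds$n_correct),
          fallback = if (fset == "roi") sel$fallback else FALSE,
          significant = ci95$lower > 0.5
        )
      }
    }
  }
  dplyr::bind_rows(out)
}
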