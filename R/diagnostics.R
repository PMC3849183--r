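#' Type-I calibration of the cluster permutation test
#'
#' Monte-Carlo check of the within-subject cluster-based sign-flip test
#' under the global null: generates `n_datasets` subject x sensor
#' matrices of i.i.d. standard-normal modulation values on a
#' mirror-symmetric grid layout, runs the test on each, and records
#' whether any cluster attains a corrected p-value below `alpha`. For a
#' calibrated test the rejection fraction is at most the nominal level
#' (up to Monte-Carlo error).
#'
#' @param n_datasets Number of null datasets.
#' @param n_subjects,n_sensors Dimensions of each dataset.
#' @param n_perm Randomizations per dataset.
#' @param alpha Nominal level.
#' @param seed Seed for the whole study.
#' @return A list with `rejection_rate`, `n_datasets`, `mc_se` (binomial
#'   Monte-Carlo standard error at `alpha`) and the per-dataset tibble
#'   `runs`.
#' @export
calibrate_cluster_test <- function(n_datasets = 200, n_subjects = 14,
                                   n_sensors = 30, n_perm = 500,
                                   alpha = 0.05, seed = 1L) {
  sensors <- make_sensor_array(n_sensors, "grid")
  adj <- sensor_adjacency(sensors, "list")
  runs <- withr::with_seed(seed, {
    lapply(seq_len(n_datasets), function(i) {
      values <- matrix(rnorm(n_subjects * n_sensors), n_subjects)
      res <- cluster_permutation_test(values, adj, cluster_alpha = alpha,
                                      n_perm = n_perm)
      tibble::tibble(
        dataset = i,
        n_clusters = nrow(res$clusters),
        min_p = if (nrow(res$clusters)) min(res$clusters$p.value) else NA_real_,
        rejected = nrow(res$clusters) > 0 && min(res$clusters$p.value) < alpha
      )
    })
  })
  runs <- dplyr::bind_rows(runs)
  list(
    rejection_rate = mean(runs$rejected),
    n_datasets = n_datasets,
    mc_se = sqrt(alpha * (1 - alpha) / n_datasets),
    runs = runs
  )
}

#' Chance-level decoding on null datasets
#'
#' Generates replicate datasets with every attention effect set to zero,
#' runs each through the standard path — rejection cascade, planar
#' gradient, sliding Hanning alpha power, window-averaged log-power
#' features over all sensors, nested cross-validated linear decoding —
#' and reports the mean fold accuracy per replicate. For an unbiased
#' decoder the grand mean accuracy lies at the 50% chance level within
#' the binomial error of the pooled trial count.
#'
#' @param n_replicates Number of replicate datasets.
#' @param n_trials_per_condition Trials per condition per replicate
#'   (labels are balanced and interleaved by construction).
#' @param n_sensors Sensor count of the grid layout.
#' @param seed Seed for the whole study.
#' @return A list with `mean_accuracy` (grand mean over replicates),
#'   `pooled_n` (total trials scored), `pooled_correct`, and the
#'   per-replicate tibble `runs`.
#' @export
chance_decoding <- function(n_replicates = 50, n_trials_per_condition = 40,
                            n_sensors = 30, seed = 1L) {
  child_seeds <- withr::with_seed(seed, {
    sample.int(.Machine$integer.max - 1L, n_replicates)
  })
  runs <- lapply(seq_len(n_replicates), function(i) {
    cfg <- generator_preset("null", n_subjects = 1,
                            n_trials_per_condition = n_trials_per_condition,
                            n_sensors = n_sensors, seed = child_seeds[i])
    dataset <- generate_dataset(cfg)
    pp <- preprocess(dataset)
    power <- planar_alpha_power(pp$dataset, tmin = 1, tmax = 2.5)
    summ <- window_average(power)
    feats <- log_power_features(summ)  # all sensors: the flagged fallback set
    cv <- nested_cv_accuracy(feats)
    tibble::tibble(replicate = i, accuracy = cv$mean_accuracy,
                   n_trials = cv$n_trials,
                   n_correct = sum(cv$folds$n_correct),
                   n_test = sum(cv$folds$n_test))
  })
  runs <- dplyr::bind_rows(runs)
  list(
    mean_accuracy = mean(runs$accuracy),
    pooled_n = sum(runs$n_test),
    pooled_correct = sum(runs$n_correct),
    runs = runs
  )
}
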