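#' Pipeline configuration
#'
#' Bundles the per-stage settings of the end-to-end analysis
#' (simulate -> preprocess -> spectral -> lateralization statistics ->
#' decoding) with a single global seed fanned out to fixed per-stage
#' child seeds, so stages are reproducible yet use independent streams.
#'
#' @param preset Generator preset name (see [generator_preset()]).
#' @param seed Global integer seed.
#' @param n_perm Randomizations for the cluster permutation tests.
#' @param cluster_alpha,roi_alpha Cluster-forming and ROI-inclusion
#'   alphas.
#' @param analysis_window Post-cue window for power averaging and
#'   temporal tests, s.
#' @param baseline Baseline window for z-normalization, s.
#' @param feature_sets Decoder feature sets (`"roi"`, `"all"`).
#' @param outer_folds,inner_folds,cost_grid Decoder settings.
#' @param ... Overrides forwarded to [generator_preset()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preset = "paper", seed = 1L, n_perm = 1000,
                            cluster_alpha = 0.05, roi_alpha = 0.05,
                            analysis_window = c(1, 2.5),
                            baseline = c(-0.75, -0.25),
                            feature_sets = c("roi", "all"),
                            outer_folds = 10, inner_folds = 5,
                            cost_grid = 10^seq(-3, 3), ...) {
  structure(
    list(
      preset = preset, seed = as.integer(seed),
      generator = generator_preset(preset, seed = as.integer(seed), ...),
      stats = list(n_perm = n_perm, cluster_alpha = cluster_alpha,
                   roi_alpha = roi_alpha, seed = as.integer(seed) + 1000003L),
      analysis_window = analysis_window, baseline = baseline,
      decode = list(feature_sets = feature_sets, outer_folds = outer_folds,
                    inner_folds = inner_folds, cost_grid = cost_grid)
    ),
    class = "pipeline_config"
  )
}

#' @describeIn pipeline_config Read a pipeline configuration from a YAML
#'   key/value file; keys mirror the function arguments (generator
#'   overrides under a `generator:` block).
#' @param path Path to the YAML file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- y$generator %||% list()
  y$generator <- NULL
  do.call(pipeline_config, c(y, gen))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", stage, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Executes generation, the rejection cascade, the planar-gradient
#' alpha-power estimation, modulation/lateralization statistics with
#' cluster-permutation ROI definition, temporal cluster tests of the
#' easy-vs-difficult lateralization timecourse, behavioural statistics,
#' and per-subject left/right decoding. Any stage failure aborts with a
#' stage-tagged message. Identical configurations produce identical
#' results.
#'
#' @param config A [pipeline_config()].
#' @return An `attn_pipeline` list with tibbles `summary`,
#'   `lateralization`, `modulation`, `roi`, `clusters`, `anova`,
#'   `behavior`, `decode`, `rejection` and `log`, plus the fitted
#'   objects in `objects`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dataset <- run_stage("simulate", generate_dataset(config$generator))
  pp <- run_stage("preprocess", preprocess(dataset))
  power <- run_stage("spectral", planar_alpha_power(pp$dataset))
  summ <- run_stage("spectral", window_average(power, config$analysis_window))
  maps <- run_stage("stats", modulation_maps(summ))
  cam <- run_stage("stats", condition_average_maps(maps))
  rois <- run_stage("stats", define_rois(
    cam, dataset$sensors, roi_alpha = config$stats$roi_alpha,
    cluster_alpha = config$stats$cluster_alpha,
    n_perm = config$stats$n_perm, seed = config$stats$seed
  ))
  if (!length(rois$left) || !length(rois$right)) {
    abort("[stats] no significant sensor cluster in one or both hemispheres; cannot define ROIs.")
  }
  al <- run_stage("stats", lateralization_table(maps, rois))
  anova_al <- run_stage("stats", rm_anova_2x2(al, "al"))
  al_diff <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(al, .data$subject, .data$difficulty),
                     al = mean(.data$al), .groups = "drop"),
    names_from = "difficulty", values_from = "al"
  )
  wx_al <- run_stage("stats",
                     wilcoxon_signed_rank(al_diff$difficult, al_diff$easy))

  rtc <- run_stage("spectral", roi_timecourses(power, rois))
  alt <- run_stage("stats", lateralization_timecourse(rtc))
  tct <- run_stage("stats", timecourse_cluster_test(
    alt$difficult, alt$easy, time = alt$time,
    window = config$analysis_window,
    cluster_alpha = config$stats$cluster_alpha,
    n_perm = config$stats$n_perm, seed = config$stats$seed
  ))

  beh <- run_stage("behavior", behavior_stats(pp$dataset$trials))
  decode <- run_stage("decode", classify_all(
    summ, cam, dataset$sensors,
    feature_sets = config$decode$feature_sets,
    outer_folds = config$decode$outer_folds,
    inner_folds = config$decode$inner_folds,
    cost_grid = config$decode$cost_grid,
    roi_alpha = config$stats$roi_alpha,
    cluster_alpha = config$stats$cluster_alpha,
    n_perm = config$stats$n_perm, seed = config$stats$seed
  ))

  cond_sum <- dplyr::summarise(
    dplyr::group_by(al, .data$difficulty, .data$eccentricity),
    al = mean(.data$al), .groups = "drop"
  )
  dec_sum <- dplyr::summarise(
    dplyr::group_by(decode, .data$difficulty, .data$eccentricity,
                    .data$feature_set),
    accuracy = mean(.data$accuracy), .groups = "drop"
  )
  summary_tbl <- dplyr::left_join(
    cond_sum,
    tidyr::pivot_wider(dec_sum, names_from = "feature_set",
                       values_from = "accuracy",
                       names_prefix = "accuracy_"),
    by = c("difficulty", "eccentricity")
  )
  anova_tbl <- dplyr::bind_rows(
    dplyr::mutate(tidy(anova_al), analysis = "lateralization"),
    dplyr::mutate(tidy(beh$anova_accuracy), analysis = "accuracy"),
    dplyr::mutate(tidy(beh$anova_rt), analysis = "rt")
  )
  roi_tbl <- tibble::tibble(
    sensor = c(rois$left, rois$right),
    label = dataset$sensors$label[c(rois$left, rois$right)],
    hemisphere = c(rep("left", length(rois$left)),
                   rep("right", length(rois$right)))
  )
  clusters_tbl <- dplyr::bind_rows(
    dplyr::mutate(tidy(rois$clusters), analysis = "sensor_roi"),
    dplyr::mutate(tidy(tct), analysis = "al_difficulty_time")
  )
  log_tbl <- tibble::tibble(
    key = c("seed", "preset", "n_subjects", "n_trials_generated",
            "n_trials_surviving", "n_perm",
            paste0("removed_", unique(pp$report$rule))),
    value = as.character(c(
      config$seed, config$preset, config$generator$n_subjects,
      nrow(dataset$trials), nrow(pp$dataset$trials), config$stats$n_perm,
      vapply(unique(pp$report$rule), function(r) {
        sum(pp$report$n_removed[pp$report$rule == r])
      }, numeric(1))
    ))
  )
  structure(
    list(summary = summary_tbl, lateralization = al, modulation = maps,
         roi = roi_tbl, clusters = clusters_tbl, anova = anova_tbl,
         behavior = beh$table, decode = decode, rejection = pp$report,
         log = log_tbl, wilcoxon_al = wx_al, config = config,
         objects = list(rois = rois, anova_al = anova_al,
                        timecourse_test = tct, al_timecourse = alt,
                        behavior = beh)),
    class = "attn_pipeline"
  )
}

# per-subject x difficulty lateralization timecourse from raw ROI power
#' Time-resolved lateralization per difficulty level
#'
#' For each subject, difficulty level and time step, averages the ROI
#' power over trials per attended hemifield, forms the modulation index
#' per hemisphere ROI, and takes the left-minus-right ROI difference.
#'
#' @param rtc A `roi_timecourse` (raw, not baseline-normalized: the
#'   modulation index is a ratio of powers).
#' @return A list with matrices `easy` and `difficult` (subjects x time
#'   steps) and the `time` axis.
#' @export
lateralization_timecourse <- function(rtc) {
  meta <- rtc$trials
  subjects <- sort(unique(meta$subject))
  out <- list(time = rtc$time)
  for (dif in c("easy", "difficult")) {
    m <- matrix(NA_real_, length(subjects), length(rtc$time))
    for (si in seq_along(subjects)) {
      selL <- meta$subject == subjects[si] & meta$difficulty == dif &
        meta$hemifield == "left"
      selR <- meta$subject == subjects[si] & meta$difficulty == dif &
        meta$hemifield == "right"
      pl <- apply(rtc$power[selL, , , drop = FALSE], c(2L, 3L), mean)
      pr <- apply(rtc$power[selR, , , drop = FALSE], c(2L, 3L), mean)
      am <- (pl - pr) / (pl + pr)  # hemisphere x time
      m[si, ] <- am[1L, ] - am[2L, ]
    }
    out[[dif]] <- m
  }
  out
}

behavior_stats <- function(trials) {
  per_cell <- dplyr::summarise(
    dplyr::group_by(trials, .data$subject, .data$difficulty,
                    .data$eccentricity),
    accuracy = mean(.data$correct), rt = mean(.data$rt), .groups = "drop"
  )
  acc_diff <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(per_cell, .data$subject, .data$difficulty),
                     accuracy = mean(.data$accuracy), .groups = "drop"),
    names_from = "difficulty", values_from = "accuracy"
  )
  per_subject_ci <- dplyr::summarise(
    dplyr::group_by(trials, .data$subject, .data$difficulty),
    k = sum(.data$correct), n = dplyr::n(), .groups = "drop"
  )
  per_subject_ci <- dplyr::bind_cols(
    per_subject_ci,
    binomial_ci(per_subject_ci$k, per_subject_ci$n)[, c("lower", "upper")]
  )
  list(
    table = per_cell,
    anova_accuracy = rm_anova_2x2(per_cell, "accuracy"),
    anova_rt = rm_anova_2x2(per_cell, "rt"),
    wilcoxon_accuracy = wilcoxon_signed_rank(acc_diff$difficult, acc_diff$easy),
    binomial = per_subject_ci,
    rt_trend = accuracy_rt_trend(trials)
  )
}

#' @export
print.attn_pipeline <- function(x, ...) {
  cat("<attn_pipeline>\n\nCondition summary:\n")
  print(x$summary)
  invisible(x)
}

#' Write the pipeline result tables to TSV files
#'
#' Writes `summary.tsv`, `lateralization.tsv` (columns subject,
#' difficulty, eccentricity, AL), `modulation.tsv`, `roi.tsv`,
#' `clusters.tsv`, `anova.tsv`, `decode.tsv`, `report.tsv` and `log.tsv`
#' with floats at 6 significant digits.
#'
#' @param results An `attn_pipeline` (or a named list of data frames).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort("cannot create output directory ", out_dir)
  }
  tables <- if (inherits(results, "attn_pipeline")) {
    list(
      summary = results$summary,
      lateralization = dplyr::rename(results$lateralization, AL = "al"),
      modulation = dplyr::rename(
        results$modulation[, c("subject", "difficulty", "eccentricity",
                               "sensor", "am")], AM = "am"),
      roi = results$roi,
      clusters = results$clusters,
      anova = results$anova,
      decode = results$decode,
      report = results$rejection,
      log = results$log
    )
  } else {
    results
  }
  paths <- character(0)
  for (nm in names(tables)) {
    tb <- dplyr::mutate(tibble::as_tibble(tables[[nm]]),
                        dplyr::across(dplyr::where(is.double), ~ signif(.x, 6)))
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tb, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @describeIn run_pipeline Plot the grand-average lateralization
#'   timecourse per difficulty level.
#' @param object,... An `attn_pipeline` and ignored arguments.
#' @method autoplot attn_pipeline
#' @export
autoplot.attn_pipeline <- function(object, ...) {
  alt <- object$objects$al_timecourse
  df <- dplyr::bind_rows(
    tibble::tibble(time = alt$time, al = colMeans(alt$easy),
                   difficulty = "easy"),
    tibble::tibble(time = alt$time, al = colMeans(alt$difficult),
                   difficulty = "difficult")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$al,
                                   colour = .data$difficulty)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time relative to cue onset (s)",
                  y = "alpha lateralization",
                  title = "Grand-average lateralization timecourse") +
    ggplot2::theme_minimal()
}
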