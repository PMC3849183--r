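# simulation experiments used by the acceptance-style tests

# one effect-size-grid replicate: small cohort, fixed posterior-band ROIs
# (ROI selection cannot run at zero effect), pipeline AL plus single-subject
# pooled decoding accuracy
recovery_replicate <- function(effect_scale, seed) {
  cfg <- generator_config(
    n_subjects = 4, n_trials_per_condition = 8, n_sensors = 12,
    contra_decrease = c(easy = 0.055, difficult = 0.085) * effect_scale,
    ipsi_increase = c(easy = 0.028, difficult = 0.043) * effect_scale,
    seed = seed
  )
  ds <- generate_dataset(cfg)
  pp <- preprocess(ds)
  pw <- planar_alpha_power(pp$dataset, tmin = 1, tmax = 2.5)
  summ <- window_average(pw)
  maps <- modulation_maps(summ)
  sens <- ds$sensors
  rois <- list(left = which(sens$posterior & sens$hemisphere == "left"),
               right = which(sens$posterior & sens$hemisphere == "right"))
  al <- mean(lateralization_table(maps, rois)$al)
  rows <- which(summ$trials$subject == 1)
  cv <- nested_cv_accuracy(log_power_features(summ, rows = rows))
  tibble::tibble(effect_scale = effect_scale, seed = seed, al = al,
                 accuracy = cv$mean_accuracy)
}

# one full-design sensitivity replicate at the default ("paper") preset:
# ROI definition by cluster permutation, lateralization per condition,
# 2x2 within-subject ANOVA
sensitivity_replicate <- function(seed, n_trials = 12) {
  cfg <- generator_preset("paper", n_subjects = 14,
                          n_trials_per_condition = n_trials,
                          n_sensors = 30, seed = seed)
  ds <- generate_dataset(cfg)
  pp <- preprocess(ds)
  pw <- planar_alpha_power(pp$dataset, tmin = 1, tmax = 2.5)
  summ <- window_average(pw)
  maps <- modulation_maps(summ)
  cam <- condition_average_maps(maps)
  rois <- define_rois(cam, ds$sensors, n_perm = 500, seed = seed + 7)
  if (!length(rois$left) || !length(rois$right)) {
    return(tibble::tibble(seed = seed, p_diff = NA_real_, p_ecc = NA_real_,
                          al_easy = NA_real_, al_diff = NA_real_))
  }
  al <- lateralization_table(maps, rois)
  an <- tidy(rm_anova_2x2(al, "al"))
  tibble::tibble(
    seed = seed,
    p_diff = an$p.value[an$term == "difficulty"],
    p_ecc = an$p.value[an$term == "eccentricity"],
    al_easy = mean(al$al[al$difficulty == "easy"]),
    al_diff = mean(al$al[al$difficulty == "difficult"])
  )
}
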