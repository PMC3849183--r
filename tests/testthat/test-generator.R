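test_that("pre-target mixture has the right support, weights and means", {
  withr::with_seed(11, {
    x <- sample_pretarget_period(10000)
  })
  expect_true(all(x >= 0.5 & x <= 3))
  # 90/10 mixture split at 2 s
  p_long <- mean(x >= 2)
  expect_lt(abs(p_long - 0.9), 3 * sqrt(0.9 * 0.1 / 10000))
  short <- x[x < 2]
  se_short <- sd(short) / sqrt(length(short))
  expect_lt(abs(mean(short) - 0.8), 3 * se_short)
  long <- x[x >= 2]
  expect_lt(abs(mean(long) - 2.5), 3 * sd(long) / sqrt(length(long)))
})

test_that("psychometric function hits its anchor points", {
  expect_equal(psychometric_accuracy(0, threshold = 0.1), 0.5)
  expect_equal(psychometric_accuracy(0.1, threshold = 0.1), 0.75)
  expect_gte(psychometric_accuracy(1, threshold = 0.05), 0.95)
  expect_error(psychometric_accuracy(0.5, threshold = 0), "positive")
  # inverse round-trips
  for (p in c(0.6, 0.75, 0.9, 0.96)) {
    cc <- contrast_for_accuracy(p, threshold = 0.12)
    expect_equal(psychometric_accuracy(cc, threshold = 0.12), p, tolerance = 1e-9)
  }
})

test_that("behavioural draws match the condition presets", {
  cfg <- generator_config()
  withr::with_seed(21, {
    easy <- sample_behavior(rep("easy", 10000), cfg)
    diff <- sample_behavior(rep("difficult", 10000), cfg)
  })
  expect_lt(abs(mean(easy$rt) - 0.571), 0.01)
  expect_lt(abs(mean(diff$rt) - 0.763), 0.015)
  expect_lt(abs(mean(easy$correct) - 0.96), 0.01)
  expect_lt(abs(mean(diff$correct) - 0.75), 0.015)
  # slower and less accurate when difficult
  expect_gt(mean(diff$rt), mean(easy$rt))
  expect_lt(mean(diff$correct), mean(easy$correct))
  # degenerate RT distribution collapses onto the configured mean
  cfg0 <- generator_config(rt_sigma = 0)
  withr::with_seed(3, rts <- sample_behavior(rep("easy", 50), cfg0)$rt)
  expect_true(all(abs(rts - 0.571) < 1e-12))
})

test_that("placeholder diameters follow the calibrated magnification law", {
  expect_equal(placeholder_diameter(3.5), 1.04, tolerance = 1e-12)
  expect_equal(placeholder_diameter(7), 1.40, tolerance = 1e-12)
  e <- seq(0.5, 12, by = 0.5)
  expect_true(all(diff(placeholder_diameter(e)) > 0))
  expect_error(placeholder_diameter(0), "singularity")
})

test_that("equal seeds give identical datasets", {
  cfg <- generator_preset("small-test", n_subjects = 2,
                          n_trials_per_condition = 4, seed = 99)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$trials, d2$trials)
  d3 <- generate_dataset(generator_preset("small-test", n_subjects = 2,
                                          n_trials_per_condition = 4,
                                          seed = 100))
  expect_false(identical(d1$trials$data[[1]], d3$trials$data[[1]]))
})

test_that("conditions are balanced and hemifields interleaved", {
  ds <- tiny_dataset()
  tab <- table(ds$trials$difficulty, ds$trials$eccentricity,
               ds$trials$hemifield)
  expect_true(all(tab == tab[1]))
  # consecutive trials of the same condition alternate hemifield
  for (s in unique(ds$trials$subject)) {
    tr <- ds$trials[ds$trials$subject == s, ]
    for (cond in split(tr, paste(tr$difficulty, tr$eccentricity))) {
      expect_true(all(cond$hemifield == rep_len(c("left", "right"), nrow(cond))))
    }
  }
})

test_that("null configuration leaves alpha power independent of hemifield", {
  cfg <- generator_preset("null", n_subjects = 1,
                          n_trials_per_condition = 150, n_sensors = 16,
                          seed = 5)
  ds <- generate_dataset(cfg)
  pw <- sliding_alpha_power(ds, tmin = 1, tmax = 2.5)
  summ <- window_average(pw)
  left <- summ$trials$hemifield == "left"
  tvals <- vapply(seq_len(ncol(summ$power)), function(j) {
    unname(t.test(summ$power[left, j], summ$power[!left, j])$statistic)
  }, numeric(1))
  # no sensor shows a systematic hemifield difference
  expect_lt(max(abs(tvals)), 4.5)
  expect_lt(mean(abs(tvals) > 2), 0.2)
})

test_that("planted effects produce the expected modulation sign pattern", {
  ds <- tiny_dataset()
  pw <- planar_alpha_power(ds, tmin = 1, tmax = 2.5)
  maps <- modulation_maps(window_average(pw))
  cam <- condition_average_maps(maps)
  post_left <- which(ds$sensors$posterior & ds$sensors$hemisphere == "left")
  post_right <- which(ds$sensors$posterior & ds$sensors$hemisphere == "right")
  # ipsilateral increase: positive modulation over left posterior sensors
  expect_gt(mean(cam[, post_left]), 0)
  expect_lt(mean(cam[, post_right]), 0)
})

test_that("artifact injection flags exactly the requested trials", {
  cfg <- generator_preset("null", n_subjects = 1,
                          n_trials_per_condition = 26, n_sensors = 6, seed = 8)
  ds <- generate_dataset(cfg)
  # identity at zero rates
  out0 <- inject_artifacts(ds, list(gaze = 0, power = 0, rt = 0), seed = 1)
  expect_identical(out0$dataset$trials, ds$trials)
  expect_equal(nrow(out0$injected), 0)

  n <- nrow(ds$trials)
  out <- inject_artifacts(ds, list(gaze = 0.1, power = 0.05, rt = 0.1),
                          seed = 2)
  expect_equal(sum(out$injected$rule == "gaze"), round(0.1 * n))
  expect_equal(sum(out$injected$rule == "power"), round(0.05 * n))
  expect_equal(sum(out$injected$rule == "rt"), round(0.1 * n))
  expect_false(any(duplicated(out$injected$row)))

  # injected power trials stand out by more than 3 SD of the clean trials
  t0 <- out$dataset$t0; fs <- out$dataset$rate
  pow <- vapply(out$dataset$trials$data, function(x) {
    t <- seq(t0, by = 1 / fs, length.out = ncol(x))
    mean(x[, t >= 1 & t <= 2.5]^2)
  }, numeric(1))
  pow_rows <- out$injected$row[out$injected$rule == "power"]
  clean <- setdiff(seq_len(n), pow_rows)
  expect_true(all(pow[pow_rows] > mean(pow[clean]) + 3 * sd(pow[clean])))

  expect_error(inject_artifacts(ds, list(gaze = 0.6, power = 0.6)), "sum")
})
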