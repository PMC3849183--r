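test_that("downsampling scales sample counts and preserves the passband", {
  rate <- 1200
  n <- 1200
  t <- seq(-1, by = 1 / rate, length.out = n)
  x10 <- matrix(rep(sin(2 * pi * 10 * t), each = 2), nrow = 2)
  ds <- manual_dataset(list(x10), rate = rate,
                       pre = (n - 1) / rate - 2)
  out <- downsample(ds, 300)
  expect_equal(out$rate, 300)
  expect_equal(ncol(out$trials$data[[1]]), 300)
  # compare against the analytically sampled sinusoid away from the edges
  t2 <- seq(-1, by = 1 / 300, length.out = 300)
  ref <- sin(2 * pi * 10 * t2)
  mid <- 40:260
  expect_lt(max(abs(out$trials$data[[1]][1, mid] - ref[mid])), 0.01)
  expect_error(downsample(manual_dataset(list(x10), rate = 1000), 300),
               "integer")
})

test_that("out-of-band components are attenuated by at least 40 dB", {
  rate <- 1200
  n <- 2400
  t <- seq(-1, by = 1 / rate, length.out = n)
  x140 <- matrix(sin(2 * pi * 140 * t), nrow = 1)
  ds <- manual_dataset(list(x140), rate = rate, pre = (n - 1) / rate - 2,
                       gaze = list(matrix(0, n, 2)))
  out <- downsample(ds, 300)
  y <- out$trials$data[[1]][1, ]
  mid <- seq(round(length(y) * 0.2), round(length(y) * 0.8))
  atten_db <- 20 * log10(sqrt(mean(y[mid]^2)) / sqrt(0.5))
  expect_lt(atten_db, -40)
})

test_that("segment filtering applies an inclusive 2 s pre-target minimum and demeans", {
  mk <- function(pre) matrix(rnorm(2 * (round((pre + 2) * 300) + 1)), nrow = 2)
  pres <- c(1.9, 2.0, 2.6)
  ds <- manual_dataset(lapply(pres, mk), pre = pres)
  out <- segment_demean_filter(ds)
  expect_equal(nrow(out$dataset$trials), 2)
  expect_equal(out$dataset$trials$pre_target_period, c(2.0, 2.6))
  expect_equal(out$report$n_removed, 1)
  for (d in out$dataset$trials$data) {
    expect_lt(max(abs(rowMeans(d))), 1e-12)
  }
  # constant signal becomes identically zero
  dsc <- manual_dataset(list(matrix(3, 2, 901)), pre = 2)
  outc <- segment_demean_filter(dsc)
  expect_true(all(outc$dataset$trials$data[[1]] == 0))
})

test_that("reaction-time rejection uses strict bounds", {
  mk <- function() matrix(0, 2, 901)
  ds <- manual_dataset(list(mk(), mk(), mk(), mk(), mk()),
                       rt = c(0.25, 0.5, 2.5, 0.3, 2.0), pre = rep(2, 5))
  out <- reject_rt(ds)
  # 0.25 and 2.5 rejected; boundary values 0.3 and 2.0 kept
  expect_equal(out$dataset$trials$rt, c(0.5, 0.3, 2.0))
  expect_equal(out$report$n_removed, 2)
})

test_that("gaze rejection detects sustained excursions after drift correction", {
  rate <- 300
  n <- round(3.5 * rate) + 1  # pre = 2.5
  t <- seq(-1, by = 1 / rate, length.out = n)
  base <- function() matrix(0, n, 2)
  # 0.06 s excursion at 2.5 deg inside the window -> rejected
  g1 <- base(); g1[t >= 1.5 & t <= 1.56, 1] <- 2.5
  # 0.04 s excursion at 3 deg -> kept (too short)
  g2 <- base(); g2[t >= 1.5 & t <= 1.54, 1] <- 3
  # constant 2.5 deg offset present throughout, incl. pre-cue -> kept
  g3 <- base(); g3[, 1] <- 2.5
  # excursion outside the 1-2.5 s window -> kept
  g4 <- base(); g4[t >= 0.2 & t <= 0.4, 1] <- 3
  mk <- function() matrix(0, 2, n)
  ds <- manual_dataset(list(mk(), mk(), mk(), mk()),
                       gaze = list(g1, g2, g3, g4), pre = rep(2.5, 4))
  out <- reject_gaze(ds)
  expect_equal(out$dataset$trials$trial, c(2L, 3L, 4L))
  expect_equal(out$report$n_removed[out$report$rule == "gaze"], 1)
  # missing gaze trace: excluded under a distinct reason
  dsm <- manual_dataset(list(mk(), mk()), gaze = list(NULL, base()),
                        pre = rep(2.5, 2))
  outm <- reject_gaze(dsm)
  expect_equal(outm$dataset$trials$trial, 2L)
  expect_equal(outm$report$n_removed[outm$report$rule == "gaze_missing"], 1)
})

test_that("power-outlier rejection removes the planted outlier and only it", {
  withr::with_seed(4, {
    data <- lapply(1:50, function(i) matrix(rnorm(2 * 1201), nrow = 2))
  })
  data[[17]] <- data[[17]] * 10
  ds <- manual_dataset(data, pre = rep(2, 50))
  # confirm the fixture: trial 17's z-score exceeds 3 (window 1-2.5 s)
  pow <- vapply(data, function(x) mean(x[, 601:1051]^2), numeric(1))
  expect_gt((pow[17] - mean(pow)) / sd(pow), 3)
  out <- reject_power_outliers(ds)
  expect_false(17 %in% out$dataset$trials$trial)
  expect_equal(out$report$n_removed, 1)
  # identical trials: zero variance, nothing removed
  same <- manual_dataset(lapply(1:5, function(i) matrix(1, 2, 901)),
                         pre = rep(2, 5))
  expect_equal(nrow(reject_power_outliers(same)$dataset$trials), 5)
  expect_error(reject_power_outliers(
    manual_dataset(list(matrix(1, 2, 901)), pre = 2)), "3 trials")
})

test_that("the cascade conserves trial counts per subject", {
  ds <- tiny_dataset()
  out <- inject_artifacts(ds, list(gaze = 0.05, power = 0.03, rt = 0.05),
                          seed = 31)
  pp <- preprocess(out$dataset)
  rep_tot <- dplyr::summarise(dplyr::group_by(pp$report, subject),
                              removed = sum(n_removed))
  surv <- dplyr::count(pp$dataset$trials, subject)
  input <- dplyr::count(ds$trials, subject)
  merged <- dplyr::left_join(input, rep_tot, by = "subject")
  merged <- dplyr::left_join(merged, surv, by = "subject",
                             suffix = c("_in", "_out"))
  expect_equal(merged$n_in, merged$removed + merged$n_out)
})

test_that("rejection rules recover all and only the injected artifacts", {
  cfg <- generator_preset("null", n_subjects = 1,
                          n_trials_per_condition = 26, n_sensors = 6,
                          long_rate = 0, seed = 77)
  ds <- generate_dataset(cfg)
  # keep only trials long enough that every rule window fits
  ds <- segment_demean_filter(ds, 2.0)$dataset
  ds$trials$trial <- seq_len(nrow(ds$trials))
  out <- inject_artifacts(ds, list(rt = 0.1), seed = 5)
  res <- reject_rt(out$dataset)
  expect_setequal(setdiff(seq_len(nrow(ds$trials)), res$dataset$trials$trial),
                  out$injected$row)
})

test_that("planar gradient maps constant fields to zero and ramps to their slope", {
  sa <- make_sensor_array(30, "grid")
  n <- 50
  const <- matrix(5, nrow(sa), n)
  ds <- manual_dataset(list(const), sensors = sa, pre = (n - 1) / 300 - 2,
                       rt = 0.5)
  ps <- to_planar_gradient(ds)
  expect_lt(max(abs(ps$x$trials$data[[1]])), 1e-10)
  expect_lt(max(abs(ps$y$trials$data[[1]])), 1e-10)
  # linear ramp along x: x-gradient equals the slope, y-gradient zero
  ramp <- matrix(rep(2 * sa$x, n), ncol = n)
  ds2 <- manual_dataset(list(ramp), sensors = sa, pre = (n - 1) / 300 - 2)
  ps2 <- to_planar_gradient(ds2)
  expect_lt(max(abs(ps2$x$trials$data[[1]] - 2)), 1e-8)
  expect_lt(max(abs(ps2$y$trials$data[[1]])), 1e-8)
})

test_that("planar gradient is linear and peaks at a localized bump", {
  sa <- make_sensor_array(30, "grid")
  n <- 20
  withr::with_seed(9, {
    x1 <- matrix(rnorm(nrow(sa) * n), nrow(sa))
    x2 <- matrix(rnorm(nrow(sa) * n), nrow(sa))
  })
  tp <- function(x) {
    ps <- to_planar_gradient(manual_dataset(list(x), sensors = sa,
                                            pre = (n - 1) / 300 - 2))
    list(x = ps$x$trials$data[[1]], y = ps$y$trials$data[[1]])
  }
  a <- 2.5; b <- -1.25
  combo <- tp(a * x1 + b * x2)
  g1 <- tp(x1); g2 <- tp(x2)
  expect_equal(combo$x, a * g1$x + b * g2$x, tolerance = 1e-10)
  expect_equal(combo$y, a * g1$y + b * g2$y, tolerance = 1e-10)

  # single-sensor bump: gradient magnitude maximal at or adjacent to it
  bump_at <- 10
  bump <- matrix(0, nrow(sa), n); bump[bump_at, ] <- 1
  g <- tp(bump)
  mag <- sqrt(g$x[, 1]^2 + g$y[, 1]^2)
  nb <- c(bump_at, which(sensor_adjacency(sa)[bump_at, ]))
  expect_true(which.max(mag) %in% nb)
})
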