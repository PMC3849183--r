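test_that("the modulation index obeys its algebra", {
  expect_equal(alpha_modulation(3, 1), 0.5)
  expect_equal(alpha_modulation(2.7, 2.7), 0)
  expect_equal(alpha_modulation(c(1, 4), c(3, 4)), c(-0.5, 0))
  expect_error(alpha_modulation(0, 0), "undefined")
  expect_error(alpha_modulation(-1, 2), "nonnegative")
  withr::with_seed(3, {
    a <- runif(200, 0, 10); b <- runif(200, 0, 10)
  })
  am <- alpha_modulation(a, b)
  expect_true(all(am >= -1 & am <= 1))
  expect_equal(am, -alpha_modulation(b, a))
})

test_that("the lateralization index is the ROI difference and flips under swap", {
  am <- c(rep(0.06, 4), rep(-0.06, 4), 0.5)
  rois <- list(left = 1:4, right = 5:8)
  expect_equal(alpha_lateralization(am, rois), 0.12)
  expect_equal(alpha_lateralization(rep(0, 9), rois), 0)
  swapped <- list(left = rois$right, right = rois$left)
  expect_equal(alpha_lateralization(am, swapped),
               -alpha_lateralization(am, rois))
  expect_error(alpha_lateralization(am, list(left = integer(0), right = 5:8)),
               "nonempty")
  m <- rbind(am, 2 * am)
  expect_equal(unname(alpha_lateralization(m, rois)), c(0.12, 0.24))
})

test_that("the 2x2 within-subject ANOVA matches aov and the t^2 identity", {
  withr::with_seed(8, {
    df <- tidyr::expand_grid(subject = 1:10,
                             difficulty = c("easy", "difficult"),
                             eccentricity = c("near", "far"))
    df$al <- rnorm(nrow(df), 0.1, 0.05) +
      rep(rnorm(10, 0, 0.03), each = 4) +
      ifelse(df$difficulty == "difficult", 0.04, 0)
  })
  fit <- rm_anova_2x2(df, "al")
  td <- tidy(fit)
  # independent sums-of-squares oracle: base aov with Error strata
  ref <- summary(aov(
    al ~ difficulty * eccentricity +
      Error(factor(subject) / (difficulty * eccentricity)),
    data = df
  ))
  get_f <- function(stratum, term) {
    tab <- ref[[stratum]][[1]]
    tab[grep(term, trimws(rownames(tab)), fixed = TRUE), "F value"]
  }
  expect_equal(td$statistic[td$term == "difficulty"],
               get_f("Error: factor(subject):difficulty", "difficulty"),
               tolerance = 1e-9)
  expect_equal(td$statistic[td$term == "eccentricity"],
               get_f("Error: factor(subject):eccentricity", "eccentricity"),
               tolerance = 1e-9)
  expect_equal(td$statistic[td$term == "difficulty:eccentricity"],
               get_f("Error: factor(subject):difficulty:eccentricity",
                     "difficulty:eccentricity"),
               tolerance = 1e-9)
  expect_true(all(td$df1 == 1) && all(td$df2 == 9))

  # F(main effect) equals the squared paired t on the marginal means
  wide <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(df, subject, difficulty),
                     al = mean(al), .groups = "drop"),
    names_from = difficulty, values_from = al
  )
  tt <- t.test(wide$difficult, wide$easy, paired = TRUE)
  expect_equal(td$statistic[td$term == "difficulty"],
               unname(tt$statistic)^2, tolerance = 1e-9)

  # all-equal cells: every F is zero
  df0 <- df; df0$al <- 1
  expect_true(all(tidy(rm_anova_2x2(df0, "al"))$statistic == 0))
})

test_that("the signed-rank test matches exact enumeration", {
  # DP oracle: distribution of the positive-rank sum for n untied ranks
  exact_p_all_positive <- function(n) {
    # all differences positive: V = n(n+1)/2, the extreme point
    2 / 2^n
  }
  d <- 1:14  # 14 positive, untied differences
  res <- wilcoxon_signed_rank(d)
  expect_equal(res$method, "exact")
  expect_equal(res$p.value, exact_p_all_positive(14), tolerance = 1e-12)

  # mixed fixture against full enumeration over sign assignments
  d2 <- c(3.2, -1.1, 2.5, 0.7, -4.4, 1.9, 2.2, -0.3, 5.1, 1.4)
  res2 <- wilcoxon_signed_rank(d2)
  r <- rank(abs(d2))
  v_obs <- sum(r[d2 > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 10)))
  v_all <- signs %*% r
  p_oracle <- mean(abs(v_all - sum(r) / 2) >= abs(v_obs - sum(r) / 2))
  expect_equal(res2$p.value, p_oracle, tolerance = 1e-12)

  # symmetric differences: two-sided p near 1
  expect_gt(wilcoxon_signed_rank(c(-3, -2, -1, 1, 2, 3.0001))$p.value, 0.9)
  expect_error(wilcoxon_signed_rank(rep(0, 5)), "zero")
})

test_that("the binomial interval equals the beta-quantile construction", {
  expect_equal(binomial_ci(10, 10)$upper, 1)
  expect_equal(binomial_ci(0, 10)$lower, 0)
  ci <- binomial_ci(75, 100)
  ref <- binom.test(75, 100)$conf.int  # independent implementation
  expect_equal(ci$lower, ref[1], tolerance = 1e-9)
  expect_equal(ci$upper, ref[2], tolerance = 1e-9)
  expect_error(binomial_ci(3, 0), "positive")
})

test_that("the correlation wrapper matches the covariance formula", {
  x <- c(1, 3, 4, 7, 9, 10.5, 12)
  y <- 2 * x + 1
  expect_equal(pearson_r(x, y)$estimate, 1, tolerance = 1e-12)
  withr::with_seed(5, { x <- rnorm(40); y <- 0.3 * x + rnorm(40) })
  res <- pearson_r(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$estimate, r_direct, tolerance = 1e-12)
  expect_equal(res$df, 38)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "variance")
})

test_that("accuracy-over-RT-quartile trend behaves at its anchors", {
  # equal accuracy in every bin -> zero F and zero trend
  df <- tidyr::expand_grid(subject = 1:6, i = 1:40)
  df$rt <- df$i / 40
  df$correct <- (df$i - 1) %% 10 < 8  # same accuracy in every RT quartile
  fit <- accuracy_rt_trend(df)
  td <- tidy(fit)
  expect_equal(td$statistic, c(0, 0), tolerance = 1e-12)
  # bins contain 25% of trials each
  expect_true(all(fit$bins$n == 10))

  # strictly increasing accuracy over bins -> significant positive trend
  df2 <- tidyr::expand_grid(subject = 1:6, i = 1:40)
  df2$rt <- df2$i / 40
  bin <- ceiling(df2$i / 10)
  n_correct <- ifelse(df2$subject %% 2 == 1, c(4, 6, 7, 9), c(5, 6, 8, 9))[bin]
  df2$correct <- (df2$i - 1) %% 10 < n_correct
  fit2 <- accuracy_rt_trend(df2)
  td2 <- tidy(fit2)
  expect_lt(td2$p.value[td2$term == "linear_trend"], 0.001)
  expect_error(accuracy_rt_trend(df[df$i <= 3, ]), "at least")
})
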