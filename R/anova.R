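#' Two-way repeated-measures ANOVA for a 2 x 2 within-subject design
#'
#' Computes the two main effects and the interaction from per-subject
#' contrast scores: for each effect the contrast of the four cell means
#' is formed per subject and tested against zero, giving
#' `F = t^2` with `(1, N - 1)` degrees of freedom — the exact
#' within-subject decomposition for a balanced 2 x 2 design.
#'
#' @param data A data frame with one row per subject x cell.
#' @param value Name of the response column.
#' @param subject Name of the subject identifier column.
#' @param factors Names of the two two-level within-subject factor
#'   columns.
#' @return An `rm_anova` object; `tidy()` returns a tibble with columns
#'   `term`, `df1`, `df2`, `statistic` and `p.value`.
#' @examples
#' df <- tidyr::expand_grid(subject = 1:8, difficulty = c("easy", "difficult"),
#'                          eccentricity = c("near", "far"))
#' df$al <- rnorm(nrow(df), ifelse(df$difficulty == "difficult", 0.12, 0.08), 0.03)
#' tidy(rm_anova_2x2(df, "al"))
#' @export
rm_anova_2x2 <- function(data, value = "al", subject = "subject",
                         factors = c("difficulty", "eccentricity")) {
  f1 <- factor(data[[factors[1L]]])
  f2 <- factor(data[[factors[2L]]])
  if (nlevels(f1) != 2L || nlevels(f2) != 2L) {
    abort("both factors must have exactly two levels.")
  }
  subj <- data[[subject]]
  n <- length(unique(subj))
  if (n < 3L) abort("need at least 3 subjects.")
  cell <- interaction(f1, f2)
  if (any(table(subj, cell) != 1L)) {
    abort("design must be complete and balanced (one value per subject x cell).")
  }
  # per-subject cell matrix, columns in a fixed level order
  wide <- tapply(data[[value]], list(subj, cell), mean)
  l1 <- as.integer(f1[match(colnames(wide), as.character(cell))])  # 1/2
  l2 <- as.integer(f2[match(colnames(wide), as.character(cell))])
  s1 <- ifelse(l1 == 1L, 1, -1)
  s2 <- ifelse(l2 == 1L, 1, -1)
  contrasts <- list(s1, s2, s1 * s2)
  terms <- c(factors[1L], factors[2L],
             paste(factors[1L], factors[2L], sep = ":"))
  rows <- purrr::map2(terms, contrasts, function(tm, cw) {
    score <- as.numeric(wide %*% (cw / 2))  # contrast of cell means
    tstat <- mean(score) / (sd(score) / sqrt(n))
    if (!is.finite(tstat)) tstat <- 0
    tibble::tibble(term = tm, df1 = 1L, df2 = n - 1L,
                   statistic = tstat^2,
                   p.value = pf(tstat^2, 1, n - 1L, lower.tail = FALSE),
                   contrast_mean = mean(score))
  })
  structure(
    list(table = dplyr::bind_rows(rows), n_subjects = n,
         cell_means = colMeans(wide)),
    class = "rm_anova"
  )
}

#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) {
  dplyr::select(x$table, "term", "df1", "df2", "statistic", "p.value")
}

#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_terms = nrow(x$table))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova: %d subjects>\n", x$n_subjects))
  print(tidy(x))
  invisible(x)
}

# one-way repeated-measures ANOVA on an N x k matrix, plus linear trend
rm_anova_oneway <- function(y) {
  n <- nrow(y)
  k <- ncol(y)
  g <- mean(y)
  mj <- colMeans(y)
  mi <- rowMeans(y)
  ss_cond <- n * sum((mj - g)^2)
  resid <- y - outer(mi, rep(1, k)) - outer(rep(1, n), mj) + g
  ss_err <- sum(resid^2)
  df1 <- k - 1L
  df2 <- (n - 1L) * (k - 1L)
  fstat <- if (ss_err == 0) 0 else (ss_cond / df1) / (ss_err / df2)
  w <- seq_len(k) - (k + 1) / 2
  score <- as.numeric(y %*% w)
  t_tr <- if (sd(score) == 0) 0 else mean(score) / (sd(score) / sqrt(n))
  if (!is.finite(t_tr)) t_tr <- 0
  p_int <- pf(fstat, df1, df2, lower.tail = FALSE)
  p_tr <- pf(t_tr^2, 1, n - 1L, lower.tail = FALSE)
  tibble::tibble(
    term = c("interval", "linear_trend"),
    df1 = c(df1, 1L), df2 = c(df2, n - 1L),
    statistic = c(fstat, t_tr^2),
    p.value = c(p_int, p_tr)
  )
}

#' Accuracy trend over reaction-time quartiles
#'
#' Bins each subject's trials into `n_bins` reaction-time intervals of
#' (as close as possible to) equal trial counts, computes the accuracy
#' per bin, and tests the bin effect with a one-way within-subject ANOVA
#' with factor Interval plus a linear-trend contrast.
#'
#' @param data A data frame with columns `subject`, `rt` and `correct`.
#' @param n_bins Number of RT bins per subject.
#' @return An `rt_trend` object: `tidy()` gives the ANOVA and trend rows;
#'   `$bins` holds the per-subject bin accuracies.
#' @export
accuracy_rt_trend <- function(data, n_bins = 4) {
  counts <- table(data$subject)
  if (any(counts < n_bins)) {
    abort("every subject needs at least `n_bins` trials.")
  }
  binned <- dplyr::mutate(
    dplyr::group_by(data, .data$subject),
    bin = dplyr::ntile(.data$rt, n_bins)
  )
  acc <- dplyr::summarise(
    dplyr::group_by(binned, .data$subject, .data$bin),
    accuracy = mean(.data$correct), n = dplyr::n(), .groups = "drop"
  )
  wide <- tapply(acc$accuracy, list(acc$subject, acc$bin), mean)
  structure(
    list(table = rm_anova_oneway(wide), bins = acc,
         n_subjects = nrow(wide), n_bins = n_bins),
    class = "rt_trend"
  )
}

#' @method tidy rt_trend
#' @export
tidy.rt_trend <- function(x, ...) x$table

#' @export
print.rt_trend <- function(x, ...) {
  cat(sprintf("<rt_trend: %d subjects, %d RT bins>\n", x$n_subjects, x$n_bins))
  print(x$table)
  invisible(x)
}

#' Wilcoxon signed-rank test on paired values
#'
#' Two-sided signed-rank test of `x - y` (or of `x` alone) against a zero
#' median: exact distribution for up to 25 non-zero untied differences,
#' normal approximation with continuity correction otherwise; zero
#' differences are dropped and ties receive mid-ranks.
#'
#' @param x Numeric vector (differences, or first member of the pairs).
#' @param y Optional paired second member.
#' @return A tibble with `statistic` (V), `p.value`, `n` (non-zero
#'   pairs) and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  if (!length(d)) abort("all differences are zero; the test is undefined.")
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  res <- suppressWarnings(
    wilcox.test(d, exact = exact, correct = TRUE)
  )
  tibble::tibble(statistic = unname(res$statistic), p.value = res$p.value,
                 n = length(d),
                 method = if (exact) "exact" else "normal approximation")
}

#' Clopper-Pearson binomial confidence interval
#'
#' Two-sided equal-tailed interval for a binomial proportion from the
#' beta quantile function.
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param level Confidence level.
#' @return A tibble with `estimate`, `lower` and `upper`.
#' @export
binomial_ci <- function(k, n, level = 0.95) {
  if (any(n <= 0)) abort("`n` must be positive.")
  if (any(k < 0 | k > n)) abort("`k` must lie in [0, n].")
  a <- (1 - level) / 2
  tibble::tibble(
    estimate = k / n,
    lower = ifelse(k == 0, 0, qbeta(a, k, n - k + 1)),
    upper = ifelse(k == n, 1, qbeta(1 - a, k + 1, n - k))
  )
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero
#'   variance.
#' @return A tibble with `estimate`, `statistic`, `df` and `p.value`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("`x` and `y` must have equal length >= 3.")
  }
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance input.")
  res <- cor.test(x, y, method = "pearson")
  tibble::tibble(estimate = unname(res$estimate),
                 statistic = unname(res$statistic),
                 df = unname(res$parameter), p.value = res$p.value)
}
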