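#' Within-subject cluster-based sign-flip permutation test
#'
#' One-sample test of subject-level maps against zero with cluster-based
#' correction: a t statistic is computed per element (sensor or time
#' step); elements whose |t| exceeds the two-sided cluster-forming
#' threshold (t quantile at `cluster_alpha`, N-1 df) are grouped into
#' connected clusters separately for positive and negative signs; each
#' cluster's mass is the sum of its member t values. The null
#' distribution is built by randomly flipping the sign of each subject's
#' whole map and recording the maximum absolute cluster mass per
#' permutation; each observed cluster's p-value is the fraction of null
#' maxima at or above its absolute mass. When `2^N <= 4096` all sign
#' patterns are enumerated exactly; otherwise `n_perm` random flips
#' including the identity are drawn, so p-values are bounded below by
#' `1/n_perm`. Elements with zero variance across subjects get t = 0 and
#' never enter a cluster.
#'
#' @param values Numeric matrix, subjects x elements.
#' @param adjacency Logical adjacency matrix over elements (symmetric,
#'   irreflexive), or a list of neighbour index vectors.
#' @param cluster_alpha Two-sided cluster-forming alpha.
#' @param n_perm Number of randomizations (used when exhaustive
#'   enumeration is infeasible).
#' @param seed Optional seed for the random flips.
#' @return A `cluster_result`: list with `clusters` (tibble: `cluster`,
#'   `sign`, `n_members`, `mass`, `p.value`, and list-column `members`),
#'   `t` (element statistics), `threshold`, `n_perm_used` and
#'   `exhaustive`.
#' @export
cluster_permutation_test <- function(values, adjacency, cluster_alpha = 0.05,
                                     n_perm = 1000, seed = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 2L) abort("need at least 2 subjects.")
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  adjl <- if (is.list(adjacency)) adjacency else
    apply(adjacency, 1L, which, simplify = FALSE)
  if (length(adjl) != ncol(values)) {
    abort("adjacency must cover all elements.")
  }
  thr <- qt(1 - cluster_alpha / 2, df = n - 1L)

  t_obs <- t_onesample(colMeans(values), colSums(values^2), n)
  obs <- find_clusters(t_obs, thr, adjl)

  exhaustive <- 2^n <= 4096
  flips <- if (exhaustive) {
    as.matrix(do.call(expand.grid, rep(list(c(1, -1)), n)))
  } else {
    draw <- function() {
      rbind(rep(1, n),
            matrix(sample(c(-1, 1), (n_perm - 1L) * n, replace = TRUE),
                   ncol = n))
    }
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  ss <- colSums(values^2)
  means <- (flips %*% values) / n
  null_max <- vapply(seq_len(nrow(flips)), function(r) {
    tv <- t_onesample(means[r, ], ss, n)
    cl <- find_clusters(tv, thr, adjl)
    if (length(cl$mass)) max(abs(cl$mass)) else 0
  }, numeric(1))

  p <- vapply(obs$mass, function(m) mean(null_max >= abs(m)), numeric(1))
  ord <- order(p, -abs(obs$mass))
  clusters <- tibble::tibble(
    cluster = seq_along(ord),
    sign = ifelse(obs$mass[ord] > 0, "positive", "negative"),
    n_members = lengths(obs$members)[ord],
    mass = obs$mass[ord],
    p.value = p[ord],
    members = obs$members[ord]
  )
  structure(
    list(clusters = clusters, t = t_obs, threshold = thr,
         n_perm_used = nrow(flips), exhaustive = exhaustive),
    class = "cluster_result"
  )
}

# one-sample t from first/second moments; zero-variance elements -> t = 0
t_onesample <- function(m, ss, n) {
  v <- pmax(ss - n * m^2, 0) / (n - 1L)
  t <- m / sqrt(v / n)
  t[!is.finite(t)] <- 0
  t
}

# connected suprathreshold clusters, positive and negative separately
find_clusters <- function(tv, thr, adjl) {
  members <- list()
  mass <- numeric(0)
  for (sgn in c(1, -1)) {
    idx <- which(sgn * tv > thr)
    if (!length(idx)) next
    if (length(idx) == 1L) {
      members[[length(members) + 1L]] <- idx
      mass <- c(mass, tv[idx])
      next
    }
    in_set <- logical(length(adjl))
    in_set[idx] <- TRUE
    seen <- logical(length(adjl))
    for (s0 in idx) {
      if (seen[s0]) next
      comp <- integer(0)
      stack <- s0
      seen[s0] <- TRUE
      while (length(stack)) {
        v <- stack[[length(stack)]]
        stack <- stack[-length(stack)]
        comp <- c(comp, v)
        nb <- adjl[[v]]
        nb <- nb[in_set[nb] & !seen[nb]]
        seen[nb] <- TRUE
        stack <- c(stack, nb)
      }
      members[[length(members) + 1L]] <- sort(comp)
      mass <- c(mass, sum(tv[comp]))
    }
  }
  list(members = members, mass = mass)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: %d cluster(s), threshold |t| > %.3f, %d permutations%s>\n",
              nrow(x$clusters), x$threshold, x$n_perm_used,
              if (x$exhaustive) " (exhaustive)" else ""))
  if (nrow(x$clusters)) print(dplyr::select(x$clusters, -"members"))
  invisible(x)
}

#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  dplyr::select(x$clusters, -"members")
}

#' Temporal cluster permutation test
#'
#' Paired comparison of two subject x time series (or of one series
#' against zero) with the same sign-flip cluster machinery as
#' [cluster_permutation_test()], using contiguity of consecutive time
#' steps as adjacency. When `time` and `window` are supplied the test is
#' restricted to the steps whose centres fall inside the closed window.
#'
#' @param series_a Numeric matrix, subjects x time steps.
#' @param series_b Matching matrix, or `NULL` to test `series_a` against
#'   zero.
#' @param time Optional vector of step times, s.
#' @param window Optional closed analysis window, s.
#' @param ... Passed to [cluster_permutation_test()].
#' @return A `cluster_result`; clusters' `members` index into the
#'   restricted time axis stored in the `time` field.
#' @export
timecourse_cluster_test <- function(series_a, series_b = NULL, time = NULL,
                                    window = NULL, ...) {
  series_a <- as.matrix(series_a)
  d <- if (is.null(series_b)) series_a else {
    series_b <- as.matrix(series_b)
    if (!identical(dim(series_a), dim(series_b))) {
      abort("the two series must have identical dimensions.")
    }
    series_a - series_b
  }
  keep <- seq_len(ncol(d))
  if (!is.null(window)) {
    if (is.null(time)) abort("`window` requires `time`.")
    keep <- which(time >= window[1L] - 1e-9 & time <= window[2L] + 1e-9)
    d <- d[, keep, drop = FALSE]
  }
  k <- ncol(d)
  adjl <- lapply(seq_len(k), function(i) {
    c(if (i > 1L) i - 1L, if (i < k) i + 1L)
  })
  out <- cluster_permutation_test(d, adjl, ...)
  out$time <- if (is.null(time)) keep else time[keep]
  out
}

#' Define hemispheric regions of interest from modulation maps
#'
#' Runs the within-subject cluster permutation test on the
#' condition-averaged per-sensor modulation maps and collects the sensors
#' of every significant cluster (`p < roi_alpha`), partitioned by
#' hemisphere; midline sensors are excluded from the ROIs.
#'
#' @param maps Numeric matrix, subjects x sensors, of condition-averaged
#'   alpha modulation.
#' @param sensors The [make_sensor_array()] layout (supplies the
#'   adjacency and hemisphere tags).
#' @param roi_alpha Significance level for including a cluster.
#' @param ... Passed to [cluster_permutation_test()] (`cluster_alpha`,
#'   `n_perm`, `seed`).
#' @return A `roi_pair`: list with integer sensor indices `left` and
#'   `right` (either may be empty if no cluster reaches significance;
#'   downstream lateralization refuses empty ROIs) and the full
#'   `cluster_result` in `clusters`.
#' @export
define_rois <- function(maps, sensors, roi_alpha = 0.05, ...) {
  res <- cluster_permutation_test(maps, sensor_adjacency(sensors), ...)
  sig <- res$clusters[res$clusters$p.value < roi_alpha, , drop = FALSE]
  sel <- sort(unique(unlist(sig$members)))
  structure(
    list(
      left = sel[sensors$hemisphere[sel] == "left"],
      right = sel[sensors$hemisphere[sel] == "right"],
      clusters = res
    ),
    class = "roi_pair"
  )
}

#' @export
print.roi_pair <- function(x, ...) {
  cat(sprintf("<roi_pair: %d left / %d right sensors>\n",
              length(x$left), length(x$right)))
  invisible(x)
}
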