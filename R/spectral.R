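#' Sliding-window Hanning-taper alpha power
#'
#' Estimates band power per trial, sensor and time step by sliding a
#' Hanning-tapered window (default 0.5 s advanced in 0.05 s steps) over
#' each segment, evaluating the discrete Fourier transform at the band's
#' bin centres (default 8, 10, 12, 14 Hz: a 0.5 s window has exactly
#' 2 Hz native resolution, so these are native bins) and averaging the
#' bin powers with equal weights. Power at each bin is normalized by the
#' squared sum of the taper, so a unit-amplitude tone at a bin centre
#' has power 1/2 at that bin regardless of the window length. Time stamps are window centres,
#' aligned to the step grid anchored at cue onset; by default the time
#' axis spans the centres valid for every trial in the dataset.
#'
#' @param dataset An `attn_dataset` (or one component of a `planar_set`).
#' @param window Window length, s.
#' @param step Step between window centres, s.
#' @param band Frequency band, Hz.
#' @param bin_width Spacing of bin centres within the band, Hz.
#' @param tmin,tmax Optional restriction of the window-centre axis, s
#'   relative to cue onset.
#' @return An `alpha_power` object: list with `power` (array
#'   trials x sensors x time steps, nonnegative), `time` (window centres,
#'   s), `freqs`, `band`, `window`, `step`, `trials` (metadata tibble
#'   without the signal columns), `sensors` and `rate`.
#' @export
sliding_alpha_power <- function(dataset, window = 0.5, step = 0.05,
                                band = c(8, 14), bin_width = 2,
                                tmin = NULL, tmax = NULL) {
  fs <- dataset$rate
  t0 <- dataset$t0
  wl <- round(window * fs)
  if (abs(step * fs - round(step * fs)) > 1e-9) {
    abort("`step` must be an integer number of samples.")
  }
  seg_len <- vapply(dataset$trials$data, ncol, integer(1))
  if (any(seg_len < wl)) abort("window longer than the shortest segment.")
  # window centres on the step grid anchored at t = 0, valid for all trials
  lo <- t0 + window / 2
  hi <- t0 + (min(seg_len) - 1) / fs - window / 2
  lo <- max(lo, tmin %||% lo)
  hi <- min(hi, tmax %||% hi)
  centers <- seq(ceiling(lo / step - 1e-9), floor(hi / step + 1e-9)) * step
  if (!length(centers)) abort("no valid window centres in the requested range.")

  taper <- hanning_taper(wl)
  freqs <- seq(band[1L], band[2L], by = bin_width)
  tt <- (seq_len(wl) - 1L) / fs
  b_re <- vapply(freqs, function(f) cos(2 * pi * f * tt) * taper, numeric(wl))
  b_im <- vapply(freqs, function(f) -sin(2 * pi * f * tt) * taper, numeric(wl))
  scale <- 2 / sum(taper)^2

  starts <- round((centers - window / 2 - t0) * fs) + 1L
  n_tr <- nrow(dataset$trials)
  S <- nrow(dataset$trials$data[[1L]])
  pow <- array(0, dim = c(n_tr, S, length(centers)))
  n_win <- length(starts)
  idx <- outer(0:(wl - 1L), starts, `+`)  # wl x n_win sample indices
  for (i in seq_len(n_tr)) {
    d <- dataset$trials$data[[i]]
    # all windows of all sensors as one (wl) x (S * n_win) matrix
    segs <- array(t(d[, idx, drop = FALSE]), c(wl, n_win, S))
    segs <- matrix(aperm(segs, c(1L, 3L, 2L)), nrow = wl)
    p <- (crossprod(segs, b_re))^2 + (crossprod(segs, b_im))^2
    pow[i, , ] <- matrix(rowMeans(p) * scale, nrow = S)
  }
  meta <- dataset$trials[setdiff(names(dataset$trials), c("data", "gaze"))]
  structure(
    list(power = pow, time = centers, freqs = freqs, band = band,
         window = window, step = step, trials = meta,
         sensors = dataset$sensors, rate = fs),
    class = "alpha_power"
  )
}

# symmetric Hanning taper
hanning_taper <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

#' @export
print.alpha_power <- function(x, ...) {
  cat(sprintf(
    "<alpha_power: %d trials x %d sensors x %d steps, %g-%g Hz, window %g s>\n",
    dim(x$power)[1L], dim(x$power)[2L], dim(x$power)[3L],
    x$band[1L], x$band[2L], x$window
  ))
  invisible(x)
}

#' Combine the two planar-gradient power components
#'
#' Elementwise sum of the power of the two orthogonal gradient
#' components, the standard combination convention. The sum is invariant
#' under rotations of the gradient axes.
#'
#' @param power_x,power_y `alpha_power` objects of matching shape.
#' @return An `alpha_power` with the summed power.
#' @export
combine_planar_power <- function(power_x, power_y) {
  if (!identical(dim(power_x$power), dim(power_y$power)) ||
      !isTRUE(all.equal(power_x$time, power_y$time))) {
    abort("planar components have mismatching shapes or time axes.")
  }
  power_x$power <- power_x$power + power_y$power
  power_x
}

#' @describeIn sliding_alpha_power Convenience wrapper: planar transform,
#'   power on both components, then [combine_planar_power()].
#' @param ... Passed on to `sliding_alpha_power()`.
#' @export
planar_alpha_power <- function(dataset, ...) {
  ps <- to_planar_gradient(dataset)
  combine_planar_power(sliding_alpha_power(ps$x, ...),
                       sliding_alpha_power(ps$y, ...))
}

#' Average alpha power over an analysis window
#'
#' Arithmetic mean of the timecourse over the steps whose window centres
#' fall in the closed interval `window` (default: the 1-2.5 s post-cue
#' attention epoch).
#'
#' @param tc An `alpha_power` timecourse.
#' @param window Closed time window, s relative to cue onset.
#' @return An `alpha_summary`: list with `power` (matrix trials x
#'   sensors), `trials`, `sensors` and `window`.
#' @export
window_average <- function(tc, window = c(1, 2.5)) {
  sel <- which(tc$time >= window[1L] - 1e-9 & tc$time <= window[2L] + 1e-9)
  if (!length(sel)) abort("no window centres inside the averaging window.")
  pow <- apply(tc$power[, , sel, drop = FALSE], c(1L, 2L), mean)
  structure(
    list(power = pow, trials = tc$trials, sensors = tc$sensors,
         window = window, n_steps = length(sel)),
    class = "alpha_summary"
  )
}

#' Hemisphere-ROI-averaged power timecourses
#'
#' Averages an alpha-power timecourse over the sensors of the left and
#' right region of interest, yielding one series per hemisphere per
#' trial.
#'
#' @param tc An `alpha_power`.
#' @param rois A `roi_pair` from [define_rois()].
#' @return A `roi_timecourse`: list with `power` (array trials x 2
#'   hemispheres x steps; order left, right), `time`, `trials`.
#' @export
roi_timecourses <- function(tc, rois) {
  if (!length(rois$left) || !length(rois$right)) {
    abort("both ROIs must be nonempty.")
  }
  left <- apply(tc$power[, rois$left, , drop = FALSE], c(1L, 3L), mean)
  right <- apply(tc$power[, rois$right, , drop = FALSE], c(1L, 3L), mean)
  pow <- array(0, dim = c(dim(left)[1L], 2L, dim(left)[2L]),
               dimnames = list(NULL, c("left", "right"), NULL))
  pow[, 1L, ] <- left
  pow[, 2L, ] <- right
  structure(list(power = pow, time = tc$time, trials = tc$trials),
            class = "roi_timecourse")
}

#' Baseline z-normalization of ROI timecourses
#'
#' For each subject, pools the power of both hemisphere series over all
#' trials and all baseline steps (default -0.75 s to -0.25 s before cue
#' onset) into a single mean and standard deviation, and applies that one
#' affine transform to every time point of the subject's series. After
#' the transform the pooled baseline has mean 0 and SD 1; the transform
#' is invariant to positive affine rescalings of the raw power.
#'
#' @param rtc A `roi_timecourse`.
#' @param baseline Baseline window, s relative to cue onset.
#' @return The standardized `roi_timecourse`, with a `scaling` tibble
#'   (subject, mean, sd) attached.
#' @export
baseline_zscore <- function(rtc, baseline = c(-0.75, -0.25)) {
  bidx <- which(rtc$time >= baseline[1L] - 1e-9 & rtc$time <= baseline[2L] + 1e-9)
  if (!length(bidx)) abort("baseline window outside the time axis.")
  scalings <- list()
  for (s in unique(rtc$trials$subject)) {
    rows <- which(rtc$trials$subject == s)
    if (length(rows) < 2L) abort("baseline normalization needs >= 2 trials per subject.")
    vals <- rtc$power[rows, , bidx, drop = FALSE]
    m <- mean(vals)
    sdev <- sd(as.numeric(vals))
    if (!is.finite(sdev) || sdev == 0) abort("zero baseline variance for subject ", s)
    rtc$power[rows, , ] <- (rtc$power[rows, , , drop = FALSE] - m) / sdev
    scalings[[length(scalings) + 1L]] <-
      tibble::tibble(subject = s, mean = m, sd = sdev)
  }
  rtc$scaling <- dplyr::bind_rows(scalings)
  rtc
}
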