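#' Down-sample a dataset with anti-alias filtering
#'
#' Applies a zero-phase Blackman-windowed-sinc FIR low-pass (cutoff at
#' 0.85 of the target Nyquist frequency, transition band 0.1 of the
#' target Nyquist) to every channel and gaze trace, then decimates by the
#' integer rate ratio. Frequencies up to 0.8 of the target Nyquist are
#' preserved within 1%; out-of-band components are attenuated by well
#' over 40 dB.
#'
#' @param dataset An `attn_dataset`.
#' @param to_rate Target sampling rate, Hz; must divide `dataset$rate`.
#' @return The dataset resampled at `to_rate`.
#' @export
downsample <- function(dataset, to_rate) {
  from_rate <- dataset$rate
  if (from_rate %% to_rate != 0) {
    abort("`to_rate` must divide the current sampling rate (integer ratio).")
  }
  m <- from_rate %/% to_rate
  if (m == 1L) return(dataset)
  kern <- antialias_kernel(from_rate, to_rate)
  dataset$trials$data <- lapply(dataset$trials$data, function(x) {
    y <- t(apply(x, 1L, zero_phase_filter, kernel = kern))
    y[, seq(1L, ncol(x), by = m), drop = FALSE]
  })
  dataset$trials$gaze <- lapply(dataset$trials$gaze, function(g) {
    y <- apply(g, 2L, zero_phase_filter, kernel = kern)
    y[seq(1L, nrow(g), by = m), , drop = FALSE]
  })
  dataset$rate <- to_rate
  dataset
}

# symmetric odd-length low-pass FIR for decimation from_rate -> to_rate
antialias_kernel <- function(from_rate, to_rate) {
  nyq_t <- to_rate / 2
  fc <- 0.85 * nyq_t          # cutoff, Hz
  trans <- 0.1 * nyq_t        # transition width, Hz
  ntaps <- ceiling(5.5 * from_rate / trans)  # Blackman main-lobe rule
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  signal::fir1(ntaps - 1L, fc / (from_rate / 2), type = "low",
               window = signal::blackman(ntaps))
}

# zero-phase filtering: symmetric kernel + anti-symmetric edge reflection
zero_phase_filter <- function(x, kernel) {
  h <- (length(kernel) - 1L) %/% 2L
  n <- length(x)
  left <- 2 * x[1L] - x[pmin(seq(h + 1L, 2L), n)]
  right <- 2 * x[n] - x[pmax(seq(n - 1L, n - h), 1L)]
  xp <- c(left, x, right)
  # 'filter'-type convolution of length n + 2h with a (2h+1)-tap kernel -> n
  stats::convolve(xp, rev(kernel), type = "filter")
}

new_report <- function(dataset, rule, removed_rows) {
  input <- dplyr::count(dataset$trials, .data$subject, name = "n_input")
  rem <- dataset$trials[removed_rows, c("subject", "trial")]
  counts <- if (nrow(rem)) dplyr::count(rem, .data$subject, name = "n_removed") else
    tibble::tibble(subject = integer(0), n_removed = integer(0))
  out <- dplyr::left_join(input, counts, by = "subject")
  out$n_removed[is.na(out$n_removed)] <- 0L
  tibble::tibble(
    subject = out$subject, rule = rule, n_removed = out$n_removed,
    n_input = out$n_input, fraction = out$n_removed / out$n_input
  )
}

drop_rows <- function(dataset, rows) {
  if (length(rows)) dataset$trials <- dataset$trials[-rows, , drop = FALSE]
  dataset
}

#' Keep long-enough trials and demean each channel
#'
#' Removes trials whose pre-target period is shorter than `min_pretarget`
#' (inclusive threshold: a trial at exactly the minimum is kept), then
#' subtracts each channel's mean over the whole segment.
#'
#' @param dataset An `attn_dataset`.
#' @param min_pretarget Minimum pre-target period, s.
#' @return A list with elements `dataset` and `report` (tibble with
#'   columns `subject`, `rule`, `n_removed`, `n_input`, `fraction`).
#' @export
segment_demean_filter <- function(dataset, min_pretarget = 2.0) {
  short <- which(dataset$trials$pre_target_period < min_pretarget)
  report <- new_report(dataset, "short_pretarget", short)
  dataset <- drop_rows(dataset, short)
  dataset$trials$data <- lapply(dataset$trials$data, function(x) {
    x - rowMeans(x)
  })
  list(dataset = dataset, report = report)
}

#' Reject trials with extreme reaction times
#'
#' Removes trials with responses faster than `lo` or slower than `hi`
#' (strict inequalities: RTs exactly at a bound are kept).
#'
#' @param dataset An `attn_dataset`.
#' @param lo,hi Bounds in seconds.
#' @return A list with `dataset` and `report` (see
#'   [segment_demean_filter()]).
#' @export
reject_rt <- function(dataset, lo = 0.3, hi = 2.0) {
  bad <- which(dataset$trials$rt < lo | dataset$trials$rt > hi)
  report <- new_report(dataset, "rt", bad)
  list(dataset = drop_rows(dataset, bad), report = report)
}

#' Reject trials with gaze excursions from fixation
#'
#' Each trial's gaze trace is re-referenced to its mean position during
#' the 1 s pre-cue period (drift correction); the trial is removed iff
#' the radial deviation exceeds `threshold` degrees continuously for
#' longer than `min_excursion` seconds inside the post-cue `window`.
#' Trials with a missing gaze trace are excluded under the distinct rule
#' `"gaze_missing"`.
#'
#' @param dataset An `attn_dataset`.
#' @param threshold Radial deviation threshold, degrees.
#' @param min_excursion Minimum excursion duration, s (strictly exceeded).
#' @param window Post-cue evaluation window, s.
#' @return A list with `dataset` and `report`.
#' @export
reject_gaze <- function(dataset, threshold = 2, min_excursion = 0.05,
                        window = c(1, 2.5)) {
  fs <- dataset$rate
  t0 <- dataset$t0
  status <- vapply(dataset$trials$gaze, function(g) {
    if (is.null(g) || anyNA(g)) return("missing")
    t <- seq(t0, by = 1 / fs, length.out = nrow(g))
    base <- colMeans(g[t < 0, , drop = FALSE])
    r <- sqrt((g[, 1L] - base[1L])^2 + (g[, 2L] - base[2L])^2)
    out <- r > threshold & t >= window[1L] & t <= window[2L]
    runs <- rle(out)
    if (any(runs$values & runs$lengths / fs > min_excursion)) "excursion" else "ok"
  }, character(1))
  rep_missing <- new_report(dataset, "gaze_missing", which(status == "missing"))
  rep_gaze <- new_report(dataset, "gaze", which(status == "excursion"))
  dataset <- drop_rows(dataset, which(status != "ok"))
  list(dataset = dataset, report = dplyr::bind_rows(rep_gaze, rep_missing))
}

#' Reject broadband power outliers
#'
#' Computes, per trial, the mean squared amplitude over all sensors in
#' the post-cue `window` and removes trials whose value deviates more
#' than `k` standard deviations from the mean over all of that subject's
#' trials. With zero variance (e.g. identical trials) nothing is removed.
#'
#' @param dataset An `attn_dataset`.
#' @param k SD multiplier.
#' @param window Post-cue window, s.
#' @return A list with `dataset` and `report`.
#' @export
reject_power_outliers <- function(dataset, k = 3, window = c(1, 2.5)) {
  fs <- dataset$rate
  t0 <- dataset$t0
  if (any(table(dataset$trials$subject) < 3L)) {
    abort("power-outlier rejection needs at least 3 trials per subject.")
  }
  pow <- vapply(dataset$trials$data, function(x) {
    t <- seq(t0, by = 1 / fs, length.out = ncol(x))
    sel <- t >= window[1L] & t <= window[2L]
    mean(x[, sel, drop = FALSE]^2)
  }, numeric(1))
  bad <- unlist(lapply(split(seq_along(pow), dataset$trials$subject), function(idx) {
    m <- mean(pow[idx]); s <- sd(pow[idx])
    if (!is.finite(s) || s == 0) return(integer(0))
    idx[abs(pow[idx] - m) > k * s]
  }), use.names = FALSE)
  report <- new_report(dataset, "power", bad)
  list(dataset = drop_rows(dataset, bad), report = report)
}

#' Run the full trial-rejection cascade
#'
#' Applies, in order: minimum pre-target filtering plus demeaning,
#' reaction-time rejection, gaze rejection, and power-outlier rejection.
#' The order matters for the bookkeeping: each rule's fractions refer to
#' the subject's trial count entering that rule, and rejected sets are
#' disjoint by construction.
#'
#' @param dataset An `attn_dataset`.
#' @param min_pretarget,rt_bounds,gaze_threshold,gaze_min_excursion,window,power_k
#'   Rule parameters (see the individual rejection functions).
#' @return A list with `dataset` (survivors) and `report`, a
#'   `rejection_report` tibble stacking every rule's per-subject counts.
#' @export
preprocess <- function(dataset, min_pretarget = 2.0, rt_bounds = c(0.3, 2.0),
                       gaze_threshold = 2, gaze_min_excursion = 0.05,
                       window = c(1, 2.5), power_k = 3) {
  s1 <- segment_demean_filter(dataset, min_pretarget)
  s2 <- reject_rt(s1$dataset, rt_bounds[1L], rt_bounds[2L])
  s3 <- reject_gaze(s2$dataset, gaze_threshold, gaze_min_excursion, window)
  s4 <- reject_power_outliers(s3$dataset, power_k, window)
  report <- dplyr::bind_rows(s1$report, s2$report, s3$report, s4$report)
  class(report) <- c("rejection_report", class(report))
  list(dataset = s4$dataset, report = report)
}

#' Synthetic planar gradient transform
#'
#' Estimates, for every sensor, the local spatial gradient of the field
#' along two orthogonal layout axes from the differences with its
#' neighbouring sensors, weighted by inverse layout distance (a weighted
#' least-squares plane fit). A spatially uniform field maps to zero in
#' both components and a linear spatial ramp maps to its exact gradient.
#' The transform is linear in the data.
#'
#' @param dataset An `attn_dataset`.
#' @param sensors Sensor array (defaults to the dataset's).
#' @return A `planar_set`: list with `x` and `y` (datasets whose `data`
#'   hold the two gradient components, same trial count and sensor order
#'   as the input) and `sensors`.
#' @export
to_planar_gradient <- function(dataset, sensors = dataset$sensors) {
  ops <- planar_operators(sensors)
  dx <- dataset; dy <- dataset
  dx$trials$data <- lapply(dataset$trials$data, function(d) ops$gx %*% d)
  dy$trials$data <- lapply(dataset$trials$data, function(d) ops$gy %*% d)
  structure(list(x = dx, y = dy, sensors = sensors), class = "planar_set")
}

# per-sensor weighted least-squares gradient operators (S x S matrices)
planar_operators <- function(sensors) {
  adj <- sensor_adjacency(sensors, "list")
  pos <- cbind(sensors$x, sensors$y)
  S <- nrow(pos)
  gx <- matrix(0, S, S)
  gy <- matrix(0, S, S)
  for (i in seq_len(S)) {
    nb <- adj[[i]]
    if (length(nb) < 2L) {
      abort(sprintf("sensor %s has fewer than 2 neighbours; cannot form planar gradient.",
                    sensors$label[i]))
    }
    D <- pos[nb, , drop = FALSE] - matrix(pos[i, ], length(nb), 2, byrow = TRUE)
    w <- 1 / sqrt(rowSums(D^2))
    A <- crossprod(D * w, D)  # t(D) W D with W = diag(w)
    if (abs(det(A)) < 1e-10) {
      abort(sprintf("neighbours of sensor %s are collinear.", sensors$label[i]))
    }
    # gradient = solve(A) t(D) W (x_nb - x_i)
    G <- solve(A, t(D * w))
    gx[i, nb] <- gx[i, nb] + G[1L, ]
    gx[i, i] <- gx[i, i] - sum(G[1L, ])
    gy[i, nb] <- gy[i, nb] + G[2L, ]
    gy[i, i] <- gy[i, i] - sum(G[2L, ])
  }
  list(gx = gx, gy = gy)
}

#' @export
print.planar_set <- function(x, ...) {
  cat(sprintf("<planar_set: %d trials x %d sensors, 2 gradient components>\n",
              nrow(x$x$trials), nrow(x$sensors)))
  invisible(x)
}
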