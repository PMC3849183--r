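# shared fixtures, built once per test run
fixtures <- new.env()

# a small dataset with planted effects, reused across module tests
tiny_dataset <- function() {
  if (is.null(fixtures$tiny)) {
    fixtures$tiny <- generate_dataset(
      generator_preset("small-test", n_subjects = 6,
                       n_trials_per_condition = 8, seed = 42)
    )
  }
  fixtures$tiny
}

# hand-built dataset wrapper: trials from explicit signal matrices
manual_dataset <- function(data, gaze = NULL, rt = NULL, pre = NULL,
                           rate = 300, sensors = NULL, subject = NULL) {
  n <- length(data)
  if (is.null(sensors)) sensors <- make_sensor_array(6, "grid")
  if (is.null(gaze)) {
    gaze <- lapply(data, function(d) matrix(0, ncol(d), 2))
  }
  if (is.null(rt)) rt <- rep(0.6, n)
  if (is.null(pre)) {
    pre <- vapply(data, function(d) (ncol(d) - 1) / rate - 2, numeric(1))
  }
  if (is.null(subject)) subject <- rep(1L, n)
  trials <- tibble::tibble(
    subject = subject, trial = seq_len(n),
    difficulty = rep_len(c("easy", "difficult"), n),
    eccentricity = rep_len(c("near", "far"), n),
    hemifield = rep_len(c("left", "right"), n),
    pre_target_period = pre, correct = TRUE, rt = rt,
    true_effect = 0, data = data, gaze = gaze
  )
  structure(list(trials = trials, sensors = sensors, rate = rate, t0 = -1,
                 config = NULL),
            class = "attn_dataset")
}

# single sinusoidal trial at a given frequency/amplitude, all channels
sine_dataset <- function(freq, amp = 1, n_channels = 6, dur = 4.5,
                         rate = 300, phase = 0) {
  n <- round(dur * rate) + 1
  t <- seq(-1, by = 1 / rate, length.out = n)
  x <- matrix(rep(amp * sin(2 * pi * freq * t + phase), each = n_channels),
              nrow = n_channels)
  manual_dataset(list(x), rate = rate)
}

# brute-force tapered DFT band power, written independently of the
# package's matrix-product path (plain loops over samples and bins)
oracle_band_power <- function(seg, rate, freqs = c(8, 10, 12, 14)) {
  n <- length(seg)
  h <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  p <- numeric(length(freqs))
  for (k in seq_along(freqs)) {
    re <- 0; im <- 0
    for (j in seq_len(n)) {
      ang <- 2 * pi * freqs[k] * (j - 1) / rate
      re <- re + seg[j] * h[j] * cos(ang)
      im <- im - seg[j] * h[j] * sin(ang)
    }
    p[k] <- (re^2 + im^2) * 2 / sum(h)^2
  }
  mean(p)
}
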