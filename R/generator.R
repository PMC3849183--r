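#' Configuration for the synthetic covert-attention dataset generator
#'
#' Collects every knob of the generator with defaults set to the study
#' conditions the analysis assumes: 14 subjects, a 2 (easy/difficult) x
#' 2 (near 3.5 deg / far 7 deg) within-subject design with 110 trials per
#' condition, 50/50 left/right attended hemifield, trials spanning 1 s
#' pre-cue baseline + 0.5 s cue + variable pre-target period (90/10
#' mixture of range-limited exponentials) + 1 s post-target, sampled at
#' 300 Hz. Posterior sensors carry a 10 Hz alpha oscillation whose
#' amplitude decreases contralaterally and increases ipsilaterally to the
#' attended hemifield from `onset_ramp` after cue onset, scaled per
#' difficulty level and boosted in the left hemisphere during
#' right-hemifield attention (`hemisphere_asymmetry`). 1/f plus white
#' sensor noise is added everywhere.
#'
#' Effect amplitudes are calibrated (the study reports only derived
#' lateralization indices, not sensor-level amplitudes) such that the
#' full pipeline recovers lateralization values of the order observed
#' empirically (about 0.1).
#'
#' @param n_subjects Number of synthetic subjects.
#' @param n_trials_per_condition Trials per difficulty x eccentricity cell
#'   (must be even: hemifields are balanced 50/50 and interleaved).
#' @param n_sensors,layout_preset Passed to [make_sensor_array()].
#' @param sampling_rate Generation-side sampling rate, Hz.
#' @param alpha_freq Alpha oscillation frequency, Hz.
#' @param alpha_amplitude Baseline alpha amplitude on posterior sensors
#'   (arbitrary field units).
#' @param contra_decrease,ipsi_increase Named fractional amplitude effects
#'   per difficulty level (`easy`, `difficult`), each in `[0, 1)`.
#' @param hemisphere_asymmetry Factor boosting the left-hemisphere effect
#'   during right-hemifield attention (>= 1).
#' @param onset_ramp Time (s after cue onset) at which the lateralization
#'   reaches its plateau; the ramp starts at `ramp_start`.
#' @param ramp_start Time (s after cue onset) at which the ramp begins.
#' @param pink_exponent Spectral exponent of the 1/f background noise.
#' @param pink_sd,white_sd Standard deviations of the 1/f and white noise.
#' @param amp_jitter_sd Log-scale SD of the per-trial alpha amplitude.
#' @param eccentricity_effect Fractional scaling of the attention effect in
#'   the far condition (default 0: no eccentricity effect, the study's
#'   null finding).
#' @param cue_transient SD of an optional broadband transient added during
#'   the 0.5 s cue period (0 = off).
#' @param long_rate Decay rate of the long pre-target component on
#'   `[2, 3]` s; 0 is the uniform limit with mean exactly 2.5 s.
#' @param threshold,slope Psychometric threshold (contrast giving 75%
#'   correct) and Weibull slope used to draw trial correctness.
#' @param accuracy_easy,accuracy_difficult Target mean accuracies.
#' @param rt_mean_easy,rt_mean_difficult Target mean reaction times, s.
#' @param rt_shift,rt_sigma Shift and log-scale SD of the shifted-lognormal
#'   reaction-time distribution (`rt_sigma = 0` gives degenerate RTs equal
#'   to the configured mean).
#' @param seed Integer seed; fully determines the generated dataset.
#'
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects = 14,
                             n_trials_per_condition = 110,
                             n_sensors = 30,
                             layout_preset = "grid",
                             sampling_rate = 300,
                             alpha_freq = 10,
                             alpha_amplitude = 1,
                             contra_decrease = c(easy = 0.055, difficult = 0.085),
                             ipsi_increase = c(easy = 0.028, difficult = 0.043),
                             hemisphere_asymmetry = 1.3,
                             onset_ramp = 0.6,
                             ramp_start = 0.2,
                             pink_exponent = 1,
                             pink_sd = 2.0,
                             white_sd = 0.5,
                             amp_jitter_sd = 0.2,
                             eccentricity_effect = 0,
                             cue_transient = 0,
                             long_rate = 0,
                             threshold = 0.12,
                             slope = 3,
                             accuracy_easy = 0.96,
                             accuracy_difficult = 0.75,
                             rt_mean_easy = 0.571,
                             rt_mean_difficult = 0.763,
                             rt_shift = 0.2,
                             rt_sigma = 0.35,
                             seed = 1L) {
  cfg <- as.list(environment())
  eff <- c(cfg$contra_decrease, cfg$ipsi_increase)
  if (length(cfg$contra_decrease) != 2L || length(cfg$ipsi_increase) != 2L ||
      is.null(names(cfg$contra_decrease)) || is.null(names(cfg$ipsi_increase))) {
    abort("`contra_decrease` and `ipsi_increase` must be named (easy, difficult).")
  }
  if (any(eff < 0) || any(eff >= 1)) {
    abort("effect fractions must lie in [0, 1).")
  }
  if (sampling_rate <= 2 * alpha_freq) {
    abort("`sampling_rate` must exceed twice `alpha_freq`.")
  }
  if (n_trials_per_condition %% 2L != 0L) {
    abort("`n_trials_per_condition` must be even (balanced hemifields).")
  }
  if (onset_ramp > 1.5) {
    abort("`onset_ramp` exceeds the minimum post-cue trial length (1.5 s).")
  }
  if (onset_ramp <= ramp_start) {
    abort("`onset_ramp` must exceed `ramp_start`.")
  }
  structure(cfg, class = "generator_config")
}

#' Generator presets
#'
#' `"paper"` is the default configuration of [generator_config()];
#' `"null"` zeroes every attention effect (used for calibration studies);
#' `"small-test"` is a fast small-scale setting for examples and tests.
#'
#' @param preset Preset name.
#' @param ... Overrides forwarded to [generator_config()].
#' @return A `generator_config`.
#' @export
generator_preset <- function(preset = c("paper", "null", "small-test"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    "paper" = list(),
    "null" = list(
      contra_decrease = c(easy = 0, difficult = 0),
      ipsi_increase = c(easy = 0, difficult = 0),
      hemisphere_asymmetry = 1
    ),
    "small-test" = list(
      n_subjects = 8, n_trials_per_condition = 32, n_sensors = 16
    )
  )
  do.call(generator_config, utils::modifyList(args, list(...)))
}

#' Draw pre-target periods from the study's two-component mixture
#'
#' With probability 0.9 the period comes from a range-limited decaying
#' exponential on `[2, 3]` s (rate `long_rate`; the default 0 is the
#' uniform limit, mean exactly 2.5 s), and with probability 0.1 from a
#' range-limited exponential on `[0.5, 2)` s whose rate is solved so the
#' truncated mean is `short_mean` (default 0.8 s). Uses the current R RNG
#' stream; seed with `set.seed()` or `withr::with_seed()`.
#'
#' @param n Number of draws.
#' @param long_rate Decay rate of the long component (>= 0).
#' @param short_mean Target mean of the short component, in (0.5, 1.25).
#' @param p_long Mixture weight of the long component.
#' @return Numeric vector of durations in seconds, all in `[0.5, 3]`.
#' @export
sample_pretarget_period <- function(n = 1, long_rate = 0, short_mean = 0.8,
                                    p_long = 0.9) {
  long <- runif(n) < p_long
  out <- numeric(n)
  out[long] <- rtruncexp(sum(long), long_rate, 2, 3)
  out[!long] <- rtruncexp(sum(!long), truncexp_rate_for_mean(0.5, 2, short_mean),
                          0.5, 2)
  out
}

# inverse-CDF sampler for an exponential truncated to [lo, hi); rate 0 = uniform
rtruncexp <- function(n, rate, lo, hi) {
  if (n == 0L) return(numeric(0))
  if (rate <= 1e-12) return(runif(n, lo, hi))
  u <- runif(n)
  lo - log(1 - u * (1 - exp(-rate * (hi - lo)))) / rate
}

# mean of a truncated exponential on [lo, hi]
truncexp_mean <- function(rate, lo, hi) {
  if (rate <= 1e-12) return((lo + hi) / 2)
  w <- hi - lo
  lo + 1 / rate - w / (exp(rate * w) - 1)
}

# solve the rate giving a prescribed truncated mean (memoized)
truncexp_rate_for_mean <- function(lo, hi, target) {
  if (target <= lo || target >= (lo + hi) / 2) {
    abort("target mean must lie strictly between `lo` and the interval midpoint.")
  }
  key <- paste0("texp_", lo, "_", hi, "_", target)
  if (is.null(the[[key]])) {
    the[[key]] <- uniroot(function(r) truncexp_mean(r, lo, hi) - target,
                          interval = c(1e-6, 200), tol = 1e-12)$root
  }
  the[[key]]
}

#' Two-alternative forced-choice psychometric function
#'
#' Weibull psychometric function with guessing floor 0.5 (2AFC) and base
#' 2, so the probability correct is exactly 0.75 at `contrast ==
#' threshold` and approaches 1 at full contrast:
#' `p = 0.5 + 0.5 * (1 - 2^(-(contrast/threshold)^slope))`.
#'
#' @param contrast Stimulus Michelson contrast in `[0, 1]` (vectorized).
#' @param threshold Contrast yielding 75% correct (> 0).
#' @param slope Weibull slope (> 0).
#' @return Probability of a correct response.
#' @export
psychometric_accuracy <- function(contrast, threshold, slope = 3) {
  if (threshold <= 0) abort("`threshold` must be positive.")
  if (slope <= 0) abort("`slope` must be positive.")
  if (any(contrast < 0 | contrast > 1)) abort("`contrast` must lie in [0, 1].")
  0.5 + 0.5 * (1 - 2^(-(contrast / threshold)^slope))
}

#' @describeIn psychometric_accuracy Inverse: the contrast at which the
#'   psychometric function attains accuracy `p`.
#' @param p Target probability correct in (0.5, 1).
#' @export
contrast_for_accuracy <- function(p, threshold, slope = 3) {
  if (any(p <= 0.5 | p >= 1)) abort("`p` must lie in (0.5, 1).")
  pmin(1, threshold * (-log2(2 - 2 * p))^(1 / slope))
}

#' Draw behavioural outcomes for one difficulty level
#'
#' Correctness is Bernoulli with probability given by
#' [psychometric_accuracy()] at the condition's contrast (full-ish
#' contrast for easy, threshold contrast for difficult), and the reaction
#' time is a shifted lognormal whose mean matches the configured preset
#' (slower and less accurate in the difficult condition). Uses the
#' current RNG stream.
#'
#' @param difficulty `"easy"` or `"difficult"` (vectorized).
#' @param config A [generator_config()].
#' @return A tibble with columns `correct` (logical) and `rt` (seconds).
#' @export
sample_behavior <- function(difficulty, config = generator_config()) {
  stopifnot(all(difficulty %in% c("easy", "difficult")))
  contrast <- ifelse(
    difficulty == "easy",
    contrast_for_accuracy(config$accuracy_easy, config$threshold, config$slope),
    config$threshold  # threshold contrast: 75% by construction
  )
  p <- psychometric_accuracy(contrast, config$threshold, config$slope)
  rt_mean <- ifelse(difficulty == "easy", config$rt_mean_easy,
                    config$rt_mean_difficult)
  meanlog <- log(rt_mean - config$rt_shift) - config$rt_sigma^2 / 2
  tibble::tibble(
    correct = runif(length(difficulty)) < p,
    rt = config$rt_shift + rlnorm(length(difficulty), meanlog, config$rt_sigma)
  )
}

#' Placeholder diameter under cortical magnification
#'
#' Sizes a peripheral placeholder so that it covers an equal cortical
#' footprint at every eccentricity, using an inverse-linear cortical
#' magnification law `M(E) = a / (E + e0)`; the diameter is proportional
#' to `1 / M(E)`, i.e. `d(E) = c * (E + e0)`. The default parameters are
#' calibrated so the near (3.5 deg) and far (7 deg) placeholders measure
#' 1.04 deg and 1.40 deg.
#'
#' @param E Eccentricity in degrees of visual angle (> 0; vectorized).
#' @param params Magnification parameters from [magnification_params()].
#' @return Placeholder diameter in degrees.
#' @export
placeholder_diameter <- function(E, params = magnification_params()) {
  if (any(E <= 0)) abort("`E` must be positive (foveal singularity at E = 0).")
  params$c * (E + params$e0)
}

#' @describeIn placeholder_diameter Calibrate the inverse-linear law from
#'   two (eccentricity, diameter) anchor points.
#' @param d_near,d_far,e_near,e_far Anchor diameters and eccentricities.
#' @export
magnification_params <- function(d_near = 1.04, d_far = 1.40,
                                 e_near = 3.5, e_far = 7) {
  cc <- (d_far - d_near) / (e_far - e_near)
  list(c = cc, e0 = d_near / cc - e_near)
}

#' Generate a synthetic covert-attention dataset
#'
#' Produces per-subject trials with the statistical structure the
#' analysis pipeline assumes (see [generator_config()]). Each trial spans
#' -1 s (pre-cue) to `pre_target_period + 1` s relative to cue onset.
#' Posterior sensors carry an alpha oscillation whose amplitude is, from
#' the post-cue ramp onward, reduced contralaterally and raised
#' ipsilaterally to the attended hemifield; 1/f and white noise are added
#' on all sensors; gaze traces fixate centrally with small drift and
#' jitter; behavioural outcomes follow the condition presets. Trials are
#' generated with hemifields interleaved (alternating within each
#' condition in presentation order), so any contiguous block of a
#' condition's trials contains both classes. The configured seed fully
#' determines the output.
#'
#' @param config A [generator_config()].
#' @return An `attn_dataset`: a list with `trials` (tibble with one row
#'   per trial; columns `subject`, `trial`, `difficulty`, `eccentricity`,
#'   `hemifield`, `pre_target_period`, `correct`, `rt`, `true_effect`,
#'   plus list-columns `data` (sensors x samples matrix) and `gaze`
#'   (samples x 2, degrees)), `sensors` (the [make_sensor_array()]
#'   layout), `rate` (Hz), `t0` (segment start, s relative to cue onset)
#'   and `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  sensors <- make_sensor_array(config$n_sensors, config$layout_preset)
  withr::with_seed(config$seed, {
    subj <- lapply(seq_len(config$n_subjects), function(s) {
      generate_subject(s, config, sensors)
    })
  })
  trials <- dplyr::bind_rows(subj)
  structure(
    list(trials = trials, sensors = sensors, rate = config$sampling_rate,
         t0 = -1, config = config),
    class = "attn_dataset"
  )
}

#' @export
print.attn_dataset <- function(x, ...) {
  cat(sprintf(
    "<attn_dataset: %d trials, %d subjects, %d sensors @ %g Hz>\n",
    nrow(x$trials), length(unique(x$trials$subject)), nrow(x$sensors), x$rate
  ))
  invisible(x)
}

generate_subject <- function(subject, config, sensors) {
  n_cond <- config$n_trials_per_condition
  design <- tidyr::expand_grid(
    difficulty = c("easy", "difficult"),
    eccentricity = c("near", "far"),
    rep = seq_len(n_cond)
  )
  design <- design[sample.int(nrow(design)), c("difficulty", "eccentricity")]
  # hemifield alternates within each condition in presentation order,
  # giving exact 50/50 balance and interleaved labels
  occ <- stats::ave(seq_len(nrow(design)),
                    paste(design$difficulty, design$eccentricity),
                    FUN = seq_along)
  design$hemifield <- ifelse(occ %% 2L == 1L, "left", "right")
  design$pre_target_period <- sample_pretarget_period(
    nrow(design), long_rate = config$long_rate
  )
  beh <- sample_behavior(design$difficulty, config)
  fs <- config$sampling_rate
  post <- sensors$posterior
  hemi <- sensors$hemisphere
  n_tr <- nrow(design)
  data <- vector("list", n_tr)
  gaze <- vector("list", n_tr)
  true_effect <- numeric(n_tr)
  for (i in seq_len(n_tr)) {
    tr <- simulate_trial(
      difficulty = design$difficulty[i],
      eccentricity = design$eccentricity[i],
      hemifield = design$hemifield[i],
      pre_target = design$pre_target_period[i],
      config = config, posterior = post, hemisphere = hemi
    )
    data[[i]] <- tr$data
    gaze[[i]] <- tr$gaze
    true_effect[i] <- tr$true_effect
  }
  tibble::tibble(
    subject = subject,
    trial = seq_len(n_tr),
    difficulty = design$difficulty,
    eccentricity = design$eccentricity,
    hemifield = design$hemifield,
    pre_target_period = design$pre_target_period,
    correct = beh$correct,
    rt = beh$rt,
    true_effect = true_effect,
    data = data,
    gaze = gaze
  )
}

simulate_trial <- function(difficulty, eccentricity, hemifield, pre_target,
                           config, posterior, hemisphere) {
  fs <- config$sampling_rate
  n <- round((pre_target + 2) * fs) + 1L
  t <- seq(-1, by = 1 / fs, length.out = n)
  S <- length(posterior)

  x <- pink_noise(n, S, config$pink_exponent, config$pink_sd)
  if (config$white_sd > 0) x <- x + rnorm(S * n, sd = config$white_sd)
  x <- matrix(x, nrow = S)

  # difficulty- and eccentricity-scaled effect fractions
  ecc_scale <- if (eccentricity == "far") 1 + config$eccentricity_effect else 1
  e_contra <- config$contra_decrease[[difficulty]] * ecc_scale
  e_ipsi <- config$ipsi_increase[[difficulty]] * ecc_scale
  contra_hemi <- if (hemifield == "left") "right" else "left"
  # left-hemisphere dominance: boost during right-hemifield attention
  asym <- function(h) {
    if (h == "left" && hemifield == "right") config$hemisphere_asymmetry else 1
  }

  ramp <- pmin(1, pmax(0, (t - config$ramp_start) /
                            (config$onset_ramp - config$ramp_start)))
  amp <- config$alpha_amplitude *
    exp(rnorm(1, sd = config$amp_jitter_sd) - config$amp_jitter_sd^2 / 2)
  idx_post <- which(posterior)
  if (length(idx_post)) {
    phases <- runif(length(idx_post), 0, 2 * pi)
    carrier <- outer(phases, 2 * pi * config$alpha_freq * t, `+`)
    env <- matrix(1, nrow = length(idx_post), ncol = n)
    for (k in seq_along(idx_post)) {
      h <- hemisphere[idx_post[k]]
      env[k, ] <- if (h == contra_hemi) {
        1 - pmin(0.95, e_contra * asym(h)) * ramp
      } else {
        1 + e_ipsi * asym(h) * ramp
      }
    }
    x[idx_post, ] <- x[idx_post, ] + amp * env * sin(carrier)
  }
  if (config$cue_transient > 0) {
    in_cue <- t >= 0 & t <= 0.5
    x[, in_cue] <- x[, in_cue] +
      rnorm(S * sum(in_cue), sd = config$cue_transient)
  }

  # gaze: slow AR(1) jitter around fixation plus a constant per-trial offset
  g <- vapply(1:2, function(j) {
    as.numeric(stats::filter(rnorm(n, sd = 0.1), 0.9, method = "recursive")) +
      rnorm(1, sd = 0.2)
  }, numeric(n))

  list(
    data = x, gaze = g,
    true_effect = (e_contra * (asym("left") + asym("right")) / 2 + e_ipsi)
  )
}

# 1/f^exponent noise, n samples x k series, each rescaled to sd `sd`
pink_noise <- function(n, k, exponent, sd) {
  nf <- n %/% 2L
  f <- seq_len(nf)
  shape <- f^(-exponent / 2)
  z <- matrix(complex(
    real = rnorm(nf * k), imaginary = rnorm(nf * k)
  ) * shape, nrow = nf)
  spec <- matrix(0i, nrow = n, ncol = k)
  spec[2:(nf + 1L), ] <- z
  # the real part of the inverse transform implicitly symmetrizes the spectrum
  x <- Re(mvfft(spec, inverse = TRUE)) / n
  x <- sweep(x, 2L, apply(x, 2L, sd), `/`) * sd
  x
}

#' Inject known artifacts into a dataset
#'
#' Marks disjoint random subsets of trials and plants, per rule: (a) a
#' gaze excursion beyond 2 deg lasting more than 0.05 s inside the 1-2.5 s
#' post-cue window, (b) broadband power inflation (signal scaled 5x), and
#' (c) reaction times outside `[0.3, 2]` s (alternating 0.1 s and 2.5 s).
#' The injected trial indices are returned so downstream rejection filters
#' can be tested for exact recovery.
#'
#' @param dataset An `attn_dataset`.
#' @param rates Named list/vector of fractions in `[0, 1]` for `gaze`,
#'   `power` and `rt`; the rules are mutually exclusive so the fractions
#'   must sum to at most 1. Counts are `round(rate * n_trials)`.
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return A list with `dataset` (modified) and `injected`, a tibble with
#'   columns `rule` and `row` (row index into `dataset$trials`).
#' @export
inject_artifacts <- function(dataset, rates = list(gaze = 0, power = 0, rt = 0),
                             seed = NULL) {
  rates <- utils::modifyList(list(gaze = 0, power = 0, rt = 0), as.list(rates))
  r <- unlist(rates[c("gaze", "power", "rt")])
  if (any(r < 0 | r > 1)) abort("artifact rates must lie in [0, 1].")
  if (sum(r) > 1) abort("mutually exclusive artifact rates sum above 1.")
  n <- nrow(dataset$trials)
  counts <- round(r * n)
  run <- function() {
    pool <- seq_len(n)
    picked <- list()
    for (rule in names(counts)) {
      k <- counts[[rule]]
      if (rule %in% c("gaze", "power")) {
        # need the full 1-2.5 s window inside the segment
        elig <- intersect(pool, which(dataset$trials$pre_target_period >= 1.5))
      } else {
        elig <- pool
      }
      if (k > length(elig)) abort("not enough eligible trials for rule ", rule)
      sel <- if (k > 0) sort(sample(elig, k)) else integer(0)
      picked[[rule]] <- sel
      pool <- setdiff(pool, sel)
    }
    picked
  }
  picked <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  fs <- dataset$rate
  t0 <- dataset$t0
  for (i in picked$gaze) {
    g <- dataset$trials$gaze[[i]]
    t <- seq(t0, by = 1 / fs, length.out = nrow(g))
    win <- t >= 1.2 & t <= 1.3  # 0.1 s excursion inside [1, 2.5]
    g[win, 1L] <- g[win, 1L] + 3
    dataset$trials$gaze[[i]] <- g
  }
  for (i in picked$power) {
    dataset$trials$data[[i]] <- dataset$trials$data[[i]] * 5
  }
  if (length(picked$rt)) {
    dataset$trials$rt[picked$rt] <-
      rep_len(c(0.1, 2.5), length(picked$rt))
  }
  injected <- dplyr::bind_rows(lapply(names(picked), function(rule) {
    tibble::tibble(rule = rule, row = picked[[rule]])
  }))
  list(dataset = dataset, injected = injected)
}
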