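# Synthetic sinus-rhythm ECG generator. Beats are sums of Gaussian bumps
# (one per P/Q/R/S/T wave) placed on a beat onset train with controllable
# beat-to-beat variability, plus baseline wander and white noise. Two
# morphology presets emulate reported female/male differences: lower R
# amplitude and a later, broader T wave (larger QT fraction) in the
# female-like class.

#' Default per-lead amplitude scales
#'
#' One underlying waveform is scaled per lead; signs and magnitudes roughly
#' follow the typical adult 12-lead presentation (aVR inverted, highest
#' amplitudes in the mid-precordial leads).
#' @export
default_lead_scales <- function() {
  c(I = 0.70, II = 1.00, III = 0.45, aVR = -0.85, aVL = 0.35, aVF = 0.65,
    V1 = 0.60, V2 = 1.10, V3 = 1.25, V4 = 1.30, V5 = 1.10, V6 = 0.90)
}

#' Build a beat template for a morphology class
#'
#' Returns the P/Q/R/S/T Gaussian-bump table for one of the two synthetic
#' morphology classes. Relative to `"M-like"`, the `"F-like"` preset has a
#' lower R amplitude and a later, broader, lower T wave, i.e. a larger QT
#' fraction of the cycle — the directions reported for female ECGs.
#'
#' @param class_label `"F-like"` or `"M-like"`.
#' @param separation Scalar in `[0, 1]` scaling how far the class template
#'   sits from the midpoint of the two presets; `1` (default) gives the full
#'   preset difference, `0` makes the classes identical.
#' @return A `beat_template`: data.frame with columns `label`, `amplitude`
#'   (mV), `center` and `width` (fractions of the cardiac cycle).
#' @export
make_preset <- function(class_label = c("F-like", "M-like"), separation = 1) {
  class_label <- match.arg(class_label)
  stopifnot(separation >= 0, separation <= 1)
  f <- data.frame(
    label = c("P", "Q", "R", "S", "T"),
    amplitude = c(0.15, -0.10, 1.15, -0.25, 0.38),
    center = c(0.10, 0.19, 0.225, 0.26, 0.47),
    width = c(0.025, 0.008, 0.010, 0.008, 0.070),
    stringsAsFactors = FALSE
  )
  m <- f
  m$amplitude <- c(0.15, -0.10, 1.60, -0.25, 0.50)
  m$center <- c(0.10, 0.19, 0.225, 0.26, 0.42)
  m$width <- c(0.025, 0.008, 0.010, 0.008, 0.055)
  mid <- f
  for (col in c("amplitude", "center", "width"))
    mid[[col]] <- (f[[col]] + m[[col]]) / 2
  pick <- if (class_label == "F-like") f else m
  out <- mid
  for (col in c("amplitude", "center", "width"))
    out[[col]] <- mid[[col]] + separation * (pick[[col]] - mid[[col]])
  beat_template(out)
}

#' Construct and validate a beat template
#'
#' @param waves data.frame with columns `label` (P,Q,R,S,T in cycle order),
#'   `amplitude` (mV), `center` (fraction of cycle in `[0,1)`), `width`
#'   (Gaussian sd as fraction of cycle, positive and `< 0.5`).
#' @return The validated `beat_template`.
#' @export
beat_template <- function(waves) {
  stopifnot(is.data.frame(waves),
            all(c("label", "amplitude", "center", "width") %in% colnames(waves)))
  if (!identical(waves$label, c("P", "Q", "R", "S", "T")))
    stop("waves must be labelled P, Q, R, S, T in cycle order")
  if (any(diff(waves$center) <= 0))
    stop("wave centers must be strictly increasing in cycle order")
  if (any(waves$center < 0 | waves$center >= 1))
    stop("wave centers must lie in [0, 1)")
  if (any(waves$width <= 0 | waves$width >= 0.5))
    stop("wave widths must be positive and < 0.5")
  structure(waves, class = c("beat_template", "data.frame"))
}

#' Synthesis parameters for one record
#'
#' @param template A `beat_template`.
#' @param heart_rate_bpm Mean heart rate, beats per minute.
#' @param rr_sd Beat-to-beat (interbeat) standard deviation in seconds;
#'   intervals are drawn Normal(60/heart_rate_bpm, rr_sd) truncated at 0.3 s
#'   to prevent beat overlap.
#' @param duration Record length in seconds.
#' @param sampling_rate Hz.
#' @param baseline_amp Baseline-wander sinusoid amplitude, mV.
#' @param baseline_freq Baseline-wander frequency, Hz.
#' @param noise_sd White-noise standard deviation per lead, mV.
#' @param lead_scales Named per-lead multiplicative scales of the underlying
#'   waveform.
#' @param class_label `"F-like"`, `"M-like"` or `NA`.
#' @param seed Integer seed; the record is fully determined by it.
#' @return A `synth_params` list.
#' @export
synth_params <- function(template = make_preset("M-like"),
                         heart_rate_bpm = 70, rr_sd = 0.03,
                         duration = 10, sampling_rate = 500,
                         baseline_amp = 0.05, baseline_freq = 0.3,
                         noise_sd = 0.01,
                         lead_scales = default_lead_scales(),
                         class_label = NA_character_, seed = 1L) {
  stopifnot(heart_rate_bpm > 0, rr_sd >= 0, noise_sd >= 0,
            duration > 0, sampling_rate > 0, baseline_amp >= 0)
  structure(list(template = beat_template(template),
                 heart_rate_bpm = heart_rate_bpm, rr_sd = rr_sd,
                 duration = duration, sampling_rate = sampling_rate,
                 baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 noise_sd = noise_sd, lead_scales = lead_scales,
                 class_label = class_label, seed = as.integer(seed)),
            class = "synth_params")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Synthesize one multi-lead ECG-like record
#'
#' Beat onsets are a truncated-normal renewal process; each beat is the sum
#' of the template's Gaussian bumps (scaled per lead), to which a baseline
#' sinusoid (shared across leads) and independent white noise per lead are
#' added. With `rr_sd = noise_sd = baseline_amp = 0` the output is exactly
#' periodic with period `60/heart_rate_bpm`. The record is fully determined
#' by `params$seed`.
#'
#' @param params A `synth_params` object.
#' @param record_id,subject_id Identifiers for the produced record.
#' @return An `ecg_record` whose `sex` field is `"female"`/`"male"` when the
#'   class label is `"F-like"`/`"M-like"`, else `"unknown"`.
#' @export
synthesize_record <- function(params, record_id = "synth",
                              subject_id = record_id) {
  stopifnot(inherits(params, "synth_params"))
  t0 <- 60 / params$heart_rate_bpm
  if (params$duration < t0)
    stop("duration (", params$duration, " s) shorter than one cardiac cycle (",
         t0, " s)")
  fs <- params$sampling_rate
  n <- round(params$duration * fs)
  tt <- (seq_len(n) - 1) / fs
  with_seed(params$seed, {
    # beat onsets with two guard cycles either side so edges carry full
    # morphology (required for the exact-periodicity contract)
    n_beats <- ceiling((params$duration + 4 * t0) / max(0.3, t0 - 5 * max(params$rr_sd, 0.01))) + 2
    rr <- stats::rnorm(n_beats, mean = t0, sd = params$rr_sd)
    rr <- pmax(rr, 0.3)
    onsets <- -2 * t0 + cumsum(c(0, rr))
    onsets <- onsets[onsets < params$duration + 2 * t0]
    base_wave <- numeric(n)
    tpl <- params$template
    for (b in onsets) {
      for (w in seq_len(nrow(tpl))) {
        ctr <- b + tpl$center[w] * t0
        sd_s <- tpl$width[w] * t0
        lo <- max(1L, floor((ctr - 9 * sd_s) * fs) + 1L)
        hi <- min(n, ceiling((ctr + 9 * sd_s) * fs) + 1L)
        if (lo > hi) next
        idx <- lo:hi
        base_wave[idx] <- base_wave[idx] +
          tpl$amplitude[w] * exp(-((tt[idx] - ctr)^2) / (2 * sd_s^2))
      }
    }
    baseline <- params$baseline_amp *
      sin(2 * pi * params$baseline_freq * tt)
    leads <- names(params$lead_scales)
    samples <- matrix(0, nrow = n, ncol = length(leads),
                      dimnames = list(NULL, leads))
    for (j in seq_along(leads)) {
      noise <- if (params$noise_sd > 0)
        stats::rnorm(n, sd = params$noise_sd) else 0
      samples[, j] <- params$lead_scales[[j]] * base_wave + baseline + noise
    }
    sex <- if (is.na(params$class_label)) "unknown"
           else if (params$class_label == "F-like") "female" else "male"
    rec <- ecg_record(record_id, samples, leads, fs,
                      subject_id = subject_id, sex = sex)
    rec$params <- params
    rec$beat_onsets <- onsets[onsets >= 0 & onsets < params$duration]
    rec
  })
}

#' Synthesize a labelled cohort in two morphology classes
#'
#' @param n Number of records (>= 2).
#' @param class_mix Fraction of F-like records in `[0, 1]` (default 0.5).
#' @param age_sampler Either a function `n -> ages` or a list
#'   `list(min=, max=)` for uniform integer ages (default 20-79 years).
#' @param seed Master seed; per-record seeds and all record content derive
#'   from it.
#' @param separation Class-separation scalar passed to [make_preset()].
#' @param ... Further arguments forwarded to [synth_params()] (e.g.
#'   `noise_sd`, `rr_sd`, `sampling_rate`, `duration`).
#' @return An `ecg_cohort` with `sex` set from the class label and ages drawn
#'   from the sampler.
#' @export
synthesize_cohort <- function(n, class_mix = 0.5,
                              age_sampler = list(min = 20, max = 79),
                              seed = 1L, separation = 1, ...) {
  stopifnot(n >= 2, class_mix >= 0, class_mix <= 1)
  n_f <- round(n * class_mix)
  labels <- c(rep("F-like", n_f), rep("M-like", n - n_f))
  ages <- with_seed(seed, {
    if (is.function(age_sampler)) age_sampler(n)
    else sample(seq(age_sampler$min, age_sampler$max), n, replace = TRUE)
  })
  records <- vector("list", n)
  for (i in seq_len(n)) {
    p <- synth_params(template = make_preset(labels[i], separation),
                      class_label = labels[i],
                      seed = (as.integer(seed) * 1009L + i * 7L) %% 2147483647L,
                      ...)
    rec <- synthesize_record(p, record_id = sprintf("synth%04d", i))
    rec$age <- ages[i]
    records[[i]] <- rec
  }
  ecg_cohort(records, provenance = "synthetic")
}
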