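#' Beat morphology specification
#'
#' Parameterises one ECG beat as a sum of Gaussian bumps: one per P, Q, R,
#' S and T wave plus an optional J wave on the descending slope of the
#' terminal QRS. Each wave is an (amplitude mV, centre offset s relative to
#' the R peak, width s) triple. A morphology is J-wave-positive exactly
#' when `j_amplitude > 0`.
#'
#' Default amplitudes and timings are typical of a lead-II adult beat; the
#' J bump defaults sit 40-60 ms after R with 8-15 ms width and
#' 0.1-0.2 mV amplitude, i.e. strictly inside the 120-sample (0.24 s at
#' 500 Hz) post-R analysis window.
#'
#' @param waves Data frame with columns `wave`, `amp` (mV), `offset`
#'   (s relative to R) and `width` (s) for P, Q, R, S, T.
#' @param j_amplitude J-wave amplitude in mV (0 = J-wave-negative).
#' @param j_offset J-wave centre, seconds after the R peak.
#' @param j_width J-wave Gaussian width in seconds.
#' @return A `beat_morphology` object.
#' @export
beat_morphology <- function(waves = NULL, j_amplitude = 0,
                            j_offset = 0.05, j_width = 0.012) {
  if (is.null(waves)) {
    waves <- data.frame(
      wave   = c("P", "Q", "R", "S", "T"),
      amp    = c(0.12, -0.10, 1.20, -0.25, 0.35),
      offset = c(-0.18, -0.025, 0.00, 0.030, 0.30),
      width  = c(0.025, 0.010, 0.012, 0.010, 0.055))
  }
  stopifnot(is.data.frame(waves),
            all(c("wave", "amp", "offset", "width") %in% names(waves)),
            all(waves$width > 0), j_width > 0, j_amplitude >= 0)
  ramp <- waves$amp[waves$wave == "R"]
  if (length(ramp) != 1 ||
      ramp <= max(abs(waves$amp[waves$wave %in% c("Q", "S")])))
    stop("R amplitude must exceed |Q| and |S| amplitudes")
  if (j_amplitude > 0 &&
      (j_offset <= 0 || j_offset + 3 * j_width >= 0.24))
    stop("J wave must lie strictly inside the 0.24 s post-R window")
  structure(list(waves = waves, j_amplitude = j_amplitude,
                 j_offset = j_offset, j_width = j_width),
            class = "beat_morphology")
}

#' Noise specification for synthetic records
#'
#' Additive artefact model: sinusoidal baseline wander (respiratory-band,
#' < 1 Hz), sinusoidal powerline interference (50 or 60 Hz) and white
#' Gaussian noise. Defaults are mild enough that R-peak detection on the
#' noisy record stays essentially perfect, while giving the denoiser
#' something real to remove.
#'
#' @param baseline_amp,baseline_freq Baseline wander amplitude (mV) and
#'   frequency (Hz, must be < 1).
#' @param powerline_amp,powerline_freq Powerline amplitude (mV) and
#'   frequency (50 or 60 Hz).
#' @param white_sd White-noise standard deviation (mV).
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(baseline_amp = 0.1, baseline_freq = 0.3,
                       powerline_amp = 0.05, powerline_freq = 50,
                       white_sd = 0.03) {
  stopifnot(baseline_amp >= 0, powerline_amp >= 0, white_sd >= 0,
            baseline_freq > 0, baseline_freq < 1,
            powerline_freq %in% c(50, 60))
  structure(list(baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 powerline_amp = powerline_amp, powerline_freq = powerline_freq,
                 white_sd = white_sd),
            class = "noise_spec")
}

#' Silent noise specification (all components zero)
#' @return A `noise_spec` with every amplitude 0.
#' @export
noise_none <- function() noise_spec(baseline_amp = 0, powerline_amp = 0,
                                    white_sd = 0)

#' Generate one synthetic ECG beat
#'
#' Sum-of-Gaussians beat of duration `rr` seconds. The R peak sits at 35%
#' of the RR interval so the preceding P wave and the following T wave (and
#' J wave, if any) both fit inside the beat at physiological rates.
#'
#' @param morph A [beat_morphology()].
#' @param fs Sampling rate (Hz).
#' @param rr RR interval in seconds, within [0.4, 2].
#' @return Numeric vector of `round(rr * fs)` voltages (mV) with attribute
#'   `r_index` giving the 1-based sample of the R-wave centre.
#' @export
generate_beat <- function(morph, fs = 500, rr = 1.0) {
  stopifnot(inherits(morph, "beat_morphology"))
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  if (!is.finite(rr) || rr < 0.4 || rr > 2.0)
    stop("rr must lie in [0.4, 2.0] seconds")
  n <- round(rr * fs)
  r_time <- 0.35 * rr
  t <- (seq_len(n) - 1) / fs
  y <- numeric(n)
  for (i in seq_len(nrow(morph$waves))) {
    w <- morph$waves[i, ]
    y <- y + w$amp * exp(-((t - (r_time + w$offset))^2) / (2 * w$width^2))
  }
  if (morph$j_amplitude > 0) {
    y <- y + morph$j_amplitude *
      exp(-((t - (r_time + morph$j_offset))^2) / (2 * morph$j_width^2))
  }
  structure(y, r_index = as.integer(round(r_time * fs)) + 1L)
}

#' Generate a labelled synthetic ECG record
#'
#' Concatenates `n_beats` beats with per-beat RR jitter, then adds the
#' noise components on top of the whole record. The true R-sample of every
#' beat is kept, which is what makes detector scoring possible downstream.
#'
#' @param n_beats Number of beats (>= 1).
#' @param morph A [beat_morphology()]; its `j_amplitude` sets the label.
#' @param noise A [noise_spec()].
#' @param fs Sampling rate (Hz).
#' @param mean_hr Mean heart rate (bpm).
#' @param hr_jitter Fractional uniform RR jitter (0.05 = +/-5%).
#' @param seed Integer RNG seed; identical arguments give bit-identical
#'   records.
#' @param record_id Identifier string.
#' @return An `ecg_record`: list with `record_id`, `samples` (mV), `fs`,
#'   `label` ("positive"/"negative") and `true_r_indices` (1-based).
#' @export
generate_record <- function(n_beats, morph = beat_morphology(),
                            noise = noise_spec(), fs = 500, mean_hr = 60,
                            hr_jitter = 0.05, seed = 1,
                            record_id = "rec01") {
  stopifnot(n_beats >= 1, mean_hr > 0, hr_jitter >= 0, hr_jitter < 1)
  set.seed(seed)
  base_rr <- 60 / mean_hr
  rr <- base_rr * (1 + hr_jitter * stats::runif(n_beats, -1, 1))
  rr <- pmin(pmax(rr, 0.4), 2.0)
  beats <- lapply(rr, function(x) generate_beat(morph, fs, x))
  lens <- vapply(beats, length, 1L)
  starts <- cumsum(c(0L, lens[-n_beats]))
  samples <- unlist(beats, use.names = FALSE)
  r_idx <- starts + vapply(beats, attr, 1L, "r_index")

  n <- length(samples)
  t <- (seq_len(n) - 1) / fs
  if (noise$baseline_amp > 0)
    samples <- samples + noise$baseline_amp *
      sin(2 * pi * noise$baseline_freq * t + stats::runif(1, 0, 2 * pi))
  if (noise$powerline_amp > 0)
    samples <- samples + noise$powerline_amp *
      sin(2 * pi * noise$powerline_freq * t + stats::runif(1, 0, 2 * pi))
  if (noise$white_sd > 0)
    samples <- samples + stats::rnorm(n, 0, noise$white_sd)

  structure(list(record_id = record_id,
                 samples = samples,
                 fs = fs,
                 label = if (morph$j_amplitude > 0) "positive" else "negative",
                 true_r_indices = as.integer(r_idx)),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ecg_record %s: %d samples @ %g Hz, %d beats, label %s\n",
              x$record_id, length(x$samples), x$fs,
              length(x$true_r_indices), x$label))
  invisible(x)
}

#' Generate a multi-record labelled dataset with a record-level split
#'
#' Emulates the structure of a clinical J-wave cohort: `n_negative`
#' J-wave-negative and `n_positive` J-wave-positive records, each of
#' `beats_per_record` beats, split into train and test *by record* (a
#' record never contributes beats to both sides). Per-record morphology
#' varies through a log-normal amplitude factor; for positive records the
#' J-wave amplitude, latency and width are drawn per record, with mean
#' amplitude and between-record spread both scaled by `separation`, so
#' `separation = 0` collapses both classes onto one distribution.
#'
#' @param n_negative,n_positive Records per class (>= 1). Defaults (30/25
#'   records of 1200 beats) give 36000 negative and 30000 positive beats.
#' @param beats_per_record Beats per record.
#' @param separation Effect-size control in [0, Inf); 1 = default
#'   0.15 mV mean J amplitude.
#' @param seed Integer seed controlling every draw.
#' @param train_frac Fraction of records per class assigned to the
#'   training split (0.6 mirrors an 18/12 and 15/10 record split).
#' @param noise A [noise_spec()].
#' @param fs,mean_hr,hr_jitter Passed to [generate_record()].
#' @return List with `records` (list of `ecg_record`) and `manifest`
#'   (data.frame: record_id, label, split, seed).
#' @export
generate_dataset <- function(n_negative = 30, n_positive = 25,
                             beats_per_record = 1200, separation = 1,
                             seed = 1, train_frac = 0.6,
                             noise = noise_spec(), fs = 500, mean_hr = 60,
                             hr_jitter = 0.05) {
  stopifnot(n_negative >= 1, n_positive >= 1, beats_per_record >= 1,
            separation >= 0, train_frac > 0, train_frac < 1)
  n_tr_neg <- round(train_frac * n_negative)
  n_tr_pos <- round(train_frac * n_positive)
  if (n_tr_neg < 1 || n_tr_pos < 1 ||
      n_tr_neg >= n_negative || n_tr_pos >= n_positive)
    stop("split infeasible: each class needs at least one train and one test record")

  set.seed(seed)
  n_rec <- n_negative + n_positive
  rec_seeds <- sample.int(.Machine$integer.max - 1L, n_rec)
  base <- beat_morphology()

  records <- vector("list", n_rec)
  ids <- character(n_rec)
  labels <- character(n_rec)
  for (i in seq_len(n_rec)) {
    positive <- i > n_negative
    ids[i] <- if (positive) sprintf("pos%02d", i - n_negative)
              else sprintf("neg%02d", i)
    labels[i] <- if (positive) "positive" else "negative"
    # between-record variability: common log-normal gain on all waves
    gain <- exp(stats::rnorm(1, 0, 0.08))
    waves <- base$waves
    waves$amp <- waves$amp * gain
    if (positive && separation > 0) {
      j_amp <- separation * 0.15 * exp(stats::rnorm(1, 0, 0.2 * separation))
      j_off <- stats::runif(1, 0.040, 0.060)
      j_wid <- stats::runif(1, 0.008, 0.015)
      morph <- beat_morphology(waves, j_amplitude = j_amp,
                               j_offset = j_off, j_width = j_wid)
    } else {
      morph <- beat_morphology(waves, j_amplitude = 0)
    }
    records[[i]] <- generate_record(beats_per_record, morph, noise, fs,
                                    mean_hr, hr_jitter,
                                    seed = rec_seeds[i], record_id = ids[i])
    if (positive && separation == 0) records[[i]]$label <- "positive"
  }

  split <- c(rep(c("train", "test"), c(n_tr_neg, n_negative - n_tr_neg)),
             rep(c("train", "test"), c(n_tr_pos, n_positive - n_tr_pos)))
  manifest <- data.frame(record_id = ids, label = labels, split = split,
                         seed = rec_seeds, stringsAsFactors = FALSE)
  list(records = records, manifest = manifest)
}
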