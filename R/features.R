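#' Band-energy time-frequency descriptor of an SST plane
#'
#' Reduces the squared-magnitude SST plane to a fixed-length vector: the
#' total energy in each of `n_bands` uniform frequency bands
#' (time-marginalised, normalised by total plane energy), plus each band's
#' energy-weighted centroid time on a 0-1 scale. Gain-invariant by
#' construction.
#'
#' @param sst An `sst_plane`.
#' @param n_bands Number of uniform frequency bands (10, giving a
#'   length-20 descriptor).
#' @return Named numeric vector `tf_e01..tf_eB, tf_c01..tf_cB`.
#' @export
tf_feature <- function(sst, n_bands = 10) {
  stopifnot(inherits(sst, "sst_plane"), n_bands >= 1)
  e <- Mod(sst$T_f)^2
  nb <- nrow(e)
  nt <- ncol(e)
  band <- cut(seq_len(nb), breaks = round(seq(0, nb, length.out = n_bands + 1)),
              labels = FALSE)
  tot <- sum(e)
  enames <- sprintf("tf_e%02d", seq_len(n_bands))
  cnames <- sprintf("tf_c%02d", seq_len(n_bands))
  if (tot <= 0) {
    warning("zero-energy SST plane: zero feature vector")
    return(stats::setNames(numeric(2 * n_bands), c(enames, cnames)))
  }
  tmarg <- rowSums(e)
  be <- as.vector(rowsum(tmarg, band))
  tnorm <- if (nt > 1) (seq_len(nt) - 1) / (nt - 1) else 0.5
  cent <- vapply(seq_len(n_bands), function(b) {
    eb <- colSums(e[band == b, , drop = FALSE])
    s <- sum(eb)
    if (s > 0) sum(eb * tnorm) / s else 0.5
  }, 1)
  stats::setNames(c(be / tot, cent), c(enames, cnames))
}

#' Renyi entropy of one mode's time-frequency band
#'
#' Flattens the \eqn{|T_f|^2} cells within `bandwidth` of mode k's ridge
#' track into a probability distribution and takes its order-alpha Renyi
#' entropy — a measure of how spread the mode's energy is over its
#' time-frequency band (noise-like modes score higher than tonal ones).
#'
#' @param sst An `sst_plane`.
#' @param ridge_freqs Centre-frequency track of the mode (Hz, one value
#'   per time).
#' @param bandwidth Band half-width in Hz.
#' @param alpha Entropy order (3).
#' @return Entropy in bits.
#' @export
mode_renyi <- function(sst, ridge_freqs, bandwidth, alpha = 3) {
  stopifnot(inherits(sst, "sst_plane"),
            length(ridge_freqs) == ncol(sst$T_f))
  sel <- abs(outer(sst$freq_bins, rep(1, ncol(sst$T_f))) -
               matrix(ridge_freqs, nrow(sst$T_f), ncol(sst$T_f),
                      byrow = TRUE)) <= bandwidth
  if (!any(sel)) stop("undefined entropy: empty mode band")
  p <- Mod(sst$T_f[sel])^2
  if (sum(p) <= 0) stop("undefined entropy: zero-mass mode band")
  renyi_entropy(p, alpha)
}

#' Renyi entropy of a series' power spectrum
#'
#' Alternative complexity measure for a reconstructed mode: the order-alpha
#' Renyi entropy of the magnitude-squared DFT of the series. A narrow-band
#' (tonal) mode concentrates its spectrum into a few bins and scores low;
#' a noise-like mode spreads it and scores high. This direction is robust
#' here, whereas on the reassigned plane itself noise can look *less*
#' uniform than a tone (synchrosqueezing piles noise energy into few
#' strong cells).
#'
#' @param series Numeric vector (a mode time series).
#' @param alpha Entropy order (3).
#' @return Entropy in bits.
#' @export
spectrum_renyi <- function(series, alpha = 3) {
  p <- Mod(stats::fft(series))^2
  p <- p[seq_len(floor(length(p) / 2) + 1)]
  if (sum(p) <= 0) stop("undefined entropy: zero-energy series")
  renyi_entropy(p, alpha)
}

#' Feature configuration defaults
#'
#' All tunables of the feature chain with their operating-point values:
#' Morlet centre frequency 35 Hz, K = 5 modes, Renyi order 3, embedding
#' dimension 2, tolerance 0.2 x SD.
#'
#' @param fs Sampling rate (Hz).
#' @param center_frequency Morlet centre frequency (Hz).
#' @param n_voices Scales per octave.
#' @param K Number of modes.
#' @param gamma_rel Relative IF magnitude threshold.
#' @param bandwidth Reconstruction half-width (Hz); `NULL` = 4 bin widths.
#' @param alpha Renyi order.
#' @param m Embedding dimension for ApEn/SampEn.
#' @param r_factor Tolerance factor (x SD) for ApEn/SampEn.
#' @param n_bands Bands in the time-frequency descriptor.
#' @param lambda,max_jump Ridge-tracking controls.
#' @return A list used by [extract_features()].
#' @export
feature_config <- function(fs = 500, center_frequency = 35, n_voices = 32,
                           K = 5, gamma_rel = 1e-4, bandwidth = NULL,
                           alpha = 3, m = 2, r_factor = 0.2, n_bands = 10,
                           lambda = 0.01, max_jump = 10L) {
  list(fs = fs, center_frequency = center_frequency, n_voices = n_voices,
       K = K, gamma_rel = gamma_rel, bandwidth = bandwidth, alpha = alpha,
       m = m, r_factor = r_factor, n_bands = n_bands, lambda = lambda,
       max_jump = max_jump)
}

#' Extract the full feature vector of one beat window
#'
#' Runs the SST chain (CWT, instantaneous frequency, synchrosqueezing,
#' K-mode ridge extraction, inverse-SST reconstruction), then assembles:
#' the band-energy time-frequency descriptor of the SST plane, the Renyi
#' entropy of each mode's time-frequency band, and the approximate and
#' sample entropy of each reconstructed mode series.
#'
#' @param window Numeric beat window (mV), typically 120 samples.
#' @param config A [feature_config()].
#' @return Named numeric vector of length `2 * n_bands + 3 * K`
#'   (35 at defaults). Sample entropies that are undefined (no template
#'   match) come back as `NA`.
#' @export
extract_features <- function(window, config = feature_config()) {
  wv <- morlet_spec(center_frequency = config$center_frequency,
                    n_voices = config$n_voices,
                    freq_range = c(0.5, config$fs / 2))
  dec <- sst_decompose(window, config$fs, wavelet = wv, K = config$K,
                       gamma_rel = config$gamma_rel,
                       bandwidth = config$bandwidth,
                       lambda = config$lambda, max_jump = config$max_jump)
  tf <- tf_feature(dec$sst, config$n_bands)
  bw <- dec$modes$bandwidth
  re <- vapply(seq_len(config$K), function(k)
    mode_renyi(dec$sst, dec$ridges$freqs[k, ], bw, config$alpha), 1)
  ap <- vapply(seq_len(config$K), function(k)
    approximate_entropy(dec$modes$modes[k, ], m = config$m,
                        r_factor = config$r_factor), 1)
  se <- vapply(seq_len(config$K), function(k)
    as.numeric(sample_entropy(dec$modes$modes[k, ], m = config$m,
                              r_factor = config$r_factor)), 1)
  c(tf,
    stats::setNames(re, sprintf("re_m%d", seq_len(config$K))),
    stats::setNames(ap, sprintf("apen_m%d", seq_len(config$K))),
    stats::setNames(se, sprintf("sampen_m%d", seq_len(config$K))))
}

#' Extract features for every window of a beat collection
#'
#' Applies [extract_features()] per window; a window failing any stage is
#' skipped with a message rather than aborting the batch.
#'
#' @param beats A `beat_windows` object.
#' @param config A [feature_config()].
#' @param progress Print a progress message every `progress` windows
#'   (0 = silent).
#' @return Data frame: record_id, r_index, label, then the feature columns.
#' @export
extract_features_all <- function(beats, config = feature_config(),
                                 progress = 0) {
  stopifnot(inherits(beats, "beat_windows"))
  n <- nrow(beats$windows)
  rows <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    fv <- tryCatch(extract_features(beats$windows[i, ], config),
                   error = function(e) NULL)
    if (!is.null(fv)) {
      rows[[i]] <- fv
      ok[i] <- TRUE
    }
    if (progress > 0 && i %% progress == 0)
      message(sprintf("features: %d/%d windows", i, n))
  }
  if (any(!ok))
    message(sprintf("extract_features_all: skipped %d window(s)", sum(!ok)))
  feat <- do.call(rbind, rows[ok])
  cbind(beats$meta[ok, , drop = FALSE], as.data.frame(feat),
        row.names = NULL)
}
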