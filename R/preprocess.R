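# Daubechies-6 analysis filters (12 taps, orthonormal).
DB6_LO <- c(-0.0010773010853084796, 0.004777257510945511,
            0.0005538422011614961, -0.03158203931748603,
            0.027522865530305727, 0.09750160558732304,
            -0.12976686756726194, -0.22626469396543983,
            0.31525035170919763, 0.7511339080210954,
            0.49462389039845306, 0.11154074335010947)
DB6_HI <- c(-0.11154074335010947, 0.49462389039845306,
            -0.7511339080210954, 0.31525035170919763,
            0.22626469396543983, -0.12976686756726194,
            -0.09750160558732304, 0.027522865530305727,
            0.03158203931748603, 0.0005538422011614961,
            -0.004777257510945511, -0.0010773010853084796)

# One periodized analysis step: v (even length) -> list(a, d).
dwt_step <- function(v) {
  L <- length(v)
  half <- L %/% 2L
  nf <- length(DB6_LO)
  idx <- outer(2L * (seq_len(half) - 1L), seq_len(nf) - 1L, "+") %% L + 1L
  vm <- matrix(v[idx], half, nf)
  list(a = as.vector(vm %*% DB6_LO), d = as.vector(vm %*% DB6_HI))
}

# Inverse of dwt_step (transpose of the orthogonal analysis operator).
idwt_step <- function(a, d) {
  half <- length(a)
  L <- 2L * half
  v <- numeric(L)
  base <- 2L * (seq_len(half) - 1L)
  for (n in seq_along(DB6_LO)) {
    idx <- (base + n - 1L) %% L + 1L
    v[idx] <- v[idx] + DB6_LO[n] * a + DB6_HI[n] * d
  }
  v
}

# Multi-level periodized db6 DWT of x (length a multiple of 2^levels).
dwt_db6 <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details)
}

idwt_db6 <- function(decomp) {
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details)))
    a <- idwt_step(a, decomp$details[[j]])
  a
}

#' Wavelet-denoise an ECG record
#'
#' Eight-level Daubechies-6 decomposition with soft thresholding of every
#' detail band at the universal threshold \eqn{\hat\sigma \sqrt{2 \ln N}}
#' (\eqn{\hat\sigma} from the median absolute deviation of the level-1
#' details, where the signal is sparse and the noise is not). The
#' level-8 approximation band (0 to fs/2^9, i.e. below ~1 Hz at 500 Hz) is
#' attenuated below 0.6 Hz — its coefficient sequence is low-pass filtered
#' at 0.6 Hz and that component (less its mean) subtracted — which removes
#' respiratory-band baseline wander while sparing the DC offset and the
#' low edge of the beat spectrum, so a clean record passes through
#' essentially unchanged.
#'
#' @param record An `ecg_record` (or plain numeric vector plus `fs`).
#' @param levels Decomposition depth (8).
#' @return The record with `samples` replaced by the denoised signal
#'   (same length).
#' @export
denoise <- function(record, levels = 8) {
  x <- if (inherits(record, "ecg_record")) record$samples else record
  n <- length(x)
  if (n < 2^levels)
    stop(sprintf("record too short for a %d-level transform (need >= %d samples)",
                 levels, 2^levels))
  # pad by symmetric extension to a multiple of 2^levels, generously past
  # the filter support at the deepest level
  block <- 2^levels
  target <- max(ceiling(n / block), 16L) * block
  pad <- target - n
  xp <- c(x, rev(x)[seq_len(min(pad, n))])
  while (length(xp) < target) xp <- c(xp, rev(xp)[seq_len(min(target - length(xp), length(xp)))])
  xp <- xp[seq_len(target)]

  dec <- dwt_db6(xp, levels)
  sigma <- stats::mad(dec$details[[1]])
  thr <- sigma * sqrt(2 * log(target))
  dec$details <- lapply(dec$details, function(d) sign(d) * pmax(abs(d) - thr, 0))
  # approximation band: remove the slowly varying (< 0.6 Hz) component,
  # keep its mean (the DC offset of the waveform)
  fs <- if (inherits(record, "ecg_record")) record$fs else 500
  sub_nyq <- fs / 2^(levels + 1)
  if (0.6 < sub_nyq && length(dec$approx) > 24) {
    lp <- signal::butter(2, 0.6 / sub_nyq, type = "low")
    slow <- as.numeric(signal::filtfilt(lp, dec$approx))
    dec$approx <- dec$approx - (slow - mean(slow))
  }
  y <- idwt_db6(dec)[seq_len(n)]

  if (inherits(record, "ecg_record")) {
    record$samples <- y
    record
  } else y
}

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Classical stage chain adapted to offline analysis: zero-phase 5-15 Hz
#' Butterworth band-pass, five-point derivative, squaring, 150 ms
#' moving-window integration, then adaptive dual thresholds on the
#' integrated signal with a 200 ms refractory period and a search-back
#' pass at half threshold when an expected beat is missed. Each accepted
#' detection is refined to the local maximum of the band-passed signal so
#' the returned index lands on the R-wave sample itself.
#'
#' @param record An `ecg_record` (ideally denoised first).
#' @return Strictly increasing integer sample indices of detected R peaks;
#'   empty (with a warning) when nothing is found.
#' @export
detect_r_peaks <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  fs <- record$fs
  n <- length(x)
  if (n < fs || stats::sd(x) == 0) {
    if (stats::sd(x) > 0) warning("record too short for R detection")
    return(integer(0))
  }

  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- as.numeric(signal::filtfilt(bf, x))
  # five-point derivative (Pan-Tompkins kernel), zero-phase alignment
  dk <- c(1, 2, 0, -2, -1) * (fs / 8)
  xd <- as.numeric(stats::filter(xf, dk, sides = 2))
  xd[is.na(xd)] <- 0
  xs <- xd^2
  wlen <- round(0.15 * fs)
  mwi <- as.numeric(stats::filter(xs, rep(1 / wlen, wlen), sides = 2))
  mwi[is.na(mwi)] <- 0

  # candidate peaks of the integrated signal, with a 200 ms lockout:
  # non-maximum suppression removes the foothill maxima that ride on a
  # QRS main lobe and would otherwise trip the threshold early and push
  # the true peak into the refractory window
  refr <- as.integer(round(0.2 * fs))
  pk <- which(diff(sign(diff(mwi))) < 0) + 1L
  pk <- pk[mwi[pk] > 0]
  if (!length(pk)) {
    warning("no QRS candidates found")
    return(integer(0))
  }
  ord <- pk[order(mwi[pk], decreasing = TRUE)]
  suppressed <- logical(n)
  keep <- logical(length(ord))
  for (i in seq_along(ord)) {
    p <- ord[i]
    if (!suppressed[p]) {
      keep[i] <- TRUE
      suppressed[max(1L, p - refr):min(n, p + refr)] <- TRUE
    }
  }
  pk <- sort(ord[keep])
  init <- mwi[seq_len(min(n, 2 * fs))]
  spki <- 0.25 * max(init)
  npki <- 0.5 * mean(init)
  thr1 <- npki + 0.25 * (spki - npki)

  qrs <- integer(0)
  rr_avg <- fs          # running RR estimate (samples), start at 1 s
  last_checked <- 0L
  for (p in pk) {
    if (length(qrs) && p - qrs[length(qrs)] < refr) next
    if (mwi[p] > thr1) {
      # search-back first: did we skip a beat before this one?
      qrs <- c(qrs, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
    }
    thr1 <- npki + 0.25 * (spki - npki)
    nq <- length(qrs)
    if (nq >= 2) {
      rr <- diff(qrs)
      rr_avg <- mean(utils::tail(rr, 8))
      # search-back: gap longer than 1.66 RR -> accept best peak above thr2
      gap <- qrs[nq] - qrs[nq - 1]
      if (gap > 1.66 * rr_avg) {
        inwin <- pk[pk > qrs[nq - 1] + refr & pk < qrs[nq] - refr]
        if (length(inwin)) {
          best <- inwin[which.max(mwi[inwin])]
          if (mwi[best] > 0.5 * thr1) {
            qrs <- sort(c(qrs, best))
            spki <- 0.25 * mwi[best] + 0.75 * spki
          }
        }
      }
    }
  }
  if (!length(qrs)) {
    warning("no QRS complexes above threshold")
    return(integer(0))
  }

  # refine each detection to the R sample: local max of the band-passed
  # signal (zero phase, so the QRS stays centred), then of the raw record
  half <- as.integer(round(0.1 * fs))
  r <- vapply(as.integer(qrs), function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    p2 <- lo - 1L + which.max(xf[lo:hi])
    lo2 <- max(1L, p2 - 10L); hi2 <- min(n, p2 + 10L)
    lo2 - 1L + which.max(x[lo2:hi2])
  }, 1L)
  r <- sort(unique(r))
  # enforce refractory after refinement
  if (length(r) > 1) {
    keep <- c(TRUE, diff(r) >= refr)
    r <- r[keep]
  }
  r
}

#' Cut 120-sample post-R beat windows
#'
#' One window per R index, holding the 120 samples immediately after the
#' R peak (exclusive of the R sample itself), i.e. `samples[(r+1):(r+120)]`
#' — the region where a J wave lives. Windows that would run past the end
#' of the record are dropped and the drop count reported.
#'
#' @param record An `ecg_record`.
#' @param r_indices R-peak sample indices (1-based).
#' @param width Window length in samples (120).
#' @param include_r Start the window at the R sample itself instead of the
#'   next sample.
#' @return A `beat_windows` object: `windows` (matrix, one row per beat)
#'   and `meta` (data.frame: record_id, r_index, label).
#' @export
segment_beats <- function(record, r_indices, width = 120L,
                          include_r = FALSE) {
  stopifnot(inherits(record, "ecg_record"))
  n <- length(record$samples)
  r_indices <- as.integer(r_indices)
  stopifnot(!is.unsorted(r_indices, strictly = TRUE) || length(r_indices) <= 1)
  off <- if (include_r) 0L else 1L
  keep <- r_indices + off + width - 1L <= n & r_indices >= 1L
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("segment_beats: dropped %d window(s) at the record tail", dropped))
  r_keep <- r_indices[keep]
  win <- t(vapply(r_keep,
                  function(r) record$samples[(r + off):(r + off + width - 1L)],
                  numeric(width)))
  if (length(r_keep) == 0) win <- matrix(numeric(0), 0, width)
  structure(list(windows = win,
                 meta = data.frame(record_id = rep(record$record_id,
                                                   length(r_keep)),
                                   r_index = r_keep,
                                   label = rep(record$label, length(r_keep)),
                                   stringsAsFactors = FALSE)),
            class = "beat_windows")
}

#' @export
print.beat_windows <- function(x, ...) {
  cat(sprintf("beat_windows: %d windows x %d samples from %d record(s)\n",
              nrow(x$windows), ncol(x$windows),
              length(unique(x$meta$record_id))))
  invisible(x)
}

# Row-bind beat_windows objects.
#' @export
rbind.beat_windows <- function(...) {
  parts <- list(...)
  structure(list(windows = do.call(rbind, lapply(parts, `[[`, "windows")),
                 meta = do.call(rbind, lapply(parts, `[[`, "meta"))),
            class = "beat_windows")
}

#' Preprocess one record end to end
#'
#' Denoise, detect R peaks, segment. The spec order matters: detection runs
#' on the denoised record.
#'
#' @param record An `ecg_record`.
#' @param denoise_first Set `FALSE` to skip the wavelet denoiser (debug).
#' @param width Window length in samples.
#' @return A `beat_windows` object.
#' @export
preprocess_record <- function(record, denoise_first = TRUE, width = 120L) {
  rec <- if (denoise_first) denoise(record) else record
  r <- detect_r_peaks(rec)
  segment_beats(rec, r, width = width)
}
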