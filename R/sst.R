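#' Continuous wavelet transform of a short signal window
#'
#' FFT-based CWT with the L2-normalised convention
#' \eqn{W_f(a,b) = a^{-1/2} \int f(t)\, \psi^*((t-b)/a)\, dt},
#' evaluated on a log-spaced scale grid (`n_voices` scales per octave over
#' the wavelet's `freq_range`). Because post-R beat windows are only 0.24 s
#' long, the window is symmetrically extended before the transform and the
#' plane is cropped back afterwards, which keeps boundary smearing out of
#' the retained coefficients.
#'
#' @param window Numeric vector (>= 32 finite samples), typically a
#'   120-sample post-R beat segment in mV.
#' @param fs Sampling rate in Hz.
#' @param wavelet A [morlet_spec()].
#' @param pad Symmetric extension before the FFT (recommended; turn off
#'   only for periodic test signals).
#' @return A `cwt_plane`: complex coefficient matrix (scales x times),
#'   the scale grid, its frequency map (Hz), the time axis (s) and fs.
#' @export
cwt <- function(window, fs, wavelet = morlet_spec(), pad = TRUE) {
  if (length(window) < 32)
    stop("window must hold at least 32 samples")
  if (!all(is.finite(window)))
    stop("window must be finite")
  n <- length(window)
  if (pad) {
    x <- c(rev(window), window, rev(window))
    keep <- (n + 1):(2 * n)
  } else {
    x <- window
    keep <- seq_len(n)
  }
  m <- length(x)
  dt <- 1 / fs

  sg <- wavelet_scales(wavelet)
  scales <- sg$scales
  if (max(sg$freqs) > fs / 2 + 1e-9)
    stop("wavelet freq_range exceeds the Nyquist frequency")

  xi <- 2 * pi * (0:(m - 1)) / (m * dt)       # only xi in (0, pi/dt] used
  xi[xi > pi / dt] <- 0                       # negative-frequency half: wavelet is analytic
  xhat <- stats::fft(x)

  # psi_hat(a * xi) for every scale: m x n_scales matrix, one inverse FFT
  # per column via mvfft.
  p <- morlet_psi_hat(outer(xi, scales), wavelet)
  w <- stats::mvfft(xhat * p, inverse = TRUE) / m
  w <- t(w) * sqrt(scales)                    # n_scales x m
  w <- w[, keep, drop = FALSE]

  structure(list(coefficients = w,
                 scales = scales,
                 freqs = sg$freqs,
                 times = (seq_len(n) - 1) * dt,
                 fs = fs,
                 wavelet = wavelet),
            class = "cwt_plane")
}

#' Instantaneous-frequency plane of a CWT
#'
#' Phase-derivative estimate \eqn{w_f(a,b) = \mathrm{Im}[\partial_b W_f(a,b)
#' / W_f(a,b)]} (rad/s), with the time derivative taken as a centred
#' second-order finite difference (one-sided at the window ends). Cells
#' whose coefficient magnitude falls below `gamma`, or whose estimate is
#' non-positive or non-finite, are masked and take no part in reassignment.
#'
#' @param plane A `cwt_plane`.
#' @param gamma Magnitude threshold; default `1e-4 * max|W|`.
#' @return An `if_plane`: the `w_f` matrix (rad/s), a logical `mask`
#'   (TRUE = undefined) and the threshold used.
#' @export
instantaneous_frequency <- function(plane, gamma = NULL) {
  stopifnot(inherits(plane, "cwt_plane"))
  w <- plane$coefficients
  nt <- ncol(w)
  if (is.null(gamma)) gamma <- 1e-4 * max(Mod(w))
  stopifnot(gamma > 0)
  dt <- 1 / plane$fs

  dw <- w
  if (nt >= 3) {
    dw[, 2:(nt - 1)] <- (w[, 3:nt] - w[, 1:(nt - 2)]) / (2 * dt)
    dw[, 1] <- (w[, 2] - w[, 1]) / dt
    dw[, nt] <- (w[, nt] - w[, nt - 1]) / dt
  } else {
    dw[] <- 0
  }

  wf <- Im(dw / w)
  mask <- Mod(w) < gamma | !is.finite(wf) | wf <= 0
  wf[mask] <- NA_real_

  structure(list(w_f = wf, mask = mask, gamma = gamma),
            class = "if_plane")
}

#' Synchrosqueeze a CWT plane onto a uniform frequency grid
#'
#' Reassigns wavelet coefficients from the time-scale plane to the
#' time-frequency plane: for every time b, each unmasked cell (a_k, b) sends
#' \eqn{W_f(a_k,b)\, a_k^{-3/2}\, \Delta a_k / \Delta w} into the frequency
#' bin nearest its instantaneous-frequency estimate (ties to the lower
#' bin). The result is a far sharper ridge structure than the CWT itself,
#' and its band sums support exact narrow-band inversion.
#'
#' @param plane A `cwt_plane`.
#' @param ifreq The matching `if_plane`.
#' @param freq_bins Uniform bin-centre grid in Hz; default spans the
#'   wavelet's `freq_range` with as many bins as there are scales.
#' @return An `sst_plane`: complex matrix `T_f` (bins x times), the bin
#'   grid, bin width `delta_w`, time axis and a reference to `plane`.
#' @export
synchrosqueeze <- function(plane, ifreq, freq_bins = NULL) {
  stopifnot(inherits(plane, "cwt_plane"), inherits(ifreq, "if_plane"))
  w <- plane$coefficients
  stopifnot(all(dim(ifreq$w_f) == dim(w)))
  if (is.null(freq_bins)) {
    fr <- plane$wavelet$freq_range
    freq_bins <- seq(fr[1], fr[2], length.out = length(plane$scales))
  }
  n_bins <- length(freq_bins)
  dw_bin <- freq_bins[2] - freq_bins[1]
  stopifnot(n_bins >= 2,
            max(abs(diff(freq_bins) - dw_bin)) < 1e-9 * dw_bin)

  scales <- plane$scales
  da <- diff(scales)
  da <- c(da[1], da)
  weight <- scales^(-3 / 2) * da / dw_bin

  nt <- ncol(w)
  f_if <- ifreq$w_f / (2 * pi)                # Hz
  # nearest bin, ties to the lower bin
  l <- ceiling((f_if - freq_bins[1]) / dw_bin - 0.5) + 1
  ok <- !ifreq$mask & !is.na(l) & l >= 1 & l <= n_bins

  tf <- matrix(0 + 0i, n_bins, nt)
  if (any(ok)) {
    tcol <- col(w)[ok]
    idx <- l[ok] + (tcol - 1) * n_bins
    val <- w[ok] * weight[row(w)[ok]]
    ui <- sort(unique(idx))
    g <- findInterval(idx, ui)
    re <- rowsum(Re(val), g, reorder = TRUE)
    im <- rowsum(Im(val), g, reorder = TRUE)
    tf[ui] <- complex(real = re[, 1], imaginary = im[, 1])
  }

  structure(list(T_f = tf,
                 freq_bins = freq_bins,
                 delta_w = dw_bin,
                 times = plane$times,
                 fs = plane$fs,
                 source = plane),
            class = "sst_plane")
}

# Maximum-energy path through an energy matrix (bins x times) by dynamic
# programming: maximise sum_t E[b_t, t] - lambda * (b_t - b_{t-1})^2 with
# jumps limited to +/- max_jump bins per step. Energy is pre-normalised by
# its maximum so lambda is scale-free. Returns bin indices per time.
ridge_dp <- function(e, lambda, max_jump) {
  if (max(e) > 0) e <- e / max(e)
  .ridge_dp_cpp(e, lambda, as.integer(max_jump))
}

#' Extract ridge (centre-frequency) tracks from an SST plane
#'
#' Iterative peeling: the maximum-energy ridge is found by dynamic
#' programming on \eqn{|T_f|^2} with a smoothness penalty
#' \eqn{\lambda (\Delta \mathrm{bin})^2} per step, a band of
#' `bandwidth` Hz around it is zeroed, and the search repeats K times.
#' Tracks come back ordered by captured band energy (descending), so track
#' 1 is the dominant component.
#'
#' @param sst An `sst_plane`.
#' @param K Number of tracks (modes) to extract.
#' @param bandwidth Half-width (Hz) of the peeled band; default
#'   `4 * delta_w`.
#' @param lambda Smoothness penalty on squared bin jumps (energy is
#'   normalised to max 1, so lambda is dimensionless).
#' @param max_jump Largest allowed bin jump per time step.
#' @return A `ridge_set`: `freqs` (K x times, Hz), `bins` (K x times),
#'   `energy` (captured band energy per track), `bandwidth`.
#' @export
extract_ridges <- function(sst, K = 5, bandwidth = NULL, lambda = 0.01,
                           max_jump = 10L) {
  stopifnot(inherits(sst, "sst_plane"), K >= 1)
  if (is.null(bandwidth)) bandwidth <- 4 * sst$delta_w
  e <- Mod(sst$T_f)^2
  nb <- nrow(e)
  nt <- ncol(e)
  n_band <- max(1L, round(bandwidth / sst$delta_w))

  bins <- matrix(0L, K, nt)
  energy <- numeric(K)
  work <- e
  for (k in seq_len(K)) {
    if (max(work) <= 0) {
      # residual is empty: degenerate flat track at the lowest bin
      bins[k, ] <- 1L
      energy[k] <- 0
      next
    }
    path <- ridge_dp(work, lambda, max_jump)
    bins[k, ] <- path
    cap <- 0
    for (t in seq_len(nt)) {
      lo <- max(1L, path[t] - n_band)
      hi <- min(nb, path[t] + n_band)
      cap <- cap + sum(work[lo:hi, t])
      work[lo:hi, t] <- 0
    }
    energy[k] <- cap
  }
  ord <- order(energy, decreasing = TRUE)
  structure(list(freqs = matrix(sst$freq_bins[bins[ord, , drop = FALSE]], K, nt),
                 bins = bins[ord, , drop = FALSE],
                 energy = energy[ord],
                 bandwidth = bandwidth),
            class = "ridge_set")
}

#' Reconstruct narrow-band modes by the inverse SST
#'
#' Inverts the synchrosqueezed transform over a narrow band around each
#' ridge track: mode k at time t is
#' \eqn{f_k(t) = 2\,\mathrm{Re}[R_\psi^{-1} \sum_{|w_l - \phi'_k(t)| \le
#' \mathrm{bw}} T_f(w_l, t)\, \Delta w]}. Each frequency bin feeds at most
#' one mode per time; where bands overlap the nearest ridge wins.
#'
#' @param sst An `sst_plane`.
#' @param ridges A `ridge_set` extracted from the same plane.
#' @param bandwidth Reconstruction half-width in Hz; defaults to the
#'   ridge set's.
#' @param r_psi Admissibility constant; computed from the source wavelet
#'   when missing.
#' @return A `mode_set`: `modes` (K x times, signal units), `ridge_freqs`
#'   (K x times, Hz), `bandwidth`, `r_psi`.
#' @export
reconstruct_modes <- function(sst, ridges, bandwidth = NULL, r_psi = NULL) {
  stopifnot(inherits(sst, "sst_plane"), inherits(ridges, "ridge_set"))
  if (is.null(bandwidth)) bandwidth <- ridges$bandwidth
  if (is.null(r_psi)) r_psi <- compute_r_psi(sst$source$wavelet)
  K <- nrow(ridges$freqs)
  nt <- ncol(sst$T_f)
  nb <- nrow(sst$T_f)

  if (K > 1) {
    dist_k <- vector("list", K)
    for (k in seq_len(K))
      dist_k[[k]] <- abs(outer(sst$freq_bins, rep(1, nt)) -
                           matrix(ridges$freqs[k, ], nb, nt, byrow = TRUE))
    dmin <- dist_k[[1]]
    amin <- matrix(1L, nb, nt)
    for (k in 2:K) {
      closer <- dist_k[[k]] < dmin
      dmin[closer] <- dist_k[[k]][closer]
      amin[closer] <- k
    }
  } else {
    dmin <- abs(outer(sst$freq_bins, rep(1, nt)) -
                  matrix(ridges$freqs[1, ], nb, nt, byrow = TRUE))
    amin <- matrix(1L, nb, nt)
  }

  modes <- matrix(0, K, nt)
  for (k in seq_len(K)) {
    sel <- amin == k & dmin <= bandwidth
    modes[k, ] <- (2 / r_psi) * sst$delta_w *
      colSums(Re(sst$T_f) * sel)
  }

  structure(list(modes = modes,
                 ridge_freqs = ridges$freqs,
                 bandwidth = bandwidth,
                 r_psi = r_psi),
            class = "mode_set")
}

#' Full SST decomposition of one beat window
#'
#' Convenience chain: CWT, instantaneous frequency, synchrosqueezing,
#' ridge extraction and inverse-SST reconstruction of K modes.
#'
#' @param window Numeric signal window (mV).
#' @param fs Sampling rate (Hz).
#' @param wavelet A [morlet_spec()].
#' @param K Number of modes.
#' @param gamma_rel Relative magnitude threshold for the IF mask.
#' @param bandwidth Reconstruction half-width (Hz); default `4 * delta_w`.
#' @param lambda,max_jump Ridge-tracking controls, see [extract_ridges()].
#' @param mode_strategy `"ridge"` (default) tracks K maximum-energy ridges;
#'   `"fixed_bands"` splits the frequency axis into K equal bands and
#'   treats each band centre as a flat track.
#' @return List with elements `cwt`, `ifreq`, `sst`, `ridges`, `modes`.
#' @export
sst_decompose <- function(window, fs, wavelet = morlet_spec(), K = 5,
                          gamma_rel = 1e-4, bandwidth = NULL,
                          lambda = 0.01, max_jump = 10L,
                          mode_strategy = c("ridge", "fixed_bands")) {
  mode_strategy <- match.arg(mode_strategy)
  cw <- cwt(window, fs, wavelet)
  mx <- max(Mod(cw$coefficients))
  ifr <- instantaneous_frequency(cw, gamma = if (mx > 0) gamma_rel * mx else 1)
  ss <- synchrosqueeze(cw, ifr)
  if (mode_strategy == "ridge") {
    rg <- extract_ridges(ss, K = K, bandwidth = bandwidth, lambda = lambda,
                         max_jump = max_jump)
  } else {
    rg <- fixed_band_ridges(ss, K = K)
  }
  md <- reconstruct_modes(ss, rg)
  list(cwt = cw, ifreq = ifr, sst = ss, ridges = rg, modes = md)
}

# K flat tracks at the centres of equal-width bands spanning the bin grid;
# the reconstruction bandwidth is the band half-width, so the K modes tile
# the whole frequency axis.
fixed_band_ridges <- function(sst, K) {
  fr <- range(sst$freq_bins)
  edges <- seq(fr[1], fr[2], length.out = K + 1)
  centres <- (edges[-1] + edges[-(K + 1)]) / 2
  nt <- ncol(sst$T_f)
  e <- Mod(sst$T_f)^2
  band_of <- findInterval(sst$freq_bins, edges, rightmost.closed = TRUE)
  energy <- vapply(seq_len(K), function(k) sum(e[band_of == k, ]), 1)
  freqs <- matrix(centres, K, nt)
  bins <- matrix(vapply(centres, function(f)
    which.min(abs(sst$freq_bins - f)), 1L), K, nt)
  structure(list(freqs = freqs, bins = bins, energy = energy,
                 bandwidth = (edges[2] - edges[1]) / 2),
            class = "ridge_set")
}
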