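fs <- 500
tt <- (0:249) / fs

test_that("the CWT matches direct quadrature of its defining integral", {
  wv <- morlet_spec()
  x <- cos(2 * pi * 10 * tt)
  cw <- cwt(x, fs, wv)
  # the transform sees the symmetric extension; so must the oracle
  x_ext <- c(rev(x), x, rev(x))
  n <- length(x)
  b <- 0.25
  bcol <- which.min(abs(cw$times - b))
  b_ext <- (n + bcol - 1) / fs
  for (f_probe in c(6, 8, 10, 14, 20)) {
    a <- wv$center_frequency / f_probe
    k <- which.min(abs(cw$scales - a))
    oracle <- cwt_quadrature_oracle(x_ext, fs, wv, cw$scales[k], b_ext)
    expect_lt(Mod(cw$coefficients[k, bcol] - oracle) / Mod(oracle), 0.02)
  }
})

test_that("CWT basics: zero input, linearity, ridge position", {
  wv <- morlet_spec()
  z <- cwt(rep(0, 250), fs, wv)
  expect_equal(max(Mod(z$coefficients)), 0)

  x <- cos(2 * pi * 10 * tt)
  y <- sin(2 * pi * 25 * tt)
  cxy <- cwt(x + y, fs, wv)
  cx <- cwt(x, fs, wv)
  cy <- cwt(y, fs, wv)
  expect_equal(cxy$coefficients, cx$coefficients + cy$coefficients,
               tolerance = 1e-12)

  # per-scale max magnitude peaks at the scale mapping to 10 Hz
  mid <- 100:150
  prof <- apply(Mod(cx$coefficients[, mid]), 1, max)
  expect_equal(cx$freqs[which.max(prof)], 10, tolerance = 0.05)
  expect_true(all(diff(cx$scales) > 0))
})

test_that("instantaneous frequency recovers tones and chirps", {
  wv <- morlet_spec()
  # 250 samples of 10 Hz at 500 Hz are exactly periodic, so the unpadded
  # transform has the pure phase e^{i w b} at every scale and the
  # log-derivative must recover the tone everywhere it is defined
  x <- cos(2 * pi * 10 * tt)
  cw <- cwt(x, fs, wv, pad = FALSE)
  ifr <- instantaneous_frequency(cw)
  est <- ifr$w_f / (2 * pi)
  expect_true(all(abs(est[!is.na(est)] - 10) < 0.5))

  # gamma above max|W| masks everything
  full <- instantaneous_frequency(cw, gamma = 2 * max(Mod(cw$coefficients)))
  expect_true(all(full$mask))

  # linear chirp 5 + 20 t Hz: ridge-line estimates track the analytic IF
  chirp <- cos(2 * pi * (5 * tt + 10 * tt^2))
  cwc <- cwt(chirp, fs, wv)
  ifc <- instantaneous_frequency(cwc)
  for (bcol in seq(60, 190, by = 10)) {
    f_true <- 5 + 20 * tt[bcol]
    k <- which.min(abs(cwc$freqs - f_true))
    expect_lt(abs(ifc$w_f[k, bcol] / (2 * pi) - f_true), 1)
  }
})

test_that("synchrosqueezing concentrates tone energy far beyond the CWT", {
  wv <- morlet_spec()
  x <- cos(2 * pi * 10 * tt)
  cw <- cwt(x, fs, wv)
  ifr <- instantaneous_frequency(cw)
  ss <- synchrosqueeze(cw, ifr)

  e_sst <- Mod(ss$T_f)^2
  conc_sst <- sum(e_sst[abs(ss$freq_bins - 10) <= 1, ]) / sum(e_sst)
  e_cwt <- Mod(cw$coefficients)^2
  conc_cwt <- sum(e_cwt[abs(cw$freqs - 10) <= 1, ]) / sum(e_cwt)
  expect_gte(conc_sst, 0.9)
  expect_gt(conc_sst, conc_cwt)

  # all-masked IF plane gives an all-zero SST plane
  masked <- instantaneous_frequency(cw, gamma = 2 * max(Mod(cw$coefficients)))
  ss0 <- synchrosqueeze(cw, masked)
  expect_equal(max(Mod(ss0$T_f)), 0)

  # two tones: disjoint ridges each holding a large energy share
  y <- cos(2 * pi * 5 * tt) + cos(2 * pi * 20 * tt)
  d <- sst_decompose(y, fs, wv, K = 2)
  e2 <- Mod(d$sst$T_f)^2
  for (f0 in c(5, 20)) {
    expect_gte(sum(e2[abs(d$sst$freq_bins - f0) <= 1, ]) / sum(e2), 0.4)
  }
})

test_that("ridge extraction recovers generating frequencies", {
  wv <- morlet_spec()
  y <- cos(2 * pi * 5 * tt) + 0.5 * cos(2 * pi * 20 * tt)
  d <- sst_decompose(y, fs, wv, K = 2)
  dw <- d$sst$delta_w
  interior <- 40:210
  # tracks ordered by captured energy: the unit-amplitude 5 Hz tone first
  expect_true(all(abs(d$ridges$freqs[1, interior] - 5) <= dw))
  expect_true(all(abs(d$ridges$freqs[2, interior] - 20) <= dw))

  single <- sst_decompose(cos(2 * pi * 10 * tt), fs, wv, K = 1)
  expect_true(all(abs(single$ridges$freqs[1, interior] - 10) <= dw))

  zero <- sst_decompose(rep(0, 250), fs, wv, K = 1)
  expect_equal(zero$ridges$energy, 0)
})

test_that("the admissibility constant converges and scales linearly", {
  wv <- morlet_spec()
  r1 <- compute_r_psi(wv, n_grid = 2048)
  r2 <- compute_r_psi(wv, n_grid = 4096)
  expect_gt(r2, 0)
  expect_lt(abs(r1 - r2) / r2, 1e-3)
  # independent adaptive-quadrature oracle
  omega_c <- 2 * pi * wv$center_frequency
  sigma_t <- wv$omega0 / omega_c
  ref <- stats::integrate(function(z) exp(-0.5 * (sigma_t * (z - omega_c))^2) / z,
                          lower = 1e-6, upper = Inf)$value
  expect_equal(r2, ref, tolerance = 1e-3)
})

test_that("inverse SST reconstructs modes with calibrated amplitude", {
  wv <- morlet_spec()
  y <- cos(2 * pi * 5 * tt) + 0.5 * cos(2 * pi * 20 * tt)
  d <- sst_decompose(y, fs, wv, K = 2)
  central <- 26:225   # central 80%
  rel_rmse <- function(est, ref)
    sqrt(mean((est - ref)^2)) / sqrt(mean(ref^2))
  expect_lt(rel_rmse(d$modes$modes[1, central],
                     cos(2 * pi * 5 * tt[central])), 0.1)
  expect_lt(rel_rmse(d$modes$modes[2, central],
                     0.5 * cos(2 * pi * 20 * tt[central])), 0.1)

  # K modes of a single tone sum back to the tone
  one <- sst_decompose(cos(2 * pi * 10 * tt), fs, wv, K = 5)
  expect_lt(rel_rmse(colSums(one$modes$modes)[central],
                     cos(2 * pi * 10 * tt[central])), 0.1)

  # zero plane reconstructs to zero
  zero <- sst_decompose(rep(0, 250), fs, wv, K = 2)
  expect_equal(max(abs(zero$modes$modes)), 0)
})

test_that("ridge recovery is robust to the wavelet centre frequency", {
  y <- cos(2 * pi * 5 * tt) + 0.5 * cos(2 * pi * 20 * tt)
  recovered <- sapply(c(25, 35, 45), function(fc) {
    d <- sst_decompose(y, fs, morlet_spec(center_frequency = fc), K = 2)
    dw <- d$sst$delta_w
    sort(rowMeans(d$ridges$freqs[, 40:210]))
  })
  dw <- (250 - 0.5) / 287
  expect_true(all(abs(recovered[1, ] - 5) <= dw))
  expect_true(all(abs(recovered[2, ] - 20) <= dw))
})

test_that("fixed-band decomposition tiles the axis and captures tones", {
  y <- cos(2 * pi * 5 * tt) + 0.5 * cos(2 * pi * 20 * tt)
  d <- sst_decompose(y, fs, K = 5, mode_strategy = "fixed_bands")
  # 5 equal bands over 0.5-250 Hz: both tones fall in band 1 (0.5-50.4)
  expect_equal(nrow(d$modes$modes), 5)
  expect_gt(d$ridges$energy[1], sum(d$ridges$energy[-1]))
  central <- 26:225
  rel_rmse <- function(est, ref) sqrt(mean((est - ref)^2)) / sqrt(mean(ref^2))
  expect_lt(rel_rmse(d$modes$modes[1, central], y[central]), 0.1)
  expect_lt(max(abs(d$modes$modes[5, central])), 0.05)
})

test_that("the SST chain is deterministic", {
  y <- cos(2 * pi * 7 * tt) + 0.2 * sin(2 * pi * 31 * tt)
  d1 <- sst_decompose(y, fs, K = 3)
  d2 <- sst_decompose(y, fs, K = 3)
  expect_identical(d1$sst$T_f, d2$sst$T_f)
  expect_identical(d1$modes$modes, d2$modes$modes)
})
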