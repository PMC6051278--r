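# Independent brute-force oracles used to pin down the fast implementations.
# Each is written as plain nested loops straight from the defining formulas
# and must stay independent of the package internals it checks.

# Pincus approximate entropy by exhaustive template counting.
apen_oracle <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    cs <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0L
      for (j in seq_len(nt)) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt <- cnt + 1L
      }
      cs[i] <- cnt / nt
    }
    mean(log(cs))
  }
  phi(m) - phi(m + 1)
}

# Richman-Moorman sample entropy by exhaustive pair counting.
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  a <- 0L
  b <- 0L
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        b <- b + 1L
        dm1 <- max(abs(x[i:(i + m)] - x[j:(j + m)]))
        if (dm1 <= r) a <- a + 1L
      }
    }
  }
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

# Direct numerical quadrature of the CWT integral
# W(a,b) = a^(-1/2) Int f(t) psi*((t-b)/a) dt for the analytic Morlet,
# with psi recovered from its spectrum by inverse-FT quadrature.
cwt_quadrature_oracle <- function(x, fs, spec, a, b) {
  omega_c <- 2 * pi * spec$center_frequency
  sigma_t <- spec$omega0 / omega_c
  # time-domain analytic Morlet: (1/2pi) Int psi_hat(xi) e^{i xi t} dxi
  psi <- function(t) {
    xi <- seq(max(omega_c - 8 / sigma_t, 1e-6), omega_c + 8 / sigma_t,
              length.out = 4001)
    ph <- exp(-0.5 * (sigma_t * (xi - omega_c))^2)
    vapply(t, function(tt)
      sum(ph * exp(1i * xi * tt)) * (xi[2] - xi[1]) / (2 * pi),
      complex(1))
  }
  tgrid <- (seq_along(x) - 1) / fs
  sum(x * Conj(psi((tgrid - b) / a))) / (fs * sqrt(a))
}

# Eq-style confusion-matrix metrics, written independently.
metrics_oracle <- function(tp, fn, tn, fp) {
  list(Se = tp / (tp + fn) * 100,
       Sp = tn / (tn + fp) * 100,
       Acc = (tp + tn) / (tp + tn + fp + fn) * 100,
       MCC = (tp * tn - fp * fn) /
         sqrt((tp + fp) * (tn + fn) * (tp + fn) * (tn + fp)))
}

shannon_bits <- function(p) {
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Scored match between true and detected R indices at a sample tolerance:
# greedy one-to-one pairing, returns sensitivity and positive predictivity.
score_detection <- function(true_idx, det_idx, tol) {
  used <- logical(length(det_idx))
  hit <- 0L
  for (r in true_idx) {
    d <- abs(det_idx - r)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      hit <- hit + 1L
      used[j] <- TRUE
    }
  }
  list(se = hit / length(true_idx), ppv = sum(used) / length(det_idx))
}
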