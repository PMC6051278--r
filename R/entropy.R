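#' Renyi entropy of a discrete distribution
#'
#' Order-alpha generalisation of Shannon entropy,
#' \eqn{R_\alpha(p) = (1-\alpha)^{-1} \log_2 (\sum_i p_i^\alpha / \sum_i p_i)}
#' after normalisation to unit mass. Order 3 is the operating point for
#' time-frequency complexity: it is the most stable of the integer orders
#' and down-weights the near-zero background of an SST plane.
#'
#' @param p Nonnegative weights (need not sum to 1).
#' @param alpha Entropy order, > 0 and != 1.
#' @return Entropy in bits.
#' @export
renyi_entropy <- function(p, alpha = 3) {
  stopifnot(alpha > 0, alpha != 1)
  if (any(p < 0) || any(!is.finite(p)))
    stop("p must be finite and nonnegative")
  s <- sum(p)
  if (s <= 0) stop("undefined entropy: distribution has zero mass")
  pn <- p / s
  (1 / (1 - alpha)) * log2(sum(pn^alpha))
}

# Chebyshev-distance template match counts shared by ApEn/SampEn.
# Returns the n_templ x n_templ logical match matrix for embedding
# dimension m over x[1..n_templ + m - 1].
template_matches <- function(x, m, r, n_templ) {
  d <- abs(outer(x[seq_len(n_templ)], x[seq_len(n_templ)], "-"))
  if (m > 1) {
    for (k in seq_len(m - 1)) {
      xs <- x[seq_len(n_templ) + k]
      d <- pmax(d, abs(outer(xs, xs, "-")))
    }
  }
  d <= r
}

resolve_r <- function(x, r, r_factor) {
  if (is.null(r)) r <- r_factor * stats::sd(x)
  # floor keeps a constant series well-defined instead of erroring on r = 0
  max(r, .Machine$double.eps * max(abs(x), 1))
}

#' Approximate entropy (ApEn)
#'
#' Regularity statistic of a time series in the Pincus formulation:
#' \eqn{\mathrm{ApEn} = \Phi^m(r) - \Phi^{m+1}(r)} with
#' \eqn{\Phi^m = (N-m+1)^{-1} \sum_i \ln C_i^m(r)}, where \eqn{C_i^m} is the
#' fraction of length-m templates within Chebyshev distance r of template i
#' (self-matches included). Larger values mean a more complex, less
#' predictable series.
#'
#' @param x Numeric series, length N > m + 1.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance radius in the units of `x`; when `NULL` it is
#'   `r_factor` times the standard deviation of `x` (the SDNN convention),
#'   floored at machine epsilon times `max(abs(x))` so constant series stay
#'   defined.
#' @param r_factor Multiplier for the SD-based default radius (0.2).
#' @return ApEn in nats.
#' @export
approximate_entropy <- function(x, m = 2, r = NULL, r_factor = 0.2) {
  n <- length(x)
  stopifnot(m >= 1, n > m + 1)
  r <- resolve_r(x, r, r_factor)
  phi <- function(mm) {
    nt <- n - mm + 1
    mean(log(rowMeans(template_matches(x, mm, r, nt))))
  }
  phi(m) - phi(m + 1)
}

#' Sample entropy (SampEn)
#'
#' Richman-Moorman regularity statistic \eqn{-\ln(A/B)}: B counts pairs of
#' length-m templates within Chebyshev distance r, A the pairs still
#' matching at length m + 1; self-matches are excluded. Unlike ApEn it is
#' unbiased by self-counting, at the price of being undefined when no pair
#' matches.
#'
#' @inheritParams approximate_entropy
#' @return SampEn in nats, or `NA` (with attribute `undefined = TRUE`)
#'   when A or B is zero.
#' @export
sample_entropy <- function(x, m = 2, r = NULL, r_factor = 0.2) {
  n <- length(x)
  stopifnot(m >= 1, n > m + 1)
  r <- resolve_r(x, r, r_factor)
  nt <- n - m                     # templates for which both lengths exist
  mm <- template_matches(x, m, r, nt)
  ma <- template_matches(x, m + 1, r, nt)
  b <- sum(mm) - nt               # drop self-matches
  a <- sum(ma) - nt
  if (a <= 0 || b <= 0)
    return(structure(NA_real_, undefined = TRUE))
  -log(a / b)
}
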