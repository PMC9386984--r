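#' Beta-binomial log probability mass
#'
#' Log pmf of a count under the marginalised noise model: the per-locus
#' read probability theta is Beta(s c m, s (1 - c m)) and the count is
#' Binomial(n, theta); integrating theta out analytically gives a
#' beta-binomial with mean n c m. `c` is the relative copy number of the
#' locus, `m` its bias (expected count proportion in a diploid sample) and
#' `s` the inverse dispersion: as `s` grows a plain binomial is recovered.
#'
#' @param y count(s), 0 <= y <= n.
#' @param n total aligned reads of the sample (scalar).
#' @param c relative copy number, recycled against `y`.
#' @param m locus bias, recycled against `y`.
#' @param s inverse dispersion (> 0, scalar).
#' @return numeric vector of log probabilities.
#' @export
#' @examples
#' sum(exp(betabinom_logpmf(0:50, 50, 1, 0.01, 100))) # == 1
betabinom_logpmf <- function(y, n, c, m, s) {
  if (length(n) != 1L || length(s) != 1L)
    stop("n and s must be scalars")
  if (any(y < 0) || any(y > n)) stop("counts must lie in [0, n]")
  cm <- c * m
  if (any(cm <= 0 | cm >= 1))
    stop("invalid mean constraint: c*m must lie strictly in (0, 1)")
  L <- max(length(y), length(cm))
  bb_logpmf_cpp(as.numeric(rep_len(y, L)), as.numeric(n),
                as.numeric(rep_len(cm, L)), as.numeric(s))
}

#' Expected count at a locus
#'
#' The beta-binomial mean `n * c * m`: the relative copy number scales the
#' expected proportion of reads aligning to a locus.
#'
#' @inheritParams betabinom_logpmf
#' @return numeric vector of expected counts.
#' @export
expected_count <- function(n, c, m) n * c * m

#' Count variance as a quadratic function of the mean
#'
#' Marginal variance of a beta-binomial count written in terms of its mean
#' `mu = n c m`:
#' `(1 + (n-1)/(s+1)) * (mu - mu^2/n)`,
#' i.e. the binomial variance `mu (1 - mu/n)` inflated by the
#' overdispersion factor `(s+n)/(s+1)`. In the limit `s -> Inf` the plain
#' binomial variance is recovered; for finite `s` the count is always
#' overdispersed.
#'
#' @param n total reads.
#' @param s inverse dispersion (> 0).
#' @param mu expected count, 0 <= mu <= n.
#' @return numeric variance.
#' @export
count_variance <- function(n, s, mu) {
  if (any(s <= 0)) stop("s must be positive")
  if (any(mu < 0 | mu > n)) stop("mu must lie in [0, n]")
  (1 + (n - 1) / (s + 1)) * (mu - mu^2 / n)
}

#' Validate the beta-binomial mean constraint
#'
#' The Beta shape parameters `s c m` and `s (1 - c m)` must both be
#' positive, i.e. `0 < c_l m_l < 1` at every locus.
#'
#' @param c vector of relative copy numbers.
#' @param m vector of locus biases (same length).
#' @return `TRUE` iff the constraint holds everywhere.
#' @export
validate_mean_constraint <- function(c, m) {
  if (length(c) != length(m)) stop("c and m must have equal length")
  cm <- c * m
  all(cm > 0 & cm < 1)
}
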