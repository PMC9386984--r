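#' Simulate a locus bias vector
#'
#' Draws per-locus amplification bias and normalises to the simplex. The
#' default log-normal generator reproduces the heavy right tail of real
#' amplicon bias (orders-of-magnitude differences in per-locus read
#' counts); `shape = "beta"` draws independent Beta variates as in the
#' control-panel prior instead.
#'
#' @param L number of loci (>= 2).
#' @param shape `"lognormal"` (default) or `"beta"`.
#' @param sdlog log-scale SD of the log-normal generator (default 1).
#' @param beta_shape two Beta shape parameters for `shape = "beta"`
#'   (default flat `c(1, 1)`).
#' @param seed optional integer seed.
#' @return strictly positive numeric vector of length `L` summing to 1.
#' @export
simulate_bias <- function(L, shape = c("lognormal", "beta"), sdlog = 1,
                          beta_shape = c(1, 1), seed = NULL) {
  if (L < 2) stop("at least two loci are required")
  shape <- match.arg(shape)
  if (!is.null(seed)) set.seed(seed)
  raw <- switch(shape,
    lognormal = exp(rnorm(L, 0, sdlog)),
    beta = rbeta(L, beta_shape[1], beta_shape[2]))
  raw <- pmax(raw, .Machine$double.xmin)
  raw / sum(raw)
}

#' Simulate counts for a diploid control sample
#'
#' Two-stage draw under the control generative model with relative copy
#' number fixed at 1 everywhere: `theta_l ~ Beta(s m_l, s (1 - m_l))`, then
#' `y_l ~ Binomial(n, theta_l)`.
#'
#' @param m bias simplex.
#' @param s inverse dispersion (> 0).
#' @param n total reads.
#' @param seed optional integer seed.
#' @return integer count vector of length `length(m)`.
#' @export
simulate_control_counts <- function(m, s, n, seed = NULL) {
  stopifnot(all(m > 0), all(m < 1), s > 0, n > 0)
  if (!is.null(seed)) set.seed(seed)
  theta <- rbeta(length(m), s * m, s * (1 - m))
  rbinom(length(m), n, theta)
}

#' Simulate counts for a sample with a piecewise-constant RCN profile
#'
#' The true profile is given as ordered segments per arm; tumour purity
#' mixes it with a flat diploid background, `c_eff = p c + (1 - p)`, and
#' the effective profile is rescaled so that `sum(c_eff * m) = 1`, pinning
#' the output to the "relative to the sample mean" scale the caller
#' reports. Counts are then drawn from the beta-binomial two-stage model.
#'
#' @param m bias simplex.
#' @param s inverse dispersion of the sample.
#' @param n total reads.
#' @param segments data.frame with columns `arm`, `n_loci`, `rcn`; rows are
#'   consumed in order within each arm and must tile the arm's loci exactly.
#' @param arms character vector: arm label of each locus (same length and
#'   order as `m`).
#' @param purity tumour purity in \[0, 1\] (default 1).
#' @param seed optional integer seed.
#' @return list with `counts` (integer vector), `rcn` (true effective
#'   rescaled RCN per locus) and `state` (segment index per locus).
#' @export
simulate_rcn_sample <- function(m, s, n, segments, arms, purity = 1,
                                seed = NULL) {
  stopifnot(length(arms) == length(m), purity >= 0, purity <= 1,
            all(c("arm", "n_loci", "rcn") %in% names(segments)),
            all(segments$n_loci > 0), all(segments$rcn >= 0))
  if (!is.null(seed)) set.seed(seed)
  L <- length(m)
  c_true <- rep(NA_real_, L)
  state <- rep(NA_integer_, L)
  for (a in unique(arms)) {
    idx <- which(arms == a)
    seg_rows <- which(segments$arm == a)
    seg <- segments[seg_rows, , drop = FALSE]
    if (sum(seg$n_loci) != length(idx))
      stop("segments for arm '", a, "' cover ", sum(seg$n_loci),
           " loci but the arm has ", length(idx))
    c_true[idx] <- rep(seg$rcn, seg$n_loci)
    state[idx] <- rep(seg_rows, seg$n_loci)
  }
  if (anyNA(c_true)) stop("some loci belong to arms without segments")
  c_eff <- purity * c_true + (1 - purity)
  c_eff <- c_eff / sum(c_eff * m)
  if (!validate_mean_constraint(c_eff, m))
    stop("effective RCN violates the mean constraint c*m < 1")
  theta <- rbeta(L, s * c_eff * m, s * (1 - c_eff * m))
  list(counts = rbinom(L, n, theta), rcn = c_eff, state = state)
}

#' Reads required for an in silico dilution
#'
#' `tumour_reads = round(desired_purity * total / source_purity)` where
#' `source_purity` is the undiluted sample's (externally inferred) purity;
#' `control_reads` is the remainder.
#'
#' @param spec list with `desired_purity` in \[0, 1\],
#'   `required_total_reads` (positive integer) and `source_purity` in
#'   (0, 1].
#' @return list with integers `tumour_reads` and `control_reads`.
#' @export
dilution_reads <- function(spec) {
  stopifnot(is.list(spec),
            all(c("desired_purity", "required_total_reads",
                  "source_purity") %in% names(spec)))
  p <- spec$desired_purity; tot <- spec$required_total_reads
  src <- spec$source_purity
  if (p < 0 || p > 1 || src <= 0 || src > 1 || tot <= 0)
    stop("invalid dilution specification")
  if (p > src)
    stop("desired purity ", p, " exceeds the source sample's purity ", src)
  tumour <- round(p * tot / src)
  list(tumour_reads = as.integer(tumour),
       control_reads = as.integer(tot - tumour))
}

# multivariate hypergeometric: draw `k` reads without replacement from a
# pool with per-locus totals `x`
rmvhyper <- function(x, k) {
  stopifnot(k >= 0, sum(x) >= k)
  out <- integer(length(x))
  remaining <- sum(x)
  need <- k
  for (i in seq_along(x)) {
    if (need == 0L) break
    out[i] <- rhyper(1, x[i], remaining - x[i], need)
    need <- need - out[i]
    remaining <- remaining - x[i]
  }
  out
}

#' Mix tumour and control counts to a target purity
#'
#' Count-level analogue of read-level dilution: subsamples the required
#' number of tumour reads from the tumour count vector and the required
#' number of control reads from the pooled control vector, each without
#' replacement (multivariate hypergeometric), and sums them. The output
#' column total is exactly `required_total_reads`.
#'
#' @param tumour integer count vector of the undiluted tumour sample.
#' @param control_pool integer count vector of the pooled controls (same
#'   loci).
#' @param spec dilution specification as in [dilution_reads()].
#' @param seed optional integer seed.
#' @return integer count vector of the diluted sample.
#' @export
mix_counts <- function(tumour, control_pool, spec, seed = NULL) {
  stopifnot(length(tumour) == length(control_pool))
  need <- dilution_reads(spec)
  if (sum(tumour) < need$tumour_reads)
    stop("tumour sample has ", sum(tumour), " reads; ",
         need$tumour_reads, " required")
  if (sum(control_pool) < need$control_reads)
    stop("control pool has ", sum(control_pool), " reads; ",
         need$control_reads, " required")
  if (!is.null(seed)) set.seed(seed)
  rmvhyper(as.integer(tumour), need$tumour_reads) +
    rmvhyper(as.integer(control_pool), need$control_reads)
}

#' Synthetic locus table spread over chromosome arms
#'
#' Convenience builder for simulations and tests: `L` loci divided as
#' evenly as possible over the requested arms, with positions spaced
#' within each arm's (default GRCh38) boundaries and alternating strand.
#'
#' @param L number of loci.
#' @param arms arm labels to use (default the four arms of chromosomes
#'   1 and 2).
#' @param arm_bounds boundary table, see [default_arm_boundaries()].
#' @return data.frame with `chrom`, `pos`, `strand`, `arm`, sorted by
#'   (chrom, pos).
#' @export
make_synthetic_loci <- function(L, arms = c("1p", "1q", "2p", "2q"),
                                arm_bounds = default_arm_boundaries()) {
  stopifnot(all(arms %in% arm_bounds$arm))
  n_arm <- diff(floor(seq(0, L, length.out = length(arms) + 1)))
  parts <- lapply(seq_along(arms), function(i) {
    b <- arm_bounds[arm_bounds$arm == arms[i], ]
    pos <- floor(seq(b$start + 1e4, b$end - 1e4, length.out = n_arm[i]))
    data.frame(chrom = b$chrom, pos = as.integer(pos),
               strand = rep_len(c("+", "-"), n_arm[i]), arm = arms[i])
  })
  loci <- do.call(rbind, parts)
  loci <- loci[order(chrom_order(loci$chrom), loci$pos), ]
  rownames(loci) <- NULL
  loci
}

#' Simulate a full count matrix (controls plus optional tumour samples)
#'
#' Draws one shared bias vector, `n_controls` diploid control samples and,
#' if `segments` is given, tumour samples at the requested purities, all at
#' the same read depth. The generator draws from the same model the
#' samplers invert, so every inference stage is testable end to end.
#'
#' @param L number of loci.
#' @param n_controls number of control samples.
#' @param n total reads per sample.
#' @param s inverse dispersion used for every sample (default 1e4).
#' @param segments optional segment table (see [simulate_rcn_sample()]).
#' @param purity vector of purities; one tumour sample per entry.
#' @param arms arm labels for [make_synthetic_loci()].
#' @param sdlog bias heavy-tail parameter (see [simulate_bias()]).
#' @param seed optional integer seed.
#' @return list with `cm` (an `rcn_count_matrix`), `m` (true bias), `truth`
#'   (per-tumour list of true RCN/state vectors) and `control_ids`.
#' @export
simulate_count_matrix <- function(L, n_controls, n, s = 1e4,
                                  segments = NULL, purity = 1,
                                  arms = c("1p", "1q", "2p", "2q"),
                                  sdlog = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loci <- make_synthetic_loci(L, arms)
  m <- simulate_bias(L, sdlog = sdlog)
  ctl <- vapply(seq_len(n_controls), function(k)
    simulate_control_counts(m, s, n), integer(L))
  control_ids <- sprintf("control%02d", seq_len(n_controls))
  counts <- ctl
  ids <- control_ids
  truth <- list()
  if (!is.null(segments)) {
    for (i in seq_along(purity)) {
      sim <- simulate_rcn_sample(m, s, n, segments, loci$arm, purity[i])
      counts <- cbind(counts, sim$counts)
      id <- sprintf("tumour%02d", i)
      ids <- c(ids, id)
      truth[[id]] <- sim[c("rcn", "state")]
    }
  }
  colnames(counts) <- ids
  list(cm = rcn_count_matrix(loci, counts), m = m, truth = truth,
       control_ids = control_ids)
}
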