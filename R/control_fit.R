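#' Fit the locus bias model to a control panel
#'
#' Metropolis-Hastings MCMC over the control generative model: per-locus
#' bias `m_l` (independent Beta priors, logit random-walk proposals) and
#' per-control inverse dispersion `s_k` (Gamma prior, log random-walk),
#' with relative copy number fixed at 1 and theta marginalised
#' analytically (beta-binomial likelihood). No simplex constraint is
#' enforced during sampling — the priors on `m_l` are independent — and the
#' MAP estimates are rescaled to the simplex only at summary time.
#'
#' Proposal step sizes adapt towards ~30% acceptance during burn-in and are
#' frozen afterwards, so the post-burn-in chain is a valid MCMC.
#'
#' @param cm an `rcn_count_matrix` whose loci have already been selected
#'   (no zero counts in any control).
#' @param control_ids character vector of control sample ids.
#' @param hp hyperparameters, see [rcn_hyperparams()].
#' @param iters total MCMC iterations (default 20000).
#' @param burn burn-in iterations discarded (default 5000).
#' @param thin store every `thin`-th post-burn-in iteration (default 1).
#' @param seed optional integer seed.
#' @return An object of class `rcn_control_trace`: list with `m` (stored
#'   iterations x L matrix), `s` (stored x K), acceptance rates, loci and
#'   settings.
#' @export
fit_controls <- function(cm, control_ids, hp = rcn_hyperparams(),
                         iters = 20000, burn = 5000, thin = 1,
                         seed = NULL) {
  stopifnot(inherits(cm, "rcn_count_matrix"),
            inherits(hp, "rcn_hyperparams"))
  if (length(control_ids) == 0L) stop("no control samples given")
  if (!all(control_ids %in% cm$samples))
    stop("unknown control ids: ",
         paste(setdiff(control_ids, cm$samples), collapse = ", "))
  x <- cm$counts[, control_ids, drop = FALSE]
  if (any(x == 0))
    stop("controls contain zero counts at retained loci; run select_loci()")
  if (!is.null(seed)) set.seed(seed)
  nk <- colSums(x)
  L <- nrow(x); K <- ncol(x)
  m0 <- rowMeans(sweep(x, 2, nk, "/")) # empirical proportions as start
  s0 <- rep(hp$psi[1] * hp$psi[2], K) # prior mean
  out <- control_mh_cpp(matrix(as.numeric(x), L, K), as.numeric(nk),
                        m0, s0, hp$phi[1], hp$phi[2], hp$psi[1], hp$psi[2],
                        as.integer(iters), as.integer(burn),
                        as.integer(thin))
  colnames(out$s) <- control_ids
  structure(list(m = out$m, s = out$s, accept_m = out$accept_m,
                 accept_s = out$accept_s, loci = cm$loci,
                 control_ids = control_ids, hp = hp,
                 settings = list(iters = iters, burn = burn, thin = thin,
                                 seed = seed)),
            class = "rcn_control_trace")
}

#' @export
print.rcn_control_trace <- function(x, ...) {
  cat(sprintf(
    "rcn_control_trace: %d stored iterations, %d loci, %d controls\n",
    nrow(x$m), ncol(x$m), ncol(x$s)))
  cat(sprintf("mean acceptance: m %.2f, s %.2f\n",
              mean(x$accept_m), mean(x$accept_s)))
  invisible(x)
}

#' Posterior mode of a scalar MCMC trace
#'
#' Maximum a posteriori estimate via a Gaussian kernel density estimate:
#' normal-reference bandwidth, 401-point grid spanning the sample range.
#' A (numerically) constant trace returns the constant.
#'
#' @param samples numeric vector of post-burn-in draws.
#' @param gridsize KDE grid size (default 401).
#' @return the grid point of maximum estimated density.
#' @export
density_mode <- function(samples, gridsize = 401L) {
  samples <- samples[is.finite(samples)]
  if (length(samples) == 0L) stop("no finite samples")
  rng <- range(samples)
  if (diff(rng) < .Machine$double.eps * max(1, abs(rng[1])))
    return(samples[1])
  bw <- bw.nrd0(samples)
  if (!is.finite(bw) || bw <= 0) return(stats::median(samples))
  kde <- KernSmooth::bkde(samples, kernel = "normal", bandwidth = bw,
                          gridsize = gridsize, range.x = rng)
  kde$x[which.max(kde$y)]
}

#' Summarise a control trace into a bias model
#'
#' Per-locus MAP of `m` by [density_mode()], rescaled to sum to exactly 1
#' (the per-locus MAP estimates need not lie on the simplex), plus a MAP
#' inverse dispersion per control.
#'
#' @param trace an `rcn_control_trace`.
#' @return An object of class `rcn_bias_model`: list with `m_hat` (simplex),
#'   `s_hat` (named per control), `loci` and provenance.
#' @export
summarise_bias <- function(trace) {
  stopifnot(inherits(trace, "rcn_control_trace"))
  m_hat <- apply(trace$m, 2, density_mode)
  m_hat <- m_hat / sum(m_hat)
  s_hat <- apply(trace$s, 2, density_mode)
  structure(list(m_hat = m_hat, s_hat = s_hat, loci = trace$loci,
                 control_ids = trace$control_ids,
                 settings = trace$settings),
            class = "rcn_bias_model")
}

#' @export
print.rcn_bias_model <- function(x, ...) {
  cat(sprintf("rcn_bias_model: %d loci, %d controls\n",
              length(x$m_hat), length(x$s_hat)))
  cat(sprintf("s_hat: %s\n", paste(signif(x$s_hat, 3), collapse = ", ")))
  invisible(x)
}

#' Write / read a bias model
#'
#' TSV with columns `chrom`, `pos`, `strand`, `m_hat`, plus a JSON sidecar
#' (same path with extension `.json`) holding `s_hat` and the run settings.
#'
#' @param bias an `rcn_bias_model`.
#' @param path output TSV path.
#' @export
write_bias_model <- function(bias, path) {
  stopifnot(inherits(bias, "rcn_bias_model"))
  df <- cbind(bias$loci[c("chrom", "pos", "strand")], m_hat = bias$m_hat)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.[^.]*$", "", path)
  jsonlite::write_json(
    list(s_hat = as.list(bias$s_hat), control_ids = bias$control_ids,
         settings = bias$settings),
    paste0(side, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_bias_model
#' @return `read_bias_model()` returns an `rcn_bias_model`.
#' @export
read_bias_model <- function(path) {
  df <- read.delim(path, colClasses = NA)
  stopifnot(all(c("chrom", "pos", "strand", "m_hat") %in% names(df)))
  side <- paste0(sub("\\.[^.]*$", "", path), ".json")
  extra <- if (file.exists(side)) jsonlite::read_json(side,
                                                      simplifyVector = TRUE)
           else list()
  structure(list(m_hat = df$m_hat,
                 s_hat = unlist(extra$s_hat),
                 loci = df[c("chrom", "pos", "strand")],
                 control_ids = extra$control_ids,
                 settings = extra$settings),
            class = "rcn_bias_model")
}
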