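#' Expected sticky transition row
#'
#' Under the sticky HDP prior the expected transition row of state `u` is
#' the convex combination `(1 - rho) * beta + rho * delta_u`: `rho` is the
#' weight on self-transition, `beta` the global state distribution.
#'
#' @param beta global state weight simplex.
#' @param rho self-transition weight in \[0, 1\].
#' @param u 1-based state index.
#' @return numeric vector summing to 1.
#' @export
sticky_row_expectation <- function(beta, rho, u) {
  stopifnot(rho >= 0, rho <= 1, u >= 1, u <= length(beta))
  out <- (1 - rho) * beta
  out[u] <- out[u] + rho
  out
}

#' Draw a state path from its conditional posterior
#'
#' Exact joint draw of the hidden path given emissions and the transition
#' model: backward message pass followed by forward sampling, in log
#' space. Emissions may contain `-Inf` (impossible state/locus pairs) but a
#' locus with no possible state is an error.
#'
#' @param log_emissions L x K matrix of log emission probabilities.
#' @param pi K x K row-stochastic transition matrix.
#' @param pi0 initial distribution (length K).
#' @param seed optional integer seed.
#' @return integer vector of 1-based states, length L.
#' @export
forward_backward_sample <- function(log_emissions, pi, pi0, seed = NULL) {
  log_emissions <- as.matrix(log_emissions)
  if (any(is.nan(log_emissions)) || any(log_emissions == Inf))
    stop("log emissions must be finite or -Inf")
  stopifnot(nrow(pi) == ncol(log_emissions),
            length(pi0) == ncol(log_emissions),
            all(abs(rowSums(pi) - 1) < 1e-8), abs(sum(pi0) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  fb_sample_cpp(log_emissions, as.matrix(pi), as.numeric(pi0))
}

# one Dirichlet draw, floored away from exact zero so log-densities stay
# finite (states with vanishing weight remain reachable in principle)
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, scale = 1)
  g <- pmax(g, 1e-300)
  g / sum(g)
}

# Chinese-restaurant table count: number of tables among n customers at a
# dish with concentration a
crt_count <- function(n, a) {
  if (n == 0L || a <= 0) return(0L)
  sum(runif(n) < a / (a + seq_len(n) - 1))
}

ddirichlet_log <- function(x, alpha) {
  sum((alpha - 1) * log(pmax(x, 1e-300))) + lgamma(sum(alpha)) -
    sum(lgamma(alpha))
}

#' Log joint density of one sampler state
#'
#' Sum of the arm-wise Markov chain terms, the marginalised beta-binomial
#' emissions and every prior term (state RCN values, sample dispersion,
#' stickiness, concentration, global weights, transition rows), up to an
#' additive constant. Returns `-Inf` when any assigned state violates the
#' mean constraint `c * m < 1` (an invalid configuration).
#'
#' @param draw list with elements `z` (1-based states per locus), `c`
#'   (per-state RCN), `beta`, `pi`, `pi0`, `s_tilde`, `rho`,
#'   `alpha_plus_kappa`.
#' @param y count vector.
#' @param arms arm label per locus (loci ordered within arms).
#' @param m bias vector (or an `rcn_bias_model`).
#' @param hp hyperparameters.
#' @return scalar log density (up to a constant).
#' @export
log_joint <- function(draw, y, arms, m, hp = rcn_hyperparams()) {
  if (inherits(m, "rcn_bias_model")) m <- m$m_hat
  K <- length(draw$c)
  L <- length(y)
  n <- sum(y)
  cm <- draw$c[draw$z] * m
  if (any(cm <= 0 | cm >= 1)) return(-Inf)
  ll <- sum(bb_logpmf_cpp(as.numeric(y), n, cm, draw$s_tilde))
  idx <- split(seq_len(L), factor(arms, levels = unique(arms)))
  chain <- 0
  logpi <- log(pmax(draw$pi, 1e-300))
  logpi0 <- log(pmax(draw$pi0, 1e-300))
  for (ix in idx) {
    chain <- chain + logpi0[draw$z[ix[1]]]
    if (length(ix) > 1) {
      zz <- draw$z[ix]
      chain <- chain + sum(logpi[cbind(zz[-length(zz)], zz[-1])])
    }
  }
  apk <- draw$alpha_plus_kappa
  rho <- draw$rho
  pri <- sum(dgamma(draw$c, shape = hp$lambda[1], scale = hp$lambda[2],
                    log = TRUE)) +
    dgamma(draw$s_tilde, shape = hp$omega[1], scale = hp$omega[2],
           log = TRUE) +
    dbeta(rho, hp$rho[1], hp$rho[2], log = TRUE) +
    dgamma(apk, shape = hp$alpha_plus_kappa[1],
           scale = hp$alpha_plus_kappa[2], log = TRUE) +
    ddirichlet_log(draw$beta, rep(hp$gamma / K, K)) +
    ddirichlet_log(draw$pi0, (1 - rho) * apk * draw$beta)
  for (u in seq_len(K))
    pri <- pri + ddirichlet_log(draw$pi[u, ],
                                apk * sticky_row_expectation(draw$beta,
                                                             rho, u))
  ll + chain + pri
}

#' Infer a relative copy number profile
#'
#' Blocked Gibbs sampler for the sticky HDP-HMM with beta-binomial
#' emissions, truncated at `K_max` states (weak-limit approximation of the
#' countably infinite state space). Each chromosome arm is an independent
#' Markov chain. One sweep:
#'
#' 1. joint resampling of the state path per arm (forward-backward);
#' 2. auxiliary table counts (with the sticky override correction), then
#'    Gibbs draws of the global weights `beta`, the transition rows and the
#'    initial distribution;
#' 3. Metropolis-Hastings update of each populated state's RCN value
#'    (log random walk against the Gamma base distribution); unpopulated
#'    states are redrawn from the base distribution, which is what lets the
#'    populated-state count grow;
#' 4. MH update of the sample inverse dispersion `s~`;
#' 5. MH updates of the stickiness `rho` (logit scale) and concentration
#'    `alpha + kappa` (log scale) against the instantiated transition rows
#'    and their tight Beta/Gamma priors.
#'
#' Proposal steps adapt towards ~30% acceptance during burn-in only. The
#' chain starts from the null profile: every locus in one state with RCN 1.
#'
#' @param y integer count vector for one sample over the selected loci.
#' @param loci locus table with an `arm` column (loci sorted, arms
#'   contiguous), as in `rcn_count_matrix$loci` after [assign_arms()].
#' @param bias an `rcn_bias_model` whose loci match `loci` exactly, or a
#'   bare bias simplex of the same length.
#' @param hp hyperparameters, see [rcn_hyperparams()].
#' @param iters,burn,thin MCMC schedule; defaults 50000/20000/5 (use
#'   30000/5000 for quick screens such as dilution series).
#' @param K_max truncation level (default 25). If the sampler ever
#'   populates all `K_max` states the run restarts once with `2 * K_max`
#'   (with a warning).
#' @param seed optional integer seed.
#' @return An object of class `rcn_trace` holding the thinned post-burn-in
#'   draws: `z` (draws x L), `c`, `beta`, `pi0` (draws x K), `pi`
#'   (K x K x draws), `s_tilde`, `rho`, `alpha_plus_kappa`, `n_pop`
#'   (populated-state count per stored draw), plus loci, settings and
#'   acceptance rates.
#' @export
infer_rcn <- function(y, loci, bias, hp = rcn_hyperparams(), iters = 50000,
                      burn = 20000, thin = 5, K_max = 25, seed = NULL) {
  stopifnot(inherits(hp, "rcn_hyperparams"), burn < iters, thin >= 1,
            K_max >= 2)
  if (inherits(bias, "rcn_bias_model")) {
    if (!isTRUE(all.equal(bias$loci$pos, loci$pos)) ||
        !identical(as.character(bias$loci$chrom), as.character(loci$chrom)))
      stop("bias model loci do not match the sample's loci")
    m <- bias$m_hat
  } else m <- as.numeric(bias)
  L <- length(y)
  if (length(m) != L || nrow(loci) != L)
    stop("y, loci and bias must describe the same loci")
  if (is.null(loci$arm)) stop("loci need an 'arm' column; see assign_arms()")
  n <- sum(y)
  if (!is.null(seed)) set.seed(seed)

  K <- as.integer(K_max)
  arm_f <- factor(loci$arm, levels = unique(loci$arm))
  arm_idx <- split(seq_len(L), arm_f)
  first_pos <- vapply(arm_idx, `[`, integer(1), 1)
  from_pos <- unlist(lapply(arm_idx, function(ix) ix[-length(ix)]),
                     use.names = FALSE)
  to_pos <- unlist(lapply(arm_idx, function(ix) ix[-1]), use.names = FALSE)
  max_m <- max(m)

  draw_base <- function() { # base-distribution draw kept inside the domain
    for (i in 1:50) {
      cc <- rgamma(1, shape = hp$lambda[1], scale = hp$lambda[2])
      if (cc * max_m < 1 && cc > 0) return(cc)
    }
    1
  }

  # null-profile initialisation
  z <- rep(1L, L)
  cvals <- c(1, vapply(seq_len(K - 1), function(i) draw_base(), numeric(1)))
  rho <- hp$rho[1] / sum(hp$rho)
  apk <- hp$alpha_plus_kappa[1] * hp$alpha_plus_kappa[2]
  s_t <- hp$omega[1] * hp$omega[2]
  beta <- rep(1 / K, K)
  pi <- t(vapply(seq_len(K), function(u) sticky_row_expectation(beta, rho, u),
                 numeric(K)))
  pi0 <- beta

  lambda_s <- hp$lambda[1]; lambda_sc <- hp$lambda[2]
  step <- c(c = 0.2, s = 0.5, rho = 0.5, apk = 0.1)
  acc <- try <- c(c = 0, s = 0, rho = 0, apk = 0)
  acc_tot <- try_tot <- acc

  stored <- (iters - burn) %/% thin
  tr_z <- matrix(0L, stored, L)
  tr_c <- matrix(0, stored, K)
  tr_beta <- matrix(0, stored, K)
  tr_pi0 <- matrix(0, stored, K)
  tr_pi <- array(0, c(K, K, stored))
  tr_s <- tr_rho <- tr_apk <- numeric(stored)
  tr_npop <- integer(stored)
  row <- 0L
  hit_kmax <- FALSE

  dirich_terms <- function(rho_, apk_) {
    tot <- ddirichlet_log(pi0, (1 - rho_) * apk_ * beta)
    base <- apk_ * (1 - rho_) * beta
    for (u in seq_len(K)) {
      a <- base
      a[u] <- a[u] + apk_ * rho_
      tot <- tot + ddirichlet_log(pi[u, ], a)
    }
    tot
  }

  for (it in seq_len(iters)) {
    ## (1) emissions and blocked state resampling
    E <- emission_matrix_cpp(as.numeric(y), n, m, cvals, s_t)
    for (ix in arm_idx)
      z[ix] <- fb_sample_cpp(E[ix, , drop = FALSE], pi, pi0)

    ## (2) counts, auxiliary tables, beta, transition rows
    zf <- z[from_pos]; zt <- z[to_pos]
    trans <- matrix(tabulate(zf + (zt - 1L) * K, K * K), K, K)
    n0 <- tabulate(z[first_pos], K)
    alpha0 <- (1 - rho) * apk
    mtab <- matrix(0L, K, K)
    nz <- which(trans > 0, arr.ind = TRUE)
    for (i in seq_len(nrow(nz))) {
      u <- nz[i, 1]; v <- nz[i, 2]
      a_uv <- apk * ((1 - rho) * beta[v] + rho * (u == v))
      mtab[u, v] <- crt_count(trans[u, v], a_uv)
    }
    m0tab <- vapply(seq_len(K), function(v)
      crt_count(n0[v], alpha0 * beta[v]), integer(1))
    w <- vapply(seq_len(K), function(u) {
      if (mtab[u, u] == 0L) return(0L)
      p_self <- rho / (rho + beta[u] * (1 - rho))
      as.integer(rbinom(1, mtab[u, u], p_self))
    }, integer(1))
    mbar_col <- colSums(mtab) - w # override variables remove self tables
    beta <- rdirichlet1(hp$gamma / K + mbar_col + m0tab)
    for (u in seq_len(K)) {
      a <- apk * ((1 - rho) * beta)
      a[u] <- a[u] + apk * rho
      pi[u, ] <- rdirichlet1(a + trans[u, ])
    }
    pi0 <- rdirichlet1(alpha0 * beta + n0)

    ## (3) state RCN updates
    pop_idx <- split(seq_len(L), factor(z, levels = seq_len(K)))
    pop <- which(lengths(pop_idx) > 0L)
    for (u in pop) {
      idx <- pop_idx[[u]]
      c1 <- cvals[u]
      c2 <- c1 * exp(step["c"] * rnorm(1))
      try["c"] <- try["c"] + 1; try_tot["c"] <- try_tot["c"] + 1
      if (c2 * max(m[idx]) >= 1 || c2 <= 0) next
      new_ll <- bb_logpmf_cpp(as.numeric(y[idx]), n, c2 * m[idx], s_t)
      d <- sum(new_ll) - sum(E[cbind(idx, rep(u, length(idx)))]) +
        dgamma(c2, lambda_s, scale = lambda_sc, log = TRUE) -
        dgamma(c1, lambda_s, scale = lambda_sc, log = TRUE) +
        log(c2) - log(c1)
      if (d >= 0 || runif(1) < exp(d)) {
        cvals[u] <- c2
        E[idx, u] <- new_ll
        acc["c"] <- acc["c"] + 1; acc_tot["c"] <- acc_tot["c"] + 1
      }
    }
    for (u in setdiff(seq_len(K), pop)) cvals[u] <- draw_base()

    ## (4) sample dispersion update
    cur <- sum(E[cbind(seq_len(L), z)])
    s2 <- s_t * exp(step["s"] * rnorm(1))
    try["s"] <- try["s"] + 1; try_tot["s"] <- try_tot["s"] + 1
    new_ll <- sum(bb_logpmf_cpp(as.numeric(y), n, cvals[z] * m, s2))
    d <- new_ll - cur +
      dgamma(s2, hp$omega[1], scale = hp$omega[2], log = TRUE) -
      dgamma(s_t, hp$omega[1], scale = hp$omega[2], log = TRUE) +
      log(s2) - log(s_t)
    if (is.finite(d) && (d >= 0 || runif(1) < exp(d))) {
      s_t <- s2
      acc["s"] <- acc["s"] + 1; acc_tot["s"] <- acc_tot["s"] + 1
    }

    ## (5) stickiness and concentration updates
    cur_terms <- dirich_terms(rho, apk)
    lo <- log(rho) - log1p(-rho) + step["rho"] * rnorm(1)
    rho2 <- 1 / (1 + exp(-lo))
    try["rho"] <- try["rho"] + 1; try_tot["rho"] <- try_tot["rho"] + 1
    if (rho2 > 0 && rho2 < 1) {
      d <- dirich_terms(rho2, apk) - cur_terms +
        dbeta(rho2, hp$rho[1], hp$rho[2], log = TRUE) -
        dbeta(rho, hp$rho[1], hp$rho[2], log = TRUE) +
        log(rho2) + log1p(-rho2) - log(rho) - log1p(-rho)
      if (is.finite(d) && (d >= 0 || runif(1) < exp(d))) {
        rho <- rho2
        acc["rho"] <- acc["rho"] + 1; acc_tot["rho"] <- acc_tot["rho"] + 1
        cur_terms <- dirich_terms(rho, apk)
      }
    }
    apk2 <- apk * exp(step["apk"] * rnorm(1))
    try["apk"] <- try["apk"] + 1; try_tot["apk"] <- try_tot["apk"] + 1
    d <- dirich_terms(rho, apk2) - cur_terms +
      dgamma(apk2, hp$alpha_plus_kappa[1], scale = hp$alpha_plus_kappa[2],
             log = TRUE) -
      dgamma(apk, hp$alpha_plus_kappa[1], scale = hp$alpha_plus_kappa[2],
             log = TRUE) +
      log(apk2) - log(apk)
    if (is.finite(d) && (d >= 0 || runif(1) < exp(d))) {
      apk <- apk2
      acc["apk"] <- acc["apk"] + 1; acc_tot["apk"] <- acc_tot["apk"] + 1
    }

    ## adaptation (burn-in only)
    if (it <= burn && it %% 50 == 0) {
      rate <- ifelse(try > 0, acc / try, 0.3)
      step[] <- pmin(10, pmax(1e-3, step * exp(rate - 0.3)))
      acc[] <- 0; try[] <- 0
    }

    if (length(pop) == K) hit_kmax <- TRUE

    if (it > burn && (it - burn) %% thin == 0) {
      row <- row + 1L
      tr_z[row, ] <- z
      tr_c[row, ] <- cvals
      tr_beta[row, ] <- beta
      tr_pi0[row, ] <- pi0
      tr_pi[, , row] <- pi
      tr_s[row] <- s_t
      tr_rho[row] <- rho
      tr_apk[row] <- apk
      tr_npop[row] <- length(pop)
    }
  }

  if (hit_kmax) {
    warning("all ", K, " truncation states were populated; restarting with ",
            "K_max = ", 2 * K)
    return(infer_rcn(y, loci, bias, hp, iters, burn, thin, 2 * K, seed))
  }

  structure(list(z = tr_z, c = tr_c, beta = tr_beta, pi0 = tr_pi0,
                 pi = tr_pi, s_tilde = tr_s, rho = tr_rho,
                 alpha_plus_kappa = tr_apk, n_pop = tr_npop, loci = loci,
                 accept = ifelse(try_tot > 0, acc_tot / try_tot, NA),
                 settings = list(iters = iters, burn = burn, thin = thin,
                                 K_max = K, seed = seed)),
            class = "rcn_trace")
}

#' @export
print.rcn_trace <- function(x, ...) {
  cat(sprintf("rcn_trace: %d stored draws, %d loci, K_max %d\n",
              nrow(x$z), ncol(x$z), x$settings$K_max))
  cat(sprintf("modal populated states: %d; acceptance c %.2f s %.2f\n",
              map_state_count(x), x$accept["c"], x$accept["s"]))
  invisible(x)
}

#' Run the RCN sampler on one sample of a count matrix
#'
#' Convenience wrapper: extracts the sample's counts and calls
#' [infer_rcn()].
#'
#' @param cm an `rcn_count_matrix` (after locus selection and
#'   [assign_arms()]).
#' @param sample sample id.
#' @param bias an `rcn_bias_model` fitted on the same loci.
#' @param ... passed to [infer_rcn()].
#' @return an `rcn_trace`.
#' @export
call_sample <- function(cm, sample, bias, ...) {
  stopifnot(inherits(cm, "rcn_count_matrix"))
  if (!sample %in% cm$samples) stop("unknown sample id: ", sample)
  infer_rcn(cm$counts[, sample], cm$loci, bias, ...)
}
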