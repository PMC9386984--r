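test_that("sticky row expectation mixes beta with self-transition mass", {
  beta <- c(0.5, 0.5)
  expect_equal(sticky_row_expectation(beta, 1, 1), c(1, 0))
  expect_equal(sticky_row_expectation(beta, 0, 2), beta)
  expect_equal(sticky_row_expectation(beta, 0.9, 1), c(0.95, 0.05))
})

test_that("Dirichlet rows built on the sticky expectation satisfy the
           stated mean and variance", {
  # rows are Dirichlet with concentration (alpha+kappa) * E[pi_u]; the
  # variance of each entry must shrink as 1 / (alpha + kappa + 1)
  set.seed(50)
  beta <- c(0.2, 0.3, 0.5)
  rho <- 0.8
  apk <- 500
  ex <- sticky_row_expectation(beta, rho, 2)
  draws <- replicate(20000, {
    g <- rgamma(3, shape = apk * ex)
    g / sum(g)
  })
  for (v in 1:3) {
    expect_lt(abs(mean(draws[v, ]) - ex[v]),
              3 * stats::sd(draws[v, ]) / sqrt(20000))
    v_th <- ex[v] * (1 - ex[v]) / (apk + 1)
    expect_lt(abs(var(draws[v, ]) - v_th) / v_th, 0.1)
  }
})

test_that("forward-backward sampling handles degenerate cases", {
  logE <- matrix(0, 5, 1)
  expect_equal(forward_backward_sample(logE, matrix(1, 1, 1), 1),
               rep(1L, 5))
  # uniform emissions, identity transitions, all mass on state 1
  logE2 <- matrix(log(0.5), 4, 2)
  z <- forward_backward_sample(logE2, diag(2), c(1, 0), seed = 51)
  expect_equal(z, rep(1L, 4))
  # an impossible locus (all -Inf) is an error
  logE2[2, ] <- -Inf
  expect_error(forward_backward_sample(logE2, diag(2), c(1, 0)),
               "zero emission")
  expect_identical(
    forward_backward_sample(matrix(log(runif(8)), 4, 2),
                            matrix(0.5, 2, 2), c(0.5, 0.5), seed = 52),
    forward_backward_sample(matrix(log(runif(8)), 4, 2),
                            matrix(0.5, 2, 2), c(0.5, 0.5), seed = 52))
})

test_that("sampled paths match exhaustive enumeration on a 3-locus toy", {
  logE <- log(matrix(c(0.7, 0.3,
                       0.4, 0.6,
                       0.2, 0.8), 3, 2, byrow = TRUE))
  pi <- matrix(c(0.7, 0.3,
                 0.4, 0.6), 2, 2, byrow = TRUE)
  pi0 <- c(0.6, 0.4)
  paths <- as.matrix(expand.grid(z1 = 1:2, z2 = 1:2, z3 = 1:2))
  p <- apply(paths, 1, function(z)
    pi0[z[1]] * exp(logE[1, z[1]]) * pi[z[1], z[2]] *
      exp(logE[2, z[2]]) * pi[z[2], z[3]] * exp(logE[3, z[3]]))
  p <- p / sum(p)
  set.seed(53)
  R <- 20000
  # expand.grid varies z1 fastest, so row i corresponds to path index i
  idx <- replicate(R, {
    z <- forward_backward_sample(logE, pi, pi0)
    (z[1] - 1) + 2 * (z[2] - 1) + 4 * (z[3] - 1) + 1
  })
  freq <- tabulate(idx, 8) / R
  for (i in 1:8) {
    se <- sqrt(p[i] * (1 - p[i]) / R)
    expect_lt(abs(freq[i] - p[i]), 3 * se)
  }
})

test_that("log joint reduces to emissions plus priors for one state", {
  hp <- rcn_hyperparams()
  m <- simulate_bias(10, seed = 54)
  y <- simulate_control_counts(m, 1e4, 1e4, seed = 55)
  draw <- list(z = rep(1L, 10), c = 1, beta = 1, pi = matrix(1, 1, 1),
               pi0 = 1, s_tilde = 1e4, rho = 0.99,
               alpha_plus_kappa = 2e4)
  lj <- log_joint(draw, y, arms = rep("1p", 10), m, hp)
  by_hand <- sum(betabinom_logpmf(y, sum(y), 1, m, 1e4)) +
    dgamma(1, 3, scale = 1, log = TRUE) +
    dgamma(1e4, 1.5, scale = 1e6, log = TRUE) +
    dbeta(0.99, 1e5, 100, log = TRUE) +
    dgamma(2e4, 2000, scale = 10, log = TRUE)
  # remaining terms (beta, pi, pi0 Dirichlets) are zero for K = 1
  expect_equal(lj, by_hand, tolerance = 1e-10)
})

test_that("log joint matches a brute-force chain product on a 4-locus toy", {
  hp <- rcn_hyperparams()
  m <- c(0.2, 0.3, 0.1, 0.4)
  y <- c(5L, 9L, 2L, 10L)
  n <- sum(y)
  draw <- list(z = c(1L, 1L, 2L, 2L), c = c(0.8, 1.4),
               beta = c(0.6, 0.4),
               pi = matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE),
               pi0 = c(0.5, 0.5), s_tilde = 50, rho = 0.9,
               alpha_plus_kappa = 1000)
  arms <- c("1p", "1p", "1p", "1q")
  # independent oracle: explicit product over the chain factorisation
  chain_oracle <- log(draw$pi0[1]) + log(draw$pi[1, 1]) +
    log(draw$pi[1, 2]) + # arm 1p: z = 1, 1, 2
    log(draw$pi0[2]) # arm 1q starts its own chain
  emis_oracle <- sum(vapply(1:4, function(l)
    betabinom_logpmf(y[l], n, draw$c[draw$z[l]], m[l], draw$s_tilde),
    numeric(1)))
  lj <- log_joint(draw, y, arms, m, hp)
  prior_part <- lj - chain_oracle - emis_oracle
  # the residual must be exactly the (z-independent) prior terms
  draw2 <- draw
  draw2$z <- c(2L, 1L, 1L, 2L)
  chain2 <- log(draw$pi0[2]) + log(draw$pi[2, 1]) + log(draw$pi[1, 1]) +
    log(draw$pi0[2])
  emis2 <- sum(vapply(1:4, function(l)
    betabinom_logpmf(y[l], n, draw2$c[draw2$z[l]], m[l], draw2$s_tilde),
    numeric(1)))
  expect_equal(log_joint(draw2, y, arms, m, hp) - chain2 - emis2,
               prior_part, tolerance = 1e-10)

  # constraint violation collapses the density
  draw3 <- draw
  draw3$c <- c(0.8, 3) # 3 * 0.4 > 1 at locus 4
  expect_identical(log_joint(draw3, y, arms, m, hp), -Inf)
})

test_that("a flat (purity zero) sample yields one populated state", {
  set.seed(56)
  m <- simulate_bias(120, seed = 56)
  arms <- rep(c("1p", "1q", "2p"), each = 40)
  segs <- data.frame(arm = c("1p", "1q", "2p"), n_loci = rep(40, 3),
                     rcn = c(2, 1, 0.5))
  sim <- simulate_rcn_sample(m, 1e4, 4e5, segs, arms, purity = 0,
                             seed = 57)
  loci <- data.frame(chrom = "1", pos = seq_len(120), strand = "+",
                     arm = arms)
  tr <- infer_rcn(sim$counts, loci, m, iters = 800, burn = 300, thin = 2,
                  seed = 58)
  expect_equal(map_state_count(tr), 1L)
  # and the marginal profile is flat around 1
  prof <- marginal_profile(tr)
  expect_lt(max(abs(prof$profile$map_rcn - 1)), 0.05)
})

test_that("the sampler recovers a three-state profile and is reproducible", {
  sim <- fixture_small()
  y <- sim$cm$counts[, "tumour01"]
  tr <- infer_rcn(y, sim$cm$loci, sim$m, iters = 1200, burn = 400,
                  thin = 2, seed = 59)
  expect_equal(map_state_count(tr), 3L) # true values {0.5, 1, 2}
  prof <- marginal_profile(tr)
  expect_gt(spearman_rcn(prof$profile$map_rcn, sim$truth$tumour01$rcn),
            0.9)
  tr2 <- infer_rcn(y, sim$cm$loci, sim$m, iters = 1200, burn = 400,
                   thin = 2, seed = 59)
  expect_identical(tr$z, tr2$z)
  expect_identical(tr$c, tr2$c)

  expect_error(infer_rcn(y[-1], sim$cm$loci, sim$m), "same loci")
})
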