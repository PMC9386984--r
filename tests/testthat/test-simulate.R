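test_that("bias simulator returns a reproducible strict simplex", {
  m <- simulate_bias(100, seed = 1)
  expect_equal(sum(m), 1)
  expect_true(all(m > 0))
  expect_identical(m, simulate_bias(100, seed = 1))
  expect_false(identical(m, simulate_bias(100, seed = 2)))
  expect_error(simulate_bias(1), "two loci")

  # exchangeability of the flat-Beta generator: per-locus means equalise
  set.seed(2)
  draws <- replicate(2000, simulate_bias(4, shape = "beta"))
  expect_lt(max(abs(rowMeans(draws) - 0.25)), 0.01)
})

test_that("control count simulation matches the model moments", {
  set.seed(3)
  m <- simulate_bias(50, seed = 3)
  n <- 1e5; s <- 1e4; R <- 2000
  y <- replicate(R, simulate_control_counts(m, s, n))
  expect_true(all(y >= 0 & y <= n))
  expect_true(all(y == round(y)))
  mu <- expected_count(n, 1, m)
  v <- count_variance(n, s, mu)
  z <- (rowMeans(y) - mu) / sqrt(v / R)
  expect_lt(abs(mean(z)), 3 / sqrt(length(m))) # aggregate 3 SE
  expect_gte(mean(abs(z) < 3.5), 0.98) # modest replicate count here

  # near-infinite s collapses to binomial noise
  m2 <- c(0.3, 0.7)
  y2 <- replicate(5000, simulate_control_counts(m2, 1e12, 1000))
  vb <- 1000 * m2 * (1 - m2)
  relerr <- abs(apply(y2, 1, var) - vb) / vb
  expect_lt(max(relerr), 3 * sqrt(2 / 5000))
})

test_that("RCN sample simulation rescales purity-mixed profiles", {
  m <- simulate_bias(80, seed = 4)
  arms <- rep(c("1p", "1q"), each = 40)
  segs <- data.frame(arm = c("1p", "1q", "1q"), n_loci = c(40, 20, 20),
                     rcn = c(1, 2, 1))
  # purity 0: flat profile, indistinguishable from a control draw
  s0 <- simulate_rcn_sample(m, 1e4, 1e5, segs, arms, purity = 0, seed = 5)
  expect_equal(s0$rcn, rep(1, 80))
  expect_equal(s0$state, rep(c(1L, 2L, 3L), c(40, 20, 20)))

  # purity 1: mean count ratio between gained and neutral loci is ~2
  set.seed(6)
  reps <- replicate(300, {
    x <- simulate_rcn_sample(m, 1e4, 1e5, segs, arms, purity = 1)
    mean(x$counts[41:60] / (1e5 * m[41:60])) /
      mean(x$counts[c(1:40, 61:80)] / (1e5 * m[c(1:40, 61:80)]))
  })
  expect_lt(abs(mean(reps) - 2), 3 * stats::sd(reps) / sqrt(length(reps)))

  # truth vector has exactly the piecewise-constant segment structure
  s1 <- simulate_rcn_sample(m, 1e4, 1e5, segs, arms, purity = 1, seed = 7)
  expect_equal(length(unique(s1$rcn)), 2)
  expect_equal(length(unique(s1$rcn[41:60])), 1)

  bad <- data.frame(arm = c("1p", "1q"), n_loci = c(40, 39), rcn = c(1, 2))
  expect_error(simulate_rcn_sample(m, 1e4, 1e5, bad, arms), "cover")
})

test_that("dilution read arithmetic is exact", {
  out <- dilution_reads(list(desired_purity = 0.03,
                             required_total_reads = 2e6,
                             source_purity = 0.6))
  expect_identical(out$tumour_reads, 100000L)
  expect_identical(out$control_reads, 1900000L)
  z <- dilution_reads(list(desired_purity = 0,
                           required_total_reads = 1e6, source_purity = 0.5))
  expect_identical(z$tumour_reads, 0L)
  expect_identical(z$control_reads, 1000000L)
  f <- dilution_reads(list(desired_purity = 0.4,
                           required_total_reads = 1000,
                           source_purity = 0.4))
  expect_identical(f$tumour_reads, 1000L)
  expect_identical(f$control_reads, 0L)
  expect_error(dilution_reads(list(desired_purity = 0.7,
                                   required_total_reads = 1000,
                                   source_purity = 0.6)), "exceeds")
})

test_that("count mixing conserves totals and matches expectations", {
  spec <- list(desired_purity = 0.5, required_total_reads = 100,
               source_purity = 1)
  tum <- c(100L, 0L); ctl <- c(0L, 100L)
  mixed <- mix_counts(tum, ctl, spec, seed = 8)
  expect_equal(sum(mixed), 100)
  # degenerate single-locus pools make the expectation exact
  expect_equal(mixed, c(50L, 50L))
  set.seed(9)
  tum2 <- c(60L, 40L); ctl2 <- c(30L, 70L)
  reps <- replicate(2000, mix_counts(tum2, ctl2, spec))
  expect_true(all(colSums(reps) == 100))
  # hypergeometric expectation: 50 * 0.6 + 50 * 0.3 = 45 at locus 1
  expect_lt(abs(mean(reps[1, ]) - 45),
            3 * stats::sd(reps[1, ]) / sqrt(2000))

  # desired purity 0: a pure control subsample
  spec0 <- list(desired_purity = 0, required_total_reads = 50,
                source_purity = 0.5)
  m0 <- mix_counts(tum, ctl, spec0, seed = 10)
  expect_equal(m0[1], 0L)
  expect_equal(sum(m0), 50)

  expect_error(mix_counts(c(5L, 5L), ctl, spec), "tumour sample has")
})

test_that("hypergeometric mixing agrees with read-level mixing in expectation", {
  # read-level oracle: label individual reads, subsample, re-tally
  set.seed(11)
  tum <- c(40L, 10L, 25L, 5L, 20L) # 100 reads over 5 loci
  ctl <- c(10L, 30L, 20L, 30L, 10L)
  spec <- list(desired_purity = 0.3, required_total_reads = 60,
               source_purity = 1)
  need <- dilution_reads(spec)
  R <- 3000
  oracle <- replicate(R, {
    t_reads <- sample(rep(seq_along(tum), tum), need$tumour_reads)
    c_reads <- sample(rep(seq_along(ctl), ctl), need$control_reads)
    tabulate(t_reads, 5) + tabulate(c_reads, 5)
  })
  ours <- replicate(R, mix_counts(tum, ctl, spec))
  for (l in 1:5) {
    se <- sqrt(stats::var(ours[l, ]) / R + stats::var(oracle[l, ]) / R)
    expect_lt(abs(mean(ours[l, ]) - mean(oracle[l, ])), 3 * se)
  }
})

test_that("the combined simulator is seed-deterministic", {
  a <- simulate_count_matrix(60, 2, 1e4, seed = 12)
  b <- simulate_count_matrix(60, 2, 1e4, seed = 12)
  expect_identical(a$cm$counts, b$cm$counts)
  expect_identical(a$m, b$m)
  expect_equal(nrow(a$cm$counts), 60)
  expect_equal(colnames(a$cm$counts), c("control01", "control02"))
})
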