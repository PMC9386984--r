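# Shared fixture builders. Everything is generated in code at test time;
# heavy fixtures are built once per test run and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# four-state RCN fixture: L = 1000 loci on five arms, true state values
# {0.5, 1, 1.5, 3} (before mean rescaling), 250 loci per state so the
# tied-rank structure of the truth does not cap the attainable rank
# correlation, purity 1
four_state_segments <- function() {
  data.frame(
    arm = c("1p", "1q", "1q", "2p", "2p", "2q", "2q", "3p", "3p", "3p"),
    n_loci = c(200, 100, 100, 150, 50, 100, 100, 50, 100, 50),
    rcn = c(1, 0.5, 1.5, 3, 0.5, 1.5, 0.5, 1, 3, 1.5))
}

fixture_four_state <- function() memo("four_state", function() {
  set.seed(402)
  sim <- simulate_count_matrix(
    L = 1000, n_controls = 0, n = 2e6, s = 1e4,
    segments = four_state_segments(), purity = 1,
    arms = c("1p", "1q", "2p", "2q", "3p"), seed = 402)
  sim
})

# control panel fixture for bias recovery: K = 8, L = 500, n = 2e5, s = 1e4
fixture_control_panel <- function() memo("control_panel", function() {
  simulate_count_matrix(L = 500, n_controls = 8, n = 2e5, s = 1e4,
                        seed = 301)
})

# small generic fixture reused by unit tests (fast to fit)
fixture_small <- function() memo("small", function() {
  segs <- data.frame(arm = c("1p", "1q", "2p", "2q"),
                     n_loci = c(50, 50, 50, 50), rcn = c(1, 2, 1, 0.5))
  simulate_count_matrix(L = 200, n_controls = 4, n = 5e5, s = 1e4,
                        segments = segs, purity = 1, seed = 42)
})

# hand-built rcn_trace with arbitrary contents, for summary-stage tests
make_trace <- function(z, c, loci = NULL, pi = NULL, K = ncol(c)) {
  TT <- nrow(z)
  L <- ncol(z)
  if (is.null(loci))
    loci <- data.frame(chrom = "1", pos = seq_len(L), strand = "+",
                       arm = "1p")
  if (is.null(pi)) {
    pi <- array(0, c(K, K, TT))
    for (t in seq_len(TT)) pi[, , t] <- diag(K)
  }
  structure(list(
    z = z, c = c, beta = matrix(1 / K, TT, K),
    pi0 = matrix(1 / K, TT, K), pi = pi,
    s_tilde = rep(1e4, TT), rho = rep(0.999, TT),
    alpha_plus_kappa = rep(2e4, TT),
    n_pop = apply(z, 1, function(r) length(unique(r))),
    loci = loci,
    accept = c(c = NA, s = NA, rho = NA, apk = NA),
    settings = list(iters = TT, burn = 0, thin = 1, K_max = K,
                    seed = NULL)),
    class = "rcn_trace")
}

# slow exhaustive Hamming search, the oracle for the primer scan
primer_oracle <- function(read, primer) {
  rl <- nchar(read); pl <- nchar(primer)
  if (pl > rl) return(NULL)
  pv <- strsplit(primer, "")[[1]]
  best <- NULL
  for (off in 0:(rl - pl)) {
    w <- strsplit(substr(read, off + 1, off + pl), "")[[1]]
    d <- sum(w != pv)
    if (is.null(best) || d < best$distance)
      best <- list(position = off, distance = d)
  }
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# write a FASTQ file from parallel vectors of sequence and quality strings
write_fastq <- function(seqs, quals, path,
                        ids = sprintf("read%03d", seq_along(seqs))) {
  stopifnot(length(seqs) == length(quals))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0("@", ids[i]), seqs[i], "+", quals[i]), con)
  invisible(path)
}
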