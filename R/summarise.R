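#' Marginal per-locus RCN profile
#'
#' Summarisation method 1: for each locus, pool the RCN value of its
#' assigned state across draws (marginalising the state labels), take the
#' MAP by kernel density mode and an equal-tailed credible interval.
#'
#' @param trace an `rcn_trace`.
#' @param ci_level credible level (default 0.95).
#' @return An `rcn_profile`: data.frame in `$profile` with `chrom`, `pos`,
#'   `strand`, `map_rcn`, `ci_lo`, `ci_hi`; `$method == "marginal"`;
#'   `$n_states` the modal populated-state count.
#' @export
marginal_profile <- function(trace, ci_level = 0.95) {
  stopifnot(inherits(trace, "rcn_trace"), nrow(trace$z) > 0,
            ci_level > 0, ci_level < 1)
  L <- ncol(trace$z)
  a <- (1 - ci_level) / 2
  draws <- seq_len(nrow(trace$z))
  prof <- vapply(seq_len(L), function(l) {
    v <- trace$c[cbind(draws, trace$z[, l])]
    c(density_mode(v), quantile(v, c(a, 1 - a), names = FALSE))
  }, numeric(3))
  out <- trace$loci[c("chrom", "pos", "strand")]
  out$map_rcn <- prof[1, ]
  out$ci_lo <- pmin(prof[2, ], prof[1, ]) # MAP kept inside the interval
  out$ci_hi <- pmax(prof[3, ], prof[1, ])
  structure(list(profile = out, method = "marginal",
                 n_states = map_state_count(trace), ci_level = ci_level),
            class = "rcn_profile")
}

#' Modal number of populated states
#'
#' The most frequently observed populated-state count across stored draws
#' (a state is populated in a draw if at least one locus is assigned to
#' it); ties break to the smaller count. One populated state means no
#' copy number alteration was detected.
#'
#' @param trace an `rcn_trace`.
#' @return integer.
#' @export
map_state_count <- function(trace) {
  stopifnot(length(trace$n_pop) > 0)
  tab <- table(trace$n_pop)
  as.integer(names(tab)[which.max(tab)]) # table is sorted: first max wins
}

#' Keep only draws with a given populated-state count
#'
#' @param trace an `rcn_trace`.
#' @param k required populated-state count (>= 1).
#' @return an `rcn_trace` containing the matching draws, in order.
#' @export
filter_iterations <- function(trace, k) {
  stopifnot(inherits(trace, "rcn_trace"), k >= 1)
  keep <- which(trace$n_pop == k)
  if (length(keep) == 0L)
    stop("no stored draw has ", k, " populated states; run a longer chain")
  out <- trace
  out$z <- trace$z[keep, , drop = FALSE]
  out$c <- trace$c[keep, , drop = FALSE]
  out$beta <- trace$beta[keep, , drop = FALSE]
  out$pi0 <- trace$pi0[keep, , drop = FALSE]
  out$pi <- trace$pi[, , keep, drop = FALSE]
  out$s_tilde <- trace$s_tilde[keep]
  out$rho <- trace$rho[keep]
  out$alpha_plus_kappa <- trace$alpha_plus_kappa[keep]
  out$n_pop <- trace$n_pop[keep]
  out
}

#' Solve a linear assignment problem (Hungarian method)
#'
#' Minimum-cost perfect matching of rows to columns of a square cost
#' matrix, by the shortest-augmenting-path formulation (O(k^3)).
#'
#' @param cost square numeric cost matrix (finite).
#' @return integer vector `p` with `p[i]` the column assigned to row `i`.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  k <- nrow(cost)
  stopifnot(k == ncol(cost), all(is.finite(cost)))
  # potentials u, v and column -> row matching p, with a virtual 0 column
  u <- numeric(k + 1)
  v <- numeric(k + 1)
  p <- integer(k + 1) # p[j+1] = row matched to column j (0 = none)
  way <- integer(k + 1)
  for (i in seq_len(k)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, k + 1)
    used <- rep(FALSE, k + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0
      for (j in seq_len(k)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) {
          minv[j + 1] <- cur
          way[j + 1] <- j0
        }
        if (minv[j + 1] < delta) {
          delta <- minv[j + 1]
          j1 <- j
        }
      }
      for (j in 0:k) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  out <- integer(k)
  out[p[-1]] <- seq_len(k)
  out
}

#' Resolve label switching across draws (Stephens' algorithm)
#'
#' Operates on draws that all have exactly `k` populated states. Each
#' draw's populated states are first canonically ordered by their RCN
#' value; Stephens' relabelling then iterates between (a) the average
#' assignment probabilities `q` over draws (one-hot, since the sampler
#' stores hard assignments) and (b) a per-draw permutation minimising the
#' Kullback-Leibler matching cost, solved as a k x k linear assignment.
#' Iteration stops at a fixed point or after `max_rounds` (with a warning).
#'
#' @param trace a filtered `rcn_trace` (see [filter_iterations()]).
#' @param k the populated-state count of every draw.
#' @param max_rounds maximum relabelling rounds (default 100).
#' @return list of class `rcn_relabeled`: `z` (draws x L, labels 1..k), `c`
#'   (draws x k), `pi` (k x k x draws), `loci`, `k`.
#' @export
relabel_states <- function(trace, k, max_rounds = 100) {
  stopifnot(inherits(trace, "rcn_trace"))
  if (!all(trace$n_pop == k))
    stop("all draws must have exactly k populated states; see ",
         "filter_iterations()")
  TT <- nrow(trace$z)
  L <- ncol(trace$z)

  # canonical per-draw compaction: populated states sorted by RCN value
  z <- matrix(0L, TT, L)
  cmat <- matrix(0, TT, k)
  pimat <- array(0, c(k, k, TT))
  for (t in seq_len(TT)) {
    states <- sort(unique(trace$z[t, ]))
    ord <- states[order(trace$c[t, states])]
    relab <- integer(max(ord))
    relab[ord] <- seq_len(k)
    z[t, ] <- relab[trace$z[t, ]]
    cmat[t, ] <- trace$c[t, ord]
    pimat[, , t] <- trace$pi[ord, ord, t]
  }

  eps <- 1e-10
  perms <- matrix(rep(seq_len(k), each = TT), TT, k) # current permutations
  onehot <- function(zt, lab) zt == lab
  for (round in seq_len(max_rounds)) {
    # q[l, j]: frequency of locus l carrying (relabelled) label j
    q <- matrix(0, L, k)
    for (t in seq_len(TT)) {
      pt <- perms[t, ]
      for (j in seq_len(k)) q[, pt[j]] <- q[, pt[j]] + (z[t, ] == j)
    }
    q <- pmin(pmax(q / TT, eps), 1 - eps)
    logq <- log(q)
    changed <- FALSE
    for (t in seq_len(TT)) {
      cost <- matrix(0, k, k)
      for (j in seq_len(k)) { # draw-label j -> target label j2
        sel <- z[t, ] == j
        if (any(sel)) cost[j, ] <- -colSums(logq[sel, , drop = FALSE])
      }
      pt <- solve_assignment(cost)
      if (!identical(pt, perms[t, ])) changed <- TRUE
      perms[t, ] <- pt
    }
    if (!changed) break
    if (round == max_rounds)
      warning("relabelling did not reach a fixed point after ", max_rounds,
              " rounds; returning the best permutations found")
  }

  for (t in seq_len(TT)) {
    pt <- perms[t, ]
    z[t, ] <- pt[z[t, ]]
    inv <- order(pt) # state that maps to label j
    cmat[t, ] <- cmat[t, inv]
    pimat[, , t] <- pimat[inv, inv, t]
  }
  structure(list(z = z, c = cmat, pi = pimat, loci = trace$loci, k = k,
                 ci_default = 0.95),
            class = "rcn_relabeled")
}

#' State-level RCN profile
#'
#' Summarisation method 2: per relabelled state, the MAP RCN (kernel
#' density mode) and equal-tailed credible interval; each locus is assigned
#' its modal relabelled state (ties to the lower state index) and reported
#' with that state's MAP RCN.
#'
#' @param relabeled an `rcn_relabeled` object from [relabel_states()].
#' @param ci_level credible level (default 0.95).
#' @return An `rcn_profile` with `$states` (per-state `map_rcn`, `ci_lo`,
#'   `ci_hi`) and `$profile` (per-locus `state`, `map_rcn`, CI of its
#'   state); `$method == "states"`.
#' @export
state_profile <- function(relabeled, ci_level = 0.95) {
  stopifnot(inherits(relabeled, "rcn_relabeled"))
  k <- relabeled$k
  a <- (1 - ci_level) / 2
  st <- t(vapply(seq_len(k), function(j) {
    v <- relabeled$c[, j]
    c(density_mode(v), quantile(v, c(a, 1 - a), names = FALSE))
  }, numeric(3)))
  states <- data.frame(state = seq_len(k), map_rcn = st[, 1],
                       ci_lo = pmin(st[, 2], st[, 1]),
                       ci_hi = pmax(st[, 3], st[, 1]))
  modal <- apply(relabeled$z, 2, function(zl) {
    tab <- tabulate(zl, k)
    which.max(tab) # first max: ties break to the lower state index
  })
  prof <- relabeled$loci[c("chrom", "pos", "strand")]
  prof$state <- as.integer(modal)
  prof$map_rcn <- states$map_rcn[modal]
  prof$ci_lo <- states$ci_lo[modal]
  prof$ci_hi <- states$ci_hi[modal]
  structure(list(profile = prof, states = states, method = "states",
                 n_states = k, ci_level = ci_level),
            class = "rcn_profile")
}

#' @export
print.rcn_profile <- function(x, ...) {
  cat(sprintf("rcn_profile (%s): %d loci, %d state(s)\n", x$method,
              nrow(x$profile), x$n_states))
  print(utils::head(x$profile))
  invisible(x)
}

#' Write an RCN profile as TSV (plus a JSON state summary)
#'
#' @param profile an `rcn_profile`.
#' @param path output TSV path; for state-based profiles a `.json` sidecar
#'   with the per-state summary is written alongside.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "rcn_profile"))
  write.table(profile$profile, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(profile$states))
    jsonlite::write_json(
      list(n_states = profile$n_states, ci_level = profile$ci_level,
           states = profile$states),
      paste0(sub("\\.[^.]*$", "", path), ".json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
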