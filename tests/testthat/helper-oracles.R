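# Independent oracles used across the test files. Everything here works
# from first principles (numerical quadrature, explicit enumeration of the
# 12-state chain via the full transition matrix) and never reuses the
# package's fast paths it is checking.

logsumexp_ <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# random valid constrained mixture under a local RNG stream
rand_mixture <- function() {
  w <- stats::rgamma(3, shape = c(4, 4, 1))
  w <- w / sum(w)
  beta_mixture(w[1], w[2], w[3],
               alpha_H = 1 + stats::runif(1, 0, 14),
               beta_L = 1 + stats::runif(1, 0, 14))
}

# mixture density written out locally (independent of dbeta_mixture)
mix_density <- function(theta, mix) {
  mix$w_H * stats::dbeta(theta, mix$alpha_H, 1) +
    mix$w_L * stats::dbeta(theta, 1, mix$beta_L) +
    mix$w_unif * stats::dunif(theta)
}

# quadrature of the directional emission integral: two separable 1-D
# integrals of Binom times the relevant beta component
quad_dir_emission <- function(m1, u1, m2, u2, mix1, mix2, dir) {
  int1 <- function(shape1, shape2) {
    stats::integrate(function(t) {
      stats::dbinom(m1, m1 + u1, t) * stats::dbeta(t, shape1, shape2)
    }, 0, 1, rel.tol = 1e-11, abs.tol = 0)$value
  }
  int2 <- function(shape1, shape2) {
    stats::integrate(function(t) {
      stats::dbinom(m2, m2 + u2, t) * stats::dbeta(t, shape1, shape2)
    }, 0, 1, rel.tol = 1e-11, abs.tol = 0)$value
  }
  if (dir == "U") {
    int1(mix1$alpha_H, 1) * int2(1, mix2$beta_L)
  } else {
    int1(1, mix1$beta_L) * int2(mix2$alpha_H, 1)
  }
}

# quadrature of the no-change emission: one shared level integrated against
# the normalized product of the two mixture densities
quad_noch_emission <- function(m1, u1, m2, u2, mix1, mix2) {
  num <- stats::integrate(function(t) {
    stats::dbinom(m1, m1 + u1, t) * stats::dbinom(m2, m2 + u2, t) *
      mix_density(t, mix1) * mix_density(t, mix2)
  }, 0, 1, rel.tol = 1e-11, abs.tol = 0)$value
  z <- stats::integrate(function(t) {
    mix_density(t, mix1) * mix_density(t, mix2)
  }, 0, 1, rel.tol = 1e-11, abs.tol = 0)$value
  num / z
}

# random valid dual-unit HMM parameters
rand_params <- function() {
  self <- stats::runif(6, 0.2, 0.95)
  exit <- matrix(stats::rgamma(36, 1), 6, 6)
  exit <- sweep(exit, 1, rowSums(exit), "/") * (1 - self)
  init <- stats::rgamma(6, 1)
  hmm_params(self, exit, init / sum(init))
}

# random emission matrix (log scale) for a toy chain
rand_emissions <- function(L, sd = 2) {
  em <- matrix(stats::rnorm(3 * L, sd = sd), L, 3)
  colnames(em) <- c("U", "D", "N")
  em
}

# log-probability of one explicit CpG-state path (state index 1..6 per
# site), expanding every gap run base by base through the full 12x12
# transition matrix
oracle_path_logprob <- function(A, init, em, gaps, states) {
  L <- length(states)
  lp <- log(init[states[1]]) + em[1, (states[1] + 1) %/% 2]
  for (t in seq_len(L - 1)) {
    i <- states[t]; j <- states[t + 1]
    g <- 6 + i
    lp <- lp + log(A[i, g])
    if (gaps[t] > 1) lp <- lp + (gaps[t] - 1) * log(A[g, g])
    lp <- lp + log(A[g, j]) + em[t + 1, (j + 1) %/% 2]
  }
  lp
}

# total likelihood by exhaustive enumeration of all 6^L CpG-state paths
oracle_forward_loglik <- function(params, em, gaps) {
  A <- transition_matrix(params)
  L <- nrow(em)
  grid <- as.matrix(expand.grid(rep(list(1:6), L)))
  lps <- apply(grid, 1, function(st)
    oracle_path_logprob(A, params$init, em, gaps, st))
  logsumexp_(lps)
}

# best constrained path probability by enumeration over the 2^L unit
# assignments for a fixed direction labelling (1 = U, 2 = D, 3 = N)
oracle_constrained_max <- function(params, em, gaps, labels) {
  A <- transition_matrix(params)
  L <- length(labels)
  grid <- as.matrix(expand.grid(rep(list(0:1), L)))
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    states <- (labels - 1L) * 2L + grid[r, ] + 1L
    best <- max(best, oracle_path_logprob(A, params$init, em, gaps, states))
  }
  best
}

# effective CpG-to-CpG kernel by explicit matrix products over the silent
# gap block of the full transition matrix
oracle_effective_kernel <- function(params, d) {
  A <- transition_matrix(params)
  M <- A[1:6, 7:12, drop = FALSE]
  if (d > 1) for (k in seq_len(d - 1)) M <- M %*% A[7:12, 7:12, drop = FALSE]
  M %*% A[7:12, 1:6, drop = FALSE]
}

# additive segment score as documented for extract_dmrs, assembled from
# oracle_effective_kernel instead of the package's increment code
oracle_segment_score <- function(em, gaps, params, s, e, dir) {
  x <- if (dir == "Up") 1L else 2L
  sx <- (x - 1L) * 2L + 1L
  sn <- 5L
  kern <- lapply(seq_along(gaps), function(t)
    log(oracle_effective_kernel(params, gaps[t])))
  mx <- function(t, si, sj) max(kern[[t]][si + 0:1, sj + 0:1])
  sc <- sum(em[s:e, x] - em[s:e, 3])
  if (e > s) for (t in s:(e - 1)) sc <- sc + mx(t, sx, sx) - mx(t, sn, sn)
  lpi <- log(params$init)
  sc <- sc + if (s == 1) max(lpi[sx + 0:1]) - max(lpi[sn + 0:1]) else
    mx(s - 1, sn, sx) - mx(s - 1, sn, sn)
  sc + if (e == length(gaps) + 1) 0 else mx(e, sx, sn) - mx(e, sn, sn)
}

# exhaustive iterated best-segment extraction per direction, then
# cross-direction overlap resolution by the constrained-path score
oracle_extract <- function(em, gaps, params, threshold = 0) {
  L <- nrow(em)
  out <- list()
  for (dir in c("Up", "Down")) {
    allowed <- rep(TRUE, L)
    repeat {
      best <- -Inf; bs <- NA; be <- NA
      for (s in 1:L) for (e in s:L) {
        if (!all(allowed[s:e])) next
        sc <- oracle_segment_score(em, gaps, params, s, e, dir)
        if (sc > best) { best <- sc; bs <- s; be <- e }
      }
      if (!is.finite(best) || best <= threshold) break
      out[[length(out) + 1L]] <- list(dir = dir, s = bs, e = be)
      allowed[bs:be] <- FALSE
    }
  }
  if (length(out) == 0) {
    return(data.frame(first_site = integer(), last_site = integer(),
                      direction = character(), score = numeric()))
  }
  res <- data.frame(
    first_site = vapply(out, function(z) z$s, 0L),
    last_site = vapply(out, function(z) z$e, 0L),
    direction = vapply(out, function(z) z$dir, ""),
    stringsAsFactors = FALSE)
  res$score <- vapply(seq_len(nrow(res)), function(i) {
    labels <- rep(3L, L)
    labels[res$first_site[i]:res$last_site[i]] <-
      if (res$direction[i] == "Up") 1L else 2L
    oracle_constrained_max(params, em, gaps, labels) -
      oracle_constrained_max(params, em, gaps, rep(3L, L))
  }, 0.0)
  res <- res[res$score > threshold, , drop = FALSE]
  # overlap resolution: keep the higher score of any Up/Down overlap
  keep <- rep(TRUE, nrow(res))
  if (nrow(res) > 1) {
    for (i in seq_len(nrow(res) - 1)) {
      for (j in (i + 1):nrow(res)) {
        if (!keep[i] || !keep[j]) next
        if (res$direction[i] != res$direction[j] &&
            res$first_site[i] <= res$last_site[j] &&
            res$last_site[i] >= res$first_site[j]) {
          if (res$score[i] >= res$score[j]) keep[j] <- FALSE else keep[i] <- FALSE
        }
      }
    }
  }
  res <- res[keep, , drop = FALSE]
  res[order(-res$score, res$first_site), , drop = FALSE]
}

# tiny deterministic count table used by several I/O tests
toy_table <- function() {
  cpg_table(chrom = c("chr1", "chr1", "chr1", "chr2"),
            pos = c(100L, 150L, 200L, 50L),
            m1 = c(5L, 3L, 0L, 2L), u1 = c(0L, 3L, 8L, 2L),
            m2 = c(0L, 3L, 8L, 1L), u2 = c(5L, 3L, 0L, 3L))
}
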