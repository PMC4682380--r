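test_that("default parameters are row-stochastic, seeded, and structural", {
  p <- default_hmm(seed = 4)
  A <- transition_matrix(p)
  expect_equal(rowSums(A), rep(1, 12), tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(transition_matrix(default_hmm(seed = 4)), A)
  expect_false(identical(transition_matrix(default_hmm(seed = 5)), A))
  # structural zeros: CpG states reach only their own gap state
  expect_equal(unname(A[1:6, 1:6]), matrix(0, 6, 6))
  for (i in 1:6) expect_equal(A[i, 6 + i], 1)
  # gap states never jump to another gap state
  offdiag <- A[7:12, 7:12]; diag(offdiag) <- 0
  expect_equal(unname(offdiag), matrix(0, 6, 6))
  # jitter is shared between Up and Down (sample-swap equivariance):
  # permuting the Up and Down blocks leaves the matrix unchanged
  perm <- c(3, 4, 1, 2, 5, 6)
  expect_equal(p$self[perm], p$self, ignore_attr = TRUE)
  expect_equal(unname(p$exit[perm, perm]), unname(p$exit))
})

test_that("effective kernel follows the geometric closed form", {
  p <- default_hmm(seed = 1)
  # single-direction toy check: entry = self^(d-1) * exit
  for (d in c(1, 2, 5, 40)) {
    K <- effective_transition(p, d)[1:6, 1:6]
    expect_equal(K[3, 5], p$self[3]^(d - 1) * p$exit[3, 5], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # d = 1 is the pure exit step
  expect_equal(unname(effective_transition(p, 1)[1:6, 1:6]), unname(p$exit))
  # d = 0 is the (structurally empty) direct CpG block
  expect_equal(unname(effective_transition(p, 0)), matrix(0, 12, 12))
  expect_error(effective_transition(p, -1), "non-negative")
})

test_that("effective kernel equals explicit silent-chain marginalization", {
  set.seed(11)
  for (rep in 1:5) {
    p <- rand_params()
    for (d in c(1, 2, 3, 7, 10, 17)) {
      expect_equal(unname(effective_transition(p, d)[1:6, 1:6]),
                   unname(oracle_effective_kernel(p, d)), tolerance = 1e-12)
    }
  }
})

test_that("forward-backward: single site, free emissions, posterior norm", {
  p <- default_hmm(seed = 2)
  em1 <- matrix(c(1, -1, 0.5), 1, 3, dimnames = list(NULL, c("U", "D", "N")))
  fb <- forward_backward(em1, integer(0), p)
  # single site: posterior is init * emission, normalized; loglik matches
  w <- p$init * exp(em1[1, c(1, 1, 2, 2, 3, 3)])
  expect_equal(fb$loglik, log(sum(w)))
  expect_equal(unname(fb$gamma[1, ]), unname(w / sum(w)), tolerance = 1e-12)
  # all-zero emissions on a single site: loglik is exactly 0
  em0 <- matrix(0, 1, 3, dimnames = list(NULL, c("U", "D", "N")))
  expect_equal(forward_backward(em0, integer(0), p)$loglik, 0)
  expect_error(forward_backward(em0[0, , drop = FALSE], integer(0), p), "empty")
})

test_that("forward equals exhaustive path enumeration on small chains", {
  set.seed(21)
  for (rep in 1:6) {
    L <- sample(2:5, 1)
    p <- rand_params()
    em <- rand_emissions(L)
    gaps <- sample(1:10, L - 1, replace = TRUE)
    fb <- forward_backward(em, gaps, p)
    oracle <- oracle_forward_loglik(p, em, gaps)
    expect_equal(fb$loglik, oracle, tolerance = 1e-9)
    expect_equal(fb$loglik_backward, fb$loglik, tolerance = 1e-9)
    expect_equal(rowSums(fb$posterior), rep(1, L), tolerance = 1e-9,
                 ignore_attr = TRUE)
    # with uninformative emissions the posterior is transition-driven
    fb0 <- forward_backward(matrix(0, L, 3,
                                   dimnames = list(NULL, c("U", "D", "N"))),
                            gaps, p)
    expect_equal(fb0$loglik, oracle_forward_loglik(
      p, matrix(0, L, 3), gaps), tolerance = 1e-9)
  }
})

test_that("Baum-Welch increases the likelihood and stops at a fixed point", {
  set.seed(31)
  L <- 400
  em <- rand_emissions(L, sd = 1.5)
  gaps <- sample(1:60, L - 1, replace = TRUE)
  fit <- fit_transitions(em, gaps, init = default_hmm(1), tol = 1e-4,
                         max_iter = 500)
  expect_true(attr(fit, "converged"))
  ll <- attr(fit, "fit")$loglik
  expect_true(all(diff(ll) >= -1e-10))
  # refitting from the converged point changes the likelihood < tol
  refit <- fit_transitions(em, gaps, init = fit, tol = 1e-4, max_iter = 5)
  ll2 <- attr(refit, "fit")$loglik
  expect_lt(abs(diff(ll2)[1]), 1e-4)
  expect_error(fit_transitions(em, gaps, max_iter = 0), "max_iter")
  # structural integrity preserved after learning
  A <- transition_matrix(fit)
  expect_equal(rowSums(A), rep(1, 12), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unname(A[1:6, 1:6]), matrix(0, 6, 6))
})

test_that("Baum-Welch recovers dwell parameters from simulated chains", {
  # simulate CpG-state and gap sequences from known transitions with
  # near-deterministic emissions, then learn from a default start
  set.seed(41)
  true_self <- c(0.7, 0.7, 0.6, 0.6, 0.9, 0.9)
  exit <- matrix(0, 6, 6)
  for (i in 1:6) {
    w <- rep(0.02, 6)
    w[i] <- 1
    same_dir <- 2 * ((i + 1) %/% 2) - 1:0
    w[same_dir] <- w[same_dir] + 0.5
    exit[i, ] <- w / sum(w) * (1 - true_self[i])
  }
  truth <- hmm_params(true_self, exit, c(0.02, 0.02, 0.02, 0.02, 0.46, 0.46))
  L <- 5000
  states <- integer(L); gaps <- integer(L - 1)
  states[1] <- sample.int(6, 1, prob = truth$init)
  for (t in seq_len(L - 1)) {
    a <- truth$self[states[t]]
    gaps[t] <- 1L + rgeom(1, 1 - a)
    states[t + 1] <- sample.int(6, 1, prob = truth$exit[states[t], ])
  }
  em <- matrix(-25, L, 3, dimnames = list(NULL, c("U", "D", "N")))
  em[cbind(seq_len(L), (states + 1L) %/% 2L)] <- 0
  fit <- fit_transitions(em, gaps, init = default_hmm(3), tol = 1e-6,
                         max_iter = 200)
  # NoCh dwell (both units were simulated at 0.9) recovered within 0.05
  expect_lt(abs(fit$self[5] - 0.9), 0.05)
  expect_lt(abs(fit$self[6] - 0.9), 0.05)
})

test_that("chromosomes combine as independent chains in one fit", {
  set.seed(51)
  em <- list(rand_emissions(60), rand_emissions(40))
  gaps <- list(sample(1:30, 59, TRUE), sample(1:30, 39, TRUE))
  fit <- fit_transitions(em, gaps, init = default_hmm(1), max_iter = 10)
  ll <- attr(fit, "fit")$loglik
  expect_true(all(diff(ll) >= -1e-10))
  # total likelihood at the initial parameters is the sum over chains
  p0 <- default_hmm(1)
  expect_equal(ll[1],
               forward_backward(em[[1]], gaps[[1]], p0)$loglik +
                 forward_backward(em[[2]], gaps[[2]], p0)$loglik,
               tolerance = 1e-9)
})
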