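test_that("region scores: null regions, additivity, input validation", {
  p <- default_hmm(seed = 1)
  L <- 6
  em0 <- matrix(0, L, 3, dimnames = list(NULL, c("U", "D", "N")))
  gaps <- rep(5L, L - 1)
  # indistinguishable emissions and direction-symmetric transitions: the
  # constrained and NoCh paths have identical probability, score exactly 0
  expect_equal(score_region(em0, gaps, p, 3, 4, "Up"), 0)
  # with direction-sticky transitions the boundary switches cost, score < 0
  sticky_exit <- matrix(0.01, 6, 6)
  for (i in 1:6) sticky_exit[i, i] <- 0.25
  sticky_exit <- sweep(sticky_exit, 1, rowSums(sticky_exit), "/") * 0.7
  sticky <- hmm_params(rep(0.3, 6), sticky_exit, rep(1 / 6, 6))
  expect_lt(score_region(em0, gaps, sticky, 3, 4, "Up"), 0)
  # a single-site region with emission advantage splits into
  # emission gain + boundary penalty
  em1 <- em0; em1[3, "U"] <- 10
  pen <- score_region(em0, gaps, p, 3, 3, "Up")
  expect_equal(score_region(em1, gaps, p, 3, 3, "Up"), 10 + pen,
               tolerance = 1e-12)
  expect_error(score_region(em0, gaps, p, 4, 3, "Up"), "before start")
  expect_error(score_region(em0, gaps, p, 3, 4, "NoCh"), "Up.*Down")
})

test_that("region scores match exhaustive constrained-path enumeration", {
  set.seed(61)
  for (rep in 1:6) {
    L <- sample(3:6, 1)
    p <- rand_params()
    em <- rand_emissions(L)
    gaps <- sample(1:8, L - 1, replace = TRUE)
    s <- sample(1:L, 1); e <- s + sample.int(L - s + 1, 1) - 1L
    dir <- sample(c("Up", "Down"), 1)
    labels <- rep(3L, L)
    labels[s:e] <- if (dir == "Up") 1L else 2L
    oracle <- oracle_constrained_max(p, em, gaps, labels) -
      oracle_constrained_max(p, em, gaps, rep(3L, L))
    expect_equal(score_region(em, gaps, p, s, e, dir), oracle,
                 tolerance = 1e-9)
  }
})

test_that("no DMRs are reported when no site favors a direction", {
  p <- default_hmm(seed = 1)
  L <- 12
  em <- matrix(0, L, 3, dimnames = list(NULL, c("U", "D", "N")))
  em[, c("U", "D")] <- -abs(matrix(rnorm(2 * L), L, 2))
  out <- extract_dmrs(em, rep(3L, L - 1), seq_len(L) * 10L, p)
  expect_equal(nrow(out), 0)
})

test_that("a strong block in a flat background is recovered exactly once", {
  set.seed(71)
  p <- default_hmm(seed = 1)
  L <- 60
  em <- matrix(0, L, 3, dimnames = list(NULL, c("U", "D", "N")))
  em[, "U"] <- rnorm(L, -4, 0.3)
  em[, "D"] <- rnorm(L, -4, 0.3)
  block <- 25:34
  em[block, "U"] <- rnorm(10, 6, 0.3)
  pos <- cumsum(c(100L, sample(2:50, L - 1, TRUE)))
  out <- extract_dmrs(em, diff(pos) - 1L, pos, p)
  expect_equal(nrow(out), 1)
  expect_equal(out$direction, "Up")
  expect_equal(out$first_site, 25L)
  expect_equal(out$last_site, 34L)
  expect_equal(out$start, pos[25])
  expect_equal(out$end, pos[34] + 2L)
  expect_equal(out$n_cpg, 10L)
  # reported score is recomputable by score_region
  expect_equal(out$score,
               score_region(em, diff(pos) - 1L, p, 25, 34, "Up"),
               tolerance = 1e-9)
})

test_that("extraction matches the exhaustive iterated-argmax oracle", {
  set.seed(81)
  for (rep in 1:8) {
    L <- sample(5:8, 1)
    p <- rand_params()
    em <- rand_emissions(L, sd = 3)
    gaps <- sample(1:6, L - 1, replace = TRUE)
    pos <- cumsum(c(50L, gaps + 1L))
    got <- extract_dmrs(em, gaps, pos, p)
    want <- oracle_extract(em, gaps, p)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$first_site, want$first_site)
      expect_equal(got$last_site, want$last_site)
      expect_equal(got$direction, want$direction)
      expect_equal(got$score, want$score, tolerance = 1e-9)
    }
  }
})

test_that("reported DMRs are disjoint with scores above threshold", {
  set.seed(91)
  L <- 300
  p <- default_hmm(seed = 2)
  em <- rand_emissions(L, sd = 4)
  gaps <- sample(1:40, L - 1, replace = TRUE)
  pos <- cumsum(c(1L, gaps + 1L))
  for (thr in c(0, 5)) {
    out <- extract_dmrs(em, gaps, pos, p, threshold = thr)
    expect_true(all(out$score > thr))
    if (nrow(out) > 1) {
      bysite <- out[order(out$first_site), ]
      expect_true(all(bysite$first_site[-1] > bysite$last_site[-nrow(bysite)]))
    }
    for (i in seq_len(nrow(out))) {
      expect_equal(out$score[i],
                   score_region(em, gaps, p, out$first_site[i],
                                out$last_site[i], out$direction[i]),
                   tolerance = 1e-9)
    }
  }
})

test_that("detect_dmrs handles chromosomes independently and validates input", {
  set.seed(101)
  mix <- beta_mixture(0.5, 0.45, 0.05, 8, 8)
  n <- 80
  tab <- cpg_table(rep(c("chrA", "chrB"), each = n / 2),
                   rep(cumsum(sample(10:40, n / 2, TRUE)), 2),
                   m1 = rbinom(n, 10, 0.85), u1 = 0L,
                   m2 = rbinom(n, 10, 0.85), u2 = 0L)
  tab$u1 <- 10L - tab$m1; tab$u2 <- 10L - tab$m2
  tab <- cpg_table(tab$chrom, tab$pos, tab$m1, tab$u1, tab$m2, tab$u2)
  p <- default_hmm(seed = 1)
  out <- detect_dmrs(tab, p, mix, mix)
  expect_true(all(out$chrom %in% c("chrA", "chrB")))
  expect_true(all(diff(out$score) <= 1e-12))
  expect_error(detect_dmrs(tab, p), "mix1 and mix2")
  expect_error(detect_dmrs(tab, p, emissions = "legacy"), "pseudo")
})
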