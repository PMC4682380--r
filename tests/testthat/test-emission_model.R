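test_that("pure-uniform mixtures give the forced analytic NoCh value", {
  unif <- beta_mixture(0, 0, 1, 1, 1)
  tab <- cpg_table("chr1", 100L, 0L, 1L, 0L, 1L)
  em <- compute_emissions(tab, unif, unif)
  # E_N = int (1-t)^2 dt = 1/3 with Z = 1
  expect_equal(unname(exp(em[1, "N"])), 1 / 3, tolerance = 1e-12)
  expect_equal(attr(em, "logZ"), 0, tolerance = 1e-12)
})

test_that("a site with no reads emits probability 1 in every state", {
  mix1 <- beta_mixture(0.5, 0.45, 0.05, 8, 8)
  mix2 <- beta_mixture(0.4, 0.5, 0.1, 5, 11)
  tab <- cpg_table("chr1", c(100L, 150L), c(0L, 3L), c(0L, 1L),
                   c(0L, 0L), c(0L, 4L))
  em <- compute_emissions(tab, mix1, mix2)
  expect_equal(unname(unclass(em)[1, ]), c(0, 0, 0), tolerance = 1e-12)
  leg <- compute_legacy_emissions(tab, pseudo = 1)
  expect_equal(unname(unclass(leg)[1, ]), c(0, 0, 0), tolerance = 1e-12)
})

test_that("closed forms match quadrature of the defining integrals", {
  set.seed(301)
  for (rep in 1:40) {
    mix1 <- rand_mixture(); mix2 <- rand_mixture()
    m1 <- sample(0:20, 1); u1 <- sample(0:20, 1)
    m2 <- sample(0:20, 1); u2 <- sample(0:20, 1)
    tab <- cpg_table("chr1", 100L, m1, u1, m2, u2)
    em <- compute_emissions(tab, mix1, mix2)
    expect_equal(unname(exp(em[1, "U"])), quad_dir_emission(m1, u1, m2, u2, mix1, mix2, "U"),
                 tolerance = 1e-6)
    expect_equal(unname(exp(em[1, "D"])), quad_dir_emission(m1, u1, m2, u2, mix1, mix2, "D"),
                 tolerance = 1e-6)
    expect_equal(unname(exp(em[1, "N"])), quad_noch_emission(m1, u1, m2, u2, mix1, mix2),
                 tolerance = 1e-6)
  }
})

test_that("each emission distribution sums to 1 over the count grid", {
  set.seed(302)
  mix1 <- rand_mixture(); mix2 <- rand_mixture()
  for (n in list(c(4, 6), c(10, 0), c(7, 7))) {
    grid <- expand.grid(m1 = 0:n[1], m2 = 0:n[2])
    tab <- cpg_table("chr1", seq_len(nrow(grid)) * 10L,
                     grid$m1, n[1] - grid$m1, grid$m2, n[2] - grid$m2)
    em <- unclass(compute_emissions(tab, mix1, mix2))
    expect_equal(sum(exp(em[, "U"])), 1, tolerance = 1e-9)
    expect_equal(sum(exp(em[, "D"])), 1, tolerance = 1e-9)
    expect_equal(sum(exp(em[, "N"])), 1, tolerance = 1e-9)
  }
})

test_that("swapping samples and mixtures mirrors Up and Down exactly", {
  set.seed(303)
  mix1 <- rand_mixture(); mix2 <- rand_mixture()
  n <- 30
  tab <- cpg_table("chr1", seq_len(n) * 10L,
                   rbinom(n, 10, 0.8), rbinom(n, 5, 0.5),
                   rbinom(n, 10, 0.2), rbinom(n, 5, 0.5))
  swapped <- cpg_table(tab$chrom, tab$pos, tab$m2, tab$u2, tab$m1, tab$u1)
  em <- unclass(compute_emissions(tab, mix1, mix2))
  ems <- unclass(compute_emissions(swapped, mix2, mix1))
  expect_equal(ems[, "U"], em[, "D"], tolerance = 1e-12)
  expect_equal(ems[, "D"], em[, "U"], tolerance = 1e-12)
  expect_equal(ems[, "N"], em[, "N"], tolerance = 1e-12)
})

test_that("legacy emissions reproduce the printed formulas and degeneracy", {
  # theta1_U = (m1 + pseudo) / (n1 + pseudo) at m1 = 5, n1 = 10, pseudo = 1
  tab <- cpg_table("chr1", 100L, 5L, 5L, 2L, 8L)
  em <- compute_legacy_emissions(tab, pseudo = 1)
  exp_U <- dbinom(5, 10, 6 / 11, log = TRUE) + dbinom(2, 10, 2 / 11, log = TRUE)
  expect_equal(unname(em[1, "U"]), exp_U, tolerance = 1e-12)
  exp_D <- dbinom(5, 10, 5 / 11, log = TRUE) + dbinom(2, 10, 3 / 11, log = TRUE)
  expect_equal(unname(em[1, "D"]), exp_D, tolerance = 1e-12)
  exp_N <- dbinom(5, 10, 7 / 20, log = TRUE) + dbinom(2, 10, 7 / 20, log = TRUE)
  expect_equal(unname(em[1, "N"]), exp_N, tolerance = 1e-12)

  # pseudo = 0 cannot discriminate direction: E_U = E_D at every site
  tab2 <- cpg_table("chr1", c(100L, 200L, 300L), c(5L, 9L, 0L), c(5L, 1L, 9L),
                    c(2L, 0L, 4L), c(8L, 9L, 4L))
  em0 <- compute_legacy_emissions(tab2, pseudo = 0)
  expect_equal(em0[, "U"], em0[, "D"], tolerance = 1e-12)

  # a maximally differential site: Up dominates, and every value matches
  # direct evaluation of the plug-in binomials (note the model's known
  # weakness: the pooled NoCh level 0.5 fits neither sample, so even the
  # opposite direction outranks NoCh here)
  tab3 <- cpg_table("chr1", 100L, 10L, 0L, 0L, 10L)
  em3 <- compute_legacy_emissions(tab3, pseudo = 1)
  expect_equal(unname(em3[1, "U"]), 0, tolerance = 1e-9)
  expect_equal(unname(em3[1, "D"]),
               dbinom(10, 10, 10 / 11, log = TRUE) +
                 dbinom(0, 10, 1 / 11, log = TRUE), tolerance = 1e-9)
  expect_equal(unname(em3[1, "N"]), 2 * dbinom(10, 10, 0.5, log = TRUE),
               tolerance = 1e-9)
  expect_gt(em3[1, "U"], em3[1, "D"])
  expect_gt(em3[1, "U"], em3[1, "N"])
  expect_error(compute_legacy_emissions(tab3, pseudo = -1))
})
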