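#' Constrained three-component beta mixture of methylation levels
#'
#' Genome-wide methylation levels are bimodal: most CpGs are either highly
#' methylated or essentially unmethylated, with a small background of
#' intermediate levels. The prior used by the emission model is a mixture of
#' a high beta mode `Beta(alpha_H, 1)`, a low beta mode `Beta(1, beta_L)` and
#' a uniform background `Beta(1, 1)`, with weights summing to 1. The fixed
#' unit shapes (`beta_H = alpha_L = 1`, shapes >= 1) make each beta component
#' cover exactly one mode and keep the no-change emission integral in closed
#' form.
#'
#' @param w_H,w_L,w_unif non-negative component weights summing to 1.
#' @param alpha_H shape of the high component (`>= 1`; mean
#'   `alpha_H/(alpha_H+1) > 1/2`).
#' @param beta_L shape of the low component (`>= 1`; mean
#'   `1/(1+beta_L) < 1/2`).
#' @return A `beta_mixture` object.
#' @export
beta_mixture <- function(w_H, w_L, w_unif, alpha_H, beta_L) {
  stopifnot(w_H >= 0, w_L >= 0, w_unif >= 0)
  if (abs(w_H + w_L + w_unif - 1) > 1e-8) {
    stop("component weights must sum to 1", call. = FALSE)
  }
  if (alpha_H < 1 || beta_L < 1) {
    stop("shape parameters must satisfy alpha_H >= 1 and beta_L >= 1", call. = FALSE)
  }
  structure(list(w_H = unname(w_H), w_L = unname(w_L), w_unif = unname(w_unif),
                 alpha_H = unname(alpha_H), beta_L = unname(beta_L)),
            class = "beta_mixture")
}

#' @export
print.beta_mixture <- function(x, ...) {
  cat(sprintf(
    "beta_mixture: w_H=%.4f w_L=%.4f w_unif=%.4f | alpha_H=%.3f (beta_H=1) beta_L=%.3f (alpha_L=1)\n",
    x$w_H, x$w_L, x$w_unif, x$alpha_H, x$beta_L))
  invisible(x)
}

# (alpha, beta) pairs of the three components in canonical order H, L, unif
mixture_components <- function(mix) {
  list(w = c(H = mix$w_H, L = mix$w_L, unif = mix$w_unif),
       alpha = c(H = mix$alpha_H, L = 1, unif = 1),
       beta = c(H = 1, L = mix$beta_L, unif = 1))
}

#' Mixture density of methylation levels
#'
#' @param theta methylation levels in `[0, 1]`.
#' @param mix a [beta_mixture()].
#' @return Density values.
#' @export
dbeta_mixture <- function(theta, mix) {
  mix$w_H * stats::dbeta(theta, mix$alpha_H, 1) +
    mix$w_L * stats::dbeta(theta, 1, mix$beta_L) +
    mix$w_unif
}

#' Log beta-binomial marginal probability of a count pair
#'
#' The probability of observing `m` methylated and `u` unmethylated reads
#' when the binomial success probability is integrated against a
#' `Beta(alpha, beta)` prior:
#' `log [ C(m+u, m) B(m+alpha, u+beta) / B(alpha, beta) ]`.
#' Vectorized over `m` and `u`.
#'
#' @param m,u non-negative integer counts.
#' @param alpha,beta positive beta shape parameters.
#' @return Log probabilities (finite for all valid inputs).
#' @export
log_beta_binomial_marginal <- function(m, u, alpha, beta) {
  if (any(alpha <= 0) || any(beta <= 0)) {
    stop("shape parameters must be positive", call. = FALSE)
  }
  if (any(m < 0) || any(u < 0)) stop("counts must be non-negative", call. = FALSE)
  lchoose(m + u, m) + lbeta(m + alpha, u + beta) - lbeta(alpha, beta)
}

#' Subsample covered CpG sites for mixture fitting
#'
#' Draws a uniform random subset (without replacement) of the sites with at
#' least one read in the chosen sample. Fitting on a few thousand sites is
#' enough to pin down the five free mixture parameters, so the full table
#' need not be used. If fewer eligible sites exist than requested, all are
#' returned.
#'
#' @param table a [cpg_table()].
#' @param sample_index which sample's counts to return, 1 or 2.
#' @param n_sites number of sites to draw (default 10000).
#' @param seed integer seed making the draw reproducible.
#' @param site_idx optional integer row indices to use instead of drawing
#'   (used to share one site set between the two samples; rows without
#'   coverage in this sample are dropped).
#' @return A data frame with columns `m`, `u` and attribute `idx` (row
#'   indices drawn).
#' @export
subsample_sites <- function(table, sample_index, n_sites = 10000, seed = 1,
                            site_idx = NULL) {
  stopifnot(sample_index %in% c(1, 2), n_sites >= 1)
  m <- table[[paste0("m", sample_index)]]
  u <- table[[paste0("u", sample_index)]]
  covered <- which(m + u >= 1)
  if (length(covered) == 0) stop("no site with coverage in sample ", sample_index, call. = FALSE)
  if (is.null(site_idx)) {
    if (length(covered) <= n_sites) {
      idx <- covered
    } else {
      idx <- local({
        old <- .Random.seed_save()
        on.exit(.Random.seed_restore(old))
        set.seed(seed)
        sort(sample(covered, n_sites))
      })
    }
  } else {
    idx <- intersect(site_idx, covered)
    if (length(idx) == 0) stop("no site with coverage in sample ", sample_index, call. = FALSE)
  }
  out <- data.frame(m = m[idx], u = u[idx])
  attr(out, "idx") <- idx
  out
}

# save/restore the RNG state so seeded subroutines do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# L x 3 matrix of per-component log beta-binomial marginals (H, L, unif)
component_log_marginals <- function(m, u, mix) {
  cmp <- mixture_components(mix)
  cbind(H = log_beta_binomial_marginal(m, u, cmp$alpha["H"], cmp$beta["H"]),
        L = log_beta_binomial_marginal(m, u, cmp$alpha["L"], cmp$beta["L"]),
        unif = log_beta_binomial_marginal(m, u, cmp$alpha["unif"], cmp$beta["unif"]))
}

#' Posterior component responsibilities for one or more count pairs
#'
#' Posterior probability that each site's methylation level was drawn from
#' the high, low or uniform component, proportional to
#' `w_c * BetaBinom(m, u | alpha_c, beta_c)`. A site with no reads returns
#' the prior weights.
#'
#' @param m,u non-negative integer count vectors.
#' @param mix a [beta_mixture()].
#' @return A matrix with columns `H`, `L`, `unif`, rows summing to 1.
#' @export
component_responsibilities <- function(m, u, mix) {
  lm <- component_log_marginals(m, u, mix)
  lw <- sweep(lm, 2, log(c(mix$w_H, mix$w_L, mix$w_unif)), "+")
  r <- exp(lw - row_logsumexp(lw))
  r / rowSums(r)
}

# numerically stable log(sum(exp(x))) over rows of a matrix
row_logsumexp <- function(x) {
  mx <- do.call(pmax, c(as.data.frame(x), na.rm = TRUE))
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(x - mx)))
}

# observed-data log-likelihood of counts under the mixture
mixture_loglik <- function(m, u, mix) {
  lm <- component_log_marginals(m, u, mix)
  lw <- sweep(lm, 2, log(c(mix$w_H, mix$w_L, mix$w_unif)), "+")
  sum(row_logsumexp(lw))
}

#' Fit the constrained beta-binomial mixture by EM
#'
#' Maximum likelihood estimation of the three-component mixture on read
#' counts (not ratios `m/n`, so sequencing depth informs the fit).
#' The E-step computes posterior component responsibilities via
#' [log_beta_binomial_marginal()]; the M-step updates weights as
#' responsibility means and each component's single free shape
#' (`alpha_H`, `beta_L`) by exact 1-D maximization of its weighted
#' beta-binomial likelihood, projected onto `[1, Inf)`. The observed-data
#' log-likelihood is non-decreasing across iterations.
#'
#' Initialization is a method-of-moments split: sites with `m/n > 0.5` seed
#' the high component, the rest the low component, and the uniform weight
#' starts at 0.05.
#'
#' @param counts data frame with columns `m`, `u`, each `m + u >= 1`.
#' @param tol relative log-likelihood improvement below which EM stops.
#' @param max_iter maximum EM iterations.
#' @return A [beta_mixture()] with attribute `fit` (a data frame of
#'   per-iteration log-likelihoods) and attribute `converged`.
#' @export
fit_beta_mixture <- function(counts, tol = 1e-6, max_iter = 500) {
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  m <- as.numeric(counts$m); u <- as.numeric(counts$u)
  n <- m + u
  if (length(m) == 0 || any(n < 1)) {
    stop("counts must be non-empty with m + u >= 1 at every site", call. = FALSE)
  }
  lev <- m / n
  hi <- lev > 0.5
  mom_alpha <- function(mean_hi) max(1, mean_hi / max(1 - mean_hi, 1e-6))
  mom_beta <- function(mean_lo) max(1, (1 - mean_lo) / max(mean_lo, 1e-6))
  w_H <- max(mean(hi) * 0.95, 0.01)
  w_L <- max((1 - mean(hi)) * 0.95, 0.01)
  w_unif <- 1 - w_H - w_L
  alpha_H <- if (any(hi)) mom_alpha(mean(lev[hi])) else 2
  beta_L <- if (any(!hi)) mom_beta(mean(lev[!hi])) else 2
  mix <- beta_mixture(w_H, w_L, w_unif, alpha_H, beta_L)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- component_responsibilities(m, u, mix)
    w <- colMeans(r)
    alpha_H <- mstep_shape(m, u, r[, "H"], free = "alpha", fixed = 1, cur = mix$alpha_H)
    beta_L <- mstep_shape(u, m, r[, "L"], free = "alpha", fixed = 1, cur = mix$beta_L)
    mix <- beta_mixture(w["H"], w["L"], w["unif"], alpha_H, beta_L)
    ll <- mixture_loglik(m, u, mix)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && (ll - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  attr(mix, "fit") <- data.frame(iter = seq_along(ll_trace), loglik = ll_trace)
  attr(mix, "converged") <- converged
  mix
}

# maximize sum_i r_i * log BetaBinom(m_i, u_i | a, fixed) over the single
# free shape a >= 1 (swap m/u to optimize the beta shape). Brent search on
# log(a); falls back to the current value when responsibilities vanish.
mstep_shape <- function(m, u, r, free = "alpha", fixed = 1, cur = 2) {
  if (sum(r) < 1e-12) return(cur)
  obj <- function(la) {
    a <- exp(la)
    sum(r * (lbeta(m + a, u + fixed) - lbeta(a, fixed)))
  }
  opt <- stats::optimize(obj, interval = c(0, log(1e6)), maximum = TRUE,
                         tol = 1e-10)
  cand <- exp(opt$maximum)
  # projection onto the constraint a >= 1
  if (obj(0) >= opt$objective) cand <- 1
  max(1, cand)
}
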