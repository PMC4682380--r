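#' Per-CpG log emission values under the beta-mixture model
#'
#' For each CpG site the HMM needs the likelihood of the observed count
#' quadruple under three differential methylation states:
#' \describe{
#'   \item{Up}{sample 1 drawn from the high mode of its mixture, sample 2
#'     from the low mode of its mixture;}
#'   \item{Down}{the mirror image;}
#'   \item{NoCh}{both samples share one methylation level drawn from the
#'     normalized product of the two full mixture densities.}
#' }
#' Integrating the binomial read-count likelihoods against these priors
#' gives closed forms in beta functions. With the mixture constraints
#' (all shapes `>= 1`, `beta_H = alpha_L = 1`) the NoCh integral's
#' cross-component beta functions `B(alpha_s + alpha_t - 1,
#' beta_s + beta_t - 1)` are always defined; this is asserted at entry.
#'
#' A site with no reads in either sample emits probability 1 in all three
#' states (all log emissions 0), which keeps the position in the chain for
#' distance modelling without informing the state.
#'
#' @param table a [cpg_table()].
#' @param mix1,mix2 fitted [beta_mixture()]s for samples 1 and 2.
#' @return An `emission_table`: numeric matrix with one row per site and
#'   columns `U`, `D`, `N` of log emission values, with attributes `logZ`
#'   (the NoCh normalizer) and the source `chrom`/`pos` columns.
#' @export
compute_emissions <- function(table, mix1, mix2) {
  stopifnot(inherits(mix1, "beta_mixture"), inherits(mix2, "beta_mixture"))
  c1 <- mixture_components(mix1)
  c2 <- mixture_components(mix2)
  stopifnot(all(outer(c1$alpha, c2$alpha, "+") - 1 >= 1 - 1e-12),
            all(outer(c1$beta, c2$beta, "+") - 1 >= 1 - 1e-12))
  m1 <- table$m1; u1 <- table$u1; m2 <- table$m2; u2 <- table$u2
  lc <- lchoose(m1 + u1, m1) + lchoose(m2 + u2, m2)

  logE_U <- lc +
    lbeta(m1 + mix1$alpha_H, u1 + 1) - lbeta(mix1$alpha_H, 1) +
    lbeta(m2 + 1, u2 + mix2$beta_L) - lbeta(1, mix2$beta_L)
  logE_D <- lc +
    lbeta(m1 + 1, u1 + mix1$beta_L) - lbeta(1, mix1$beta_L) +
    lbeta(m2 + mix2$alpha_H, u2 + 1) - lbeta(mix2$alpha_H, 1)

  # NoCh: 3x3 sum over component pairs (s from sample 1, t from sample 2)
  terms <- matrix(NA_real_, nrow(table), 9)
  zterms <- numeric(9)
  k <- 0
  for (s in c("H", "L", "unif")) {
    for (t in c("H", "L", "unif")) {
      k <- k + 1
      a <- c1$alpha[s] + c2$alpha[t] - 1
      b <- c1$beta[s] + c2$beta[t] - 1
      lww <- log(c1$w[s]) + log(c2$w[t])
      denom <- lbeta(c1$alpha[s], c1$beta[s]) + lbeta(c2$alpha[t], c2$beta[t])
      terms[, k] <- lww + lbeta(m1 + m2 + a, u1 + u2 + b) - denom
      zterms[k] <- lww + lbeta(a, b) - denom
    }
  }
  logZ <- logsumexp(zterms)
  logE_N <- lc + row_logsumexp(terms) - logZ

  em <- cbind(U = logE_U, D = logE_D, N = logE_N)
  structure(em, logZ = logZ, chrom = table$chrom, pos = table$pos,
            class = c("emission_table", class(em)))
}

logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

#' Per-CpG log emissions under the legacy pseudocount model
#'
#' The earlier emission design plugs fixed, state-dependent methylation
#' levels into binomial likelihoods. An empirical pseudocount `pseudo` is
#' added to the counts supporting the state's expected direction:
#' for Up, `theta1 = (m1 + pseudo)/(n1 + pseudo)` and
#' `theta2 = m2/(n2 + pseudo)`; Down mirrors it; NoCh pools both samples,
#' `theta0 = (m1 + m2)/(n1 + n2)` (clamped away from 0 and 1 before the
#' log). With `pseudo = 0` the Up and Down emissions coincide, so the model
#' cannot resolve direction — the degeneracy the pseudocount exists to break.
#'
#' @param table a [cpg_table()].
#' @param pseudo non-negative pseudocount.
#' @return An `emission_table` matrix with columns `U`, `D`, `N`.
#' @export
compute_legacy_emissions <- function(table, pseudo) {
  stopifnot(pseudo >= 0)
  m1 <- table$m1; u1 <- table$u1; m2 <- table$m2; u2 <- table$u2
  n1 <- m1 + u1; n2 <- m2 + u2
  eps <- 1e-12
  clamp <- function(x) pmin(pmax(x, eps), 1 - eps)
  # log Binom(m | n, theta) with the n = 0 convention Binom(0|0, .) = 1;
  # theta may be NaN at n = 0, in which case the contribution is 0
  lbinom <- function(m, n, theta) {
    out <- numeric(length(m))
    ok <- n > 0
    th <- clamp(theta[ok])
    out[ok] <- lchoose(n[ok], m[ok]) + m[ok] * log(th) + (n[ok] - m[ok]) * log1p(-th)
    out
  }
  theta1U <- (m1 + pseudo) / (n1 + pseudo)
  theta2U <- m2 / (n2 + pseudo)
  theta1D <- m1 / (n1 + pseudo)
  theta2D <- (m2 + pseudo) / (n2 + pseudo)
  theta0N <- (m1 + m2) / (n1 + n2)
  # a site with pseudo = 0 and n_s = 0 leaves theta undefined; the binomial
  # factor is 1 there regardless, handled inside lbinom
  em <- cbind(U = lbinom(m1, n1, theta1U) + lbinom(m2, n2, theta2U),
              D = lbinom(m1, n1, theta1D) + lbinom(m2, n2, theta2D),
              N = lbinom(m1, n1, theta0N) + lbinom(m2, n2, theta0N))
  structure(em, chrom = table$chrom, pos = table$pos,
            class = c("emission_table", class(em)))
}
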