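# State space of the dual-unit HMM.
#
# Twelve states: {CpG, gap} x {Up, Down, NoCh} x {basic, second}. CpG states
# emit the per-site count likelihoods; gap states are silent, occupy the
# interval positions between consecutive CpGs, and encode inter-CpG distance
# through their self-transition (geometric dwell). Each CpG state connects
# only to its own gap state; each gap state self-loops and exits to any of
# the six CpG states, so direction and unit changes happen at gap-to-CpG
# boundaries. The two units give every direction a two-component
# mixture-of-geometrics distance distribution.
.cpg_states <- c("U.basic", "U.second", "D.basic", "D.second",
                 "N.basic", "N.second")
.all_states <- c(paste0("cpg.", .cpg_states), paste0("gap.", .cpg_states))

#' Construct dual-unit HMM parameters
#'
#' Compact parameterization of the 12-state model: because CpG states have a
#' single outgoing edge (to their own gap state, probability 1) and gap
#' states only self-loop or exit to CpG states, the free parameters are the
#' six gap self-transition probabilities, the 6x6 gap-exit matrix, and the
#' initial distribution over the six CpG states.
#'
#' @param self numeric(6), gap self-transition probabilities in `[0, 1)`.
#' @param exit 6x6 matrix, `exit[i, j]` = probability that gap state `i`
#'   exits to CpG state `j`; row `i` sums to `1 - self[i]`.
#' @param init numeric(6), initial distribution over CpG states (sums to 1).
#' @return An `hmm_params` object.
#' @export
hmm_params <- function(self, exit, init) {
  stopifnot(length(self) == 6, all(dim(exit) == c(6, 6)), length(init) == 6)
  if (any(self < 0) || any(self >= 1)) stop("gap self-probabilities must be in [0, 1)", call. = FALSE)
  if (any(exit < 0)) stop("exit probabilities must be non-negative", call. = FALSE)
  if (any(abs(self + rowSums(exit) - 1) > 1e-9)) {
    stop("each gap row must satisfy self + sum(exit) = 1", call. = FALSE)
  }
  if (abs(sum(init) - 1) > 1e-9 || any(init < 0)) {
    stop("init must be a distribution over the six CpG states", call. = FALSE)
  }
  dimnames(exit) <- list(.cpg_states, .cpg_states)
  structure(list(self = stats::setNames(as.numeric(self), .cpg_states),
                 exit = exit,
                 init = stats::setNames(as.numeric(init), .cpg_states)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("hmm_params (dual-unit, 12 states)\n")
  cat("gap self-transition probabilities:\n")
  print(round(x$self, 4))
  cat("initial CpG-state distribution:\n")
  print(round(x$init, 4))
  invisible(x)
}

#' Full 12x12 transition matrix of the dual-unit HMM
#'
#' Rows/columns are ordered CpG states then gap states, each in
#' `(Up, Down, NoCh) x (basic, second)` order. CpG rows place probability 1
#' on the state's own gap; structurally forbidden entries are exactly 0.
#'
#' @param params an [hmm_params()].
#' @return A row-stochastic 12x12 matrix.
#' @export
transition_matrix <- function(params) {
  A <- matrix(0, 12, 12, dimnames = list(.all_states, .all_states))
  for (i in 1:6) A[i, 6 + i] <- 1                 # CpG_i -> gap_i
  for (i in 1:6) {
    A[6 + i, 6 + i] <- params$self[i]             # gap self-loop
    A[6 + i, 1:6] <- params$exit[i, ]             # gap -> CpG exits
  }
  A
}

#' Default HMM parameters
#'
#' Near-uniform allowed transitions with a small seeded jitter that differs
#' between the basic and second units (so Baum-Welch can break the unit
#' symmetry) but is shared between the Up and Down directions (so the model
#' stays exactly equivariant under swapping the two samples). The initial
#' distribution puts 0.9 on NoCh, split evenly across units.
#'
#' @param seed integer seed for the jitter.
#' @return An [hmm_params()].
#' @export
default_hmm <- function(seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  jit_self <- stats::rnorm(2, sd = 1)        # per unit
  jit_exit <- matrix(stats::rnorm(4, sd = 1), 2, 2)  # source unit x dest unit
  eps <- 0.1
  self <- numeric(6)
  exit <- matrix(0, 6, 6)
  unit_of <- rep(1:2, 3)
  for (i in 1:6) {
    ui <- unit_of[i]
    w_self <- exp(eps * jit_self[ui])
    w_exit <- exp(eps * jit_exit[ui, unit_of])  # same for all destination dirs
    tot <- w_self + sum(w_exit)
    self[i] <- w_self / tot
    exit[i, ] <- w_exit / tot
  }
  init <- c(0.025, 0.025, 0.025, 0.025, 0.45, 0.45)
  hmm_params(self, exit, init)
}

#' Effective CpG-to-CpG transition kernel for a given gap length
#'
#' Two consecutive CpG sites separated by `d >= 1` interval positions are
#' connected through a run of `d` silent gap positions. Since gap states
#' only self-loop, the run collapses analytically:
#' `T_eff(d) = A[CpG->gap] (A[gap->gap])^(d-1) A[gap->CpG]`, whose nonzero
#' block is `self_i^(d-1) * exit[i, j]`. `d = 0` returns the direct
#' CpG-to-CpG block, which is structurally zero in this topology (distinct
#' CpGs on a strand-merged table are always at least 2 bp apart, so `d >= 1`
#' in practice).
#'
#' @param params an [hmm_params()].
#' @param d non-negative integer gap length in interval positions.
#' @return A 12x12 matrix whose CpG-row by CpG-column block holds the
#'   effective kernel; all other entries are 0.
#' @export
effective_transition <- function(params, d) {
  if (d < 0) stop("gap length must be non-negative", call. = FALSE)
  out <- matrix(0, 12, 12, dimnames = list(.all_states, .all_states))
  if (d == 0) return(out)
  K <- params$self^(d - 1) * params$exit   # recycles self down columns: rows scale
  out[1:6, 1:6] <- K
  out
}

# 6x6 log effective kernel used by the C++ core inputs
log_kernel_parts <- function(params) {
  list(lself = log(params$self), lexit = log(params$exit),
       lpi = log(params$init))
}

#' Log-space forward-backward over one chromosome
#'
#' Runs the forward and backward recursions over CpG steps, using the
#' collapsed gap kernel for each observed inter-CpG distance. Emissions are
#' applied at CpG steps only and are shared between the two units.
#'
#' @param emissions numeric matrix with one row per site and columns
#'   `U`, `D`, `N` of log emissions (an `emission_table`).
#' @param gaps integer vector of inter-CpG gap lengths,
#'   `length(gaps) == nrow(emissions) - 1`, all `>= 1`.
#' @param params an [hmm_params()].
#' @return A list with `loglik`, `posterior` (site x `{U,D,N}` matrix, unit
#'   marginalized), `gamma` (site x 6 CpG-state posterior), and
#'   `loglik_backward` (the backward-pass total, for checking agreement).
#' @export
forward_backward <- function(emissions, gaps, params) {
  if (is.null(nrow(emissions)) || nrow(emissions) == 0) stop("empty emission table", call. = FALSE)
  if (length(gaps) != nrow(emissions) - 1) {
    stop("need one gap length per adjacent site pair", call. = FALSE)
  }
  kp <- log_kernel_parts(params)
  res <- cpp_forward_backward(unclass(emissions)[, c("U", "D", "N"), drop = FALSE],
                              as.integer(gaps), kp$lself, kp$lexit, kp$lpi)
  gamma <- res$gamma
  colnames(gamma) <- .cpg_states
  post <- cbind(U = gamma[, 1] + gamma[, 2],
                D = gamma[, 3] + gamma[, 4],
                N = gamma[, 5] + gamma[, 6])
  list(loglik = res$loglik, posterior = post, gamma = gamma,
       loglik_backward = res$loglik_backward)
}

# normalize emissions/gaps arguments to parallel lists of chains
as_chain_lists <- function(emissions, gaps) {
  if (is.list(emissions) && !is.data.frame(emissions)) {
    stopifnot(is.list(gaps), length(gaps) == length(emissions))
    list(em = emissions, gaps = gaps)
  } else {
    list(em = list(emissions), gaps = list(gaps))
  }
}

#' Learn transition probabilities by Baum-Welch
#'
#' Expectation-maximization over the collapsed chain with emissions held
#' fixed. The expected gap self-loop count for a transition spanning `d`
#' interval positions is exactly `d - 1` times the transition's posterior
#' probability (the gap run's length is determined by the observed
#' distance), so the E-step needs no per-base pass. Chromosomes are
#' independent chains sharing one parameter set; the initial distribution is
#' re-estimated from the first-site posteriors.
#'
#' @param emissions an emission matrix (single chromosome) or list of
#'   matrices (one per chromosome).
#' @param gaps gap-length vector or list matching `emissions`.
#' @param init an [hmm_params()] to start from, e.g. [default_hmm()].
#' @param tol absolute log-likelihood improvement below which EM stops.
#' @param max_iter maximum EM iterations.
#' @return An [hmm_params()] with attribute `fit` (per-iteration total
#'   log-likelihood) and attribute `converged`.
#' @export
fit_transitions <- function(emissions, gaps, init = default_hmm(),
                            tol = 1e-4, max_iter = 100) {
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  ch <- as_chain_lists(emissions, gaps)
  params <- init
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    kp <- log_kernel_parts(params)
    xi_sum <- matrix(0, 6, 6)
    selfw <- numeric(6)
    gamma1 <- numeric(6)
    ll <- 0
    for (c in seq_along(ch$em)) {
      em <- unclass(ch$em[[c]])[, c("U", "D", "N"), drop = FALSE]
      res <- cpp_forward_backward(em, as.integer(ch$gaps[[c]]),
                                  kp$lself, kp$lexit, kp$lpi)
      ll <- ll + res$loglik
      xi_sum <- xi_sum + res$xi_sum
      selfw <- selfw + res$selfw
      gamma1 <- gamma1 + res$gamma[1, ]
    }
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll

    exit_tot <- rowSums(xi_sum)
    self_new <- params$self
    exit_new <- params$exit
    for (i in 1:6) {
      use <- selfw[i] + exit_tot[i]
      if (use > 1e-12) {
        self_new[i] <- selfw[i] / use
        exit_new[i, ] <- (1 - self_new[i]) * xi_sum[i, ] / exit_tot[i]
      } # else: state unused, keep previous row
    }
    init_new <- gamma1 / sum(gamma1)
    params <- hmm_params(self_new, exit_new, init_new)
  }
  attr(params, "fit") <- data.frame(iter = seq_along(ll_trace), loglik = ll_trace)
  attr(params, "converged") <- converged
  params
}
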