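dir_code <- c(Up = 1L, Down = 2L, NoCh = 3L)

#' Log-likelihood-ratio score of a candidate region
#'
#' Scores the hypothesis that sites `s..e` are in the given direction state
#' while every other site of the chromosome is NoCh, against the all-NoCh
#' hypothesis:
#' `score = log P(best path: dir on s..e, NoCh elsewhere) - log P(best all-NoCh path)`.
#' Each constrained path probability is maximized exactly over the basic /
#' second unit sequence (a two-state Viterbi), with the collapsed gap
#' kernels supplying the distance terms. The score decomposes into the
#' emission log-ratios of the region's sites plus boundary and within-region
#' transition log-ratios; a region indistinguishable from NoCh scores at or
#' below 0.
#'
#' @param emissions log-emission matrix (columns `U`, `D`, `N`) for one
#'   chromosome.
#' @param gaps inter-CpG gap lengths for that chromosome.
#' @param params an [hmm_params()].
#' @param s,e 1-based first and last site indices of the region, `s <= e`.
#' @param dir `"Up"` or `"Down"`.
#' @return The log-likelihood ratio in nats.
#' @export
score_region <- function(emissions, gaps, params, s, e, dir) {
  if (e < s) stop("region end before start", call. = FALSE)
  if (!dir %in% c("Up", "Down")) stop("dir must be \"Up\" or \"Down\"", call. = FALSE)
  L <- nrow(emissions)
  stopifnot(s >= 1, e <= L)
  kp <- log_kernel_parts(params)
  em <- unclass(emissions)[, c("U", "D", "N"), drop = FALSE]
  labels <- rep(dir_code[["NoCh"]], L)
  labels[s:e] <- dir_code[[dir]]
  num <- cpp_constrained_loglik(em, as.integer(gaps), kp$lself, kp$lexit,
                                kp$lpi, as.integer(labels))
  den <- cpp_constrained_loglik(em, as.integer(gaps), kp$lself, kp$lexit,
                                kp$lpi, rep(dir_code[["NoCh"]], L))
  num - den
}

# Additive per-site increment machinery for one direction.
#
# The score of a candidate region decomposes (collapsing the unit pair of
# each step by maximization) into
#   score(s, e) = sum_{i=s..e} r_i + sum_{i=s..e-1} tau_i + A_s + B_e
# where r_i is the emission log-ratio, tau_i the within-region vs NoCh
# transition log-ratio of the step after site i, A_s the cost of switching
# NoCh -> dir on entry (or the initial-distribution ratio at the first
# site), and B_e the cost of switching dir -> NoCh on exit (0 at the last
# site). With prefix sums P_i of (r + tau) this is
#   score(s, e) = P_e + B_e + G_s,   G_s = r_s + A_s - P_s,
# so the best segment of any stretch is found in linear time.
direction_increments <- function(em, gaps, params, dir) {
  L <- nrow(em)
  la <- log(params$self)
  le <- log(params$exit)
  lpi <- log(params$init)
  x <- unname(dir_code[[dir]])          # 1 = U, 2 = D; NoCh = 3
  sx <- (x - 1L) * 2L + 1L              # basic-unit state index of dir
  sn <- 5L                              # basic-unit state index of NoCh
  # stepwise-max log kernel for a state pair (x -> y) across the 2x2 units
  maxk <- function(d, si, sj) {
    best <- rep(-Inf, length(d))
    for (u in 0:1) {
      for (v in 0:1) {
        cand <- (d - 1) * la[si + u] + le[si + u, sj + v]
        best <- pmax(best, cand)
      }
    }
    best
  }
  r <- em[, x] - em[, 3L]
  if (L == 1) {
    tau <- numeric(0); A_in <- numeric(0); B_out <- numeric(0)
  } else {
    d <- as.numeric(gaps)
    nn <- maxk(d, sn, sn)
    tau <- maxk(d, sx, sx) - nn
    A_in <- maxk(d, sn, sx) - nn
    B_out <- maxk(d, sx, sn) - nn
  }
  A <- c(max(lpi[sx + 0:1]) - max(lpi[sn + 0:1]), A_in)   # A[s], s = 1..L
  B <- c(B_out, 0)                                        # B[e], e = 1..L
  P <- cumsum(r + c(0, tau))
  list(r = r, A = A, B = B, P = P, G = r + A - P)
}

# iterated best-segment extraction: repeatedly take the highest-scoring
# segment of the additive objective, remove its sites, and search the
# flanking stretches; stops when no remaining segment exceeds the threshold
best_segments <- function(inc, threshold) {
  segs <- list()
  stack <- list(c(1L, length(inc$r)))
  while (length(stack)) {
    range <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- range[1]; hi <- range[2]
    if (lo > hi) next
    idx <- lo:hi
    G <- inc$G[idx]
    cmG <- cummax(G)
    val <- inc$P[idx] + inc$B[idx] + cmG
    ei <- which.max(val)
    if (val[ei] <= threshold) next
    si <- which.max(G[seq_len(ei)])
    s <- idx[si]; e <- idx[ei]
    segs[[length(segs) + 1L]] <- c(s, e, val[ei])
    stack[[length(stack) + 1L]] <- c(lo, s - 1L)
    stack[[length(stack) + 1L]] <- c(e + 1L, hi)
  }
  segs
}

#' Extract ranked DMRs from one chromosome
#'
#' Candidate regions are the maximal-scoring segments of the additive
#' per-site increment sequence (emission log-ratio plus transition
#' log-ratio, with the NoCh-to-direction boundary penalties folded in),
#' found independently for the Up and Down directions by iterated
#' best-segment extraction: the highest-scoring segment is taken, its sites
#' removed, and the flanking stretches searched recursively until no
#' segment exceeds `threshold`. This maximality rule bridges interior
#' stretches of weak evidence when the flanking evidence outweighs them, so
#' a region whose differential signal is interrupted by uninformative CpGs
#' is still reported whole. Overlapping Up/Down candidates are resolved by
#' keeping the higher score. Each reported region's score is recomputed
#' with [score_region()] (exact unit-path maximization) and must exceed
#' `threshold`. Results are ranked by descending score, ties broken by
#' `(chrom, start)`.
#'
#' @param emissions log-emission matrix (columns `U`, `D`, `N`) for one
#'   chromosome.
#' @param gaps inter-CpG gap lengths.
#' @param positions 0-based CpG positions (one per emission row).
#' @param params an [hmm_params()].
#' @param threshold minimum score (nats) for a reported DMR; default 0.
#' @param chrom chromosome name recorded in the output.
#' @return A data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open, `end` = last CpG position + 2 so the interval covers the
#'   dinucleotide), `direction`, `score`, `n_cpg`, `first_site`, `last_site`.
#' @export
extract_dmrs <- function(emissions, gaps, positions, params, threshold = 0,
                         chrom = "chr1") {
  stopifnot(is.finite(threshold), length(positions) == nrow(emissions))
  em <- unclass(emissions)[, c("U", "D", "N"), drop = FALSE]
  cand <- empty_dmr_frame()
  for (dir in c("Up", "Down")) {
    inc <- direction_increments(em, gaps, params, dir)
    segs <- best_segments(inc, threshold)
    for (sg in segs) {
      cand <- rbind(cand, data.frame(
        chrom = chrom, start = positions[sg[1]], end = positions[sg[2]] + 2L,
        direction = dir, score = NA_real_,
        n_cpg = as.integer(sg[2] - sg[1] + 1L),
        first_site = as.integer(sg[1]), last_site = as.integer(sg[2]),
        stringsAsFactors = FALSE))
    }
  }
  if (nrow(cand) == 0) return(cand)
  for (i in seq_len(nrow(cand))) {
    cand$score[i] <- score_region(em, gaps, params, cand$first_site[i],
                                  cand$last_site[i], cand$direction[i])
  }
  cand <- cand[cand$score > threshold, , drop = FALSE]
  cand <- resolve_direction_overlaps(cand)
  rank_dmrs(cand)
}

# drop the lower-scoring member of any overlapping Up/Down candidate pair
# (within a direction the segments are disjoint by construction, so only
# cross-direction overlaps can occur)
resolve_direction_overlaps <- function(cand) {
  up <- which(cand$direction == "Up")
  dn <- which(cand$direction == "Down")
  if (length(up) == 0 || length(dn) == 0) return(cand)
  dno <- dn[order(cand$first_site[dn])]
  dstart <- cand$first_site[dno]
  dend <- cand$last_site[dno]   # sorted too: same-direction segments disjoint
  keep <- rep(TRUE, nrow(cand))
  for (i in up) {
    j_hi <- findInterval(cand$last_site[i], dstart)
    j_lo <- findInterval(cand$first_site[i] - 1L, dend) + 1L
    if (j_lo > j_hi) next
    for (j in dno[j_lo:j_hi]) {
      if (!keep[i]) break
      if (!keep[j]) next
      if (cand$score[j] < cand$score[i] ||
          (cand$score[j] == cand$score[i])) {
        keep[j] <- FALSE
      } else {
        keep[i] <- FALSE
      }
    }
  }
  cand[keep, , drop = FALSE]
}

empty_dmr_frame <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             direction = character(), score = numeric(), n_cpg = integer(),
             first_site = integer(), last_site = integer(),
             stringsAsFactors = FALSE)
}

rank_dmrs <- function(dmrs) {
  if (nrow(dmrs) == 0) return(dmrs)
  dmrs <- dmrs[order(-dmrs$score, dmrs$chrom, dmrs$start), , drop = FALSE]
  rownames(dmrs) <- NULL
  dmrs
}

#' Detect DMRs on a full count table
#'
#' The user-level driver: computes emissions (beta-mixture or legacy
#' pseudocount model), runs [extract_dmrs()] per chromosome, and returns the
#' globally ranked list.
#'
#' @param table a [cpg_table()].
#' @param params an [hmm_params()] with learned transitions.
#' @param mix1,mix2 fitted [beta_mixture()]s (required for
#'   `emissions = "new"`).
#' @param emissions `"new"` (beta-mixture emissions) or `"legacy"`
#'   (pseudocount emissions).
#' @param pseudo pseudocount, required when `emissions = "legacy"`.
#' @param threshold minimum DMR score in nats.
#' @param top keep only the `top` highest-scoring DMRs (default all).
#' @return A ranked DMR data frame (see [extract_dmrs()]).
#' @export
detect_dmrs <- function(table, params, mix1 = NULL, mix2 = NULL,
                        emissions = c("new", "legacy"), pseudo = NULL,
                        threshold = 0, top = Inf) {
  emissions <- match.arg(emissions)
  em_all <- build_emissions(table, emissions, mix1, mix2, pseudo)
  out <- empty_dmr_frame()
  for (idx in chrom_index(table)) {
    ch <- table$chrom[idx[1]]
    em <- unclass(em_all)[idx, , drop = FALSE]
    pos <- table$pos[idx]
    out <- rbind(out, extract_dmrs(em, gap_lengths(pos), pos, params,
                                   threshold = threshold, chrom = ch))
  }
  out <- rank_dmrs(out)
  if (is.finite(top) && nrow(out) > top) out <- out[seq_len(top), , drop = FALSE]
  out
}

build_emissions <- function(table, mode, mix1, mix2, pseudo) {
  if (mode == "new") {
    if (is.null(mix1) || is.null(mix2)) {
      stop("beta-mixture emissions need mix1 and mix2", call. = FALSE)
    }
    compute_emissions(table, mix1, mix2)
  } else {
    if (is.null(pseudo)) stop("legacy emissions need a pseudo value", call. = FALSE)
    compute_legacy_emissions(table, pseudo)
  }
}
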