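#' Configuration for the count-level WGBS simulator
#'
#' The simulator emulates a two-sample bisulfite-seq comparison at the level
#' of per-CpG read counts. CpG positions are drawn from a two-component
#' geometric spacing mixture (short intra-island distances, long inter-island
#' distances); per-site baseline methylation levels are drawn independently
#' from a bimodal beta mixture; planted DMRs of a target genomic length
#' switch the sample-2 level to the minimum (Up regions, hypermethylated in
#' sample 1) or the maximum (Down regions); read totals are Poisson and
#' methylated counts binomial, with a small symmetric conversion-error flip.
#'
#' @param n_cpg number of CpG sites.
#' @param n_dmr number of planted DMRs (directions split 50/50 at random).
#' @param dmr_length target DMR length in bp; with default spacing
#'   (`0.6 * 20 + 0.4 * 150` about 72 bp mean gap) the default 3600 bp spans
#'   about 50 CpGs.
#' @param depth mean read coverage per site per sample (Poisson).
#' @param conversion_error probability that a read reports the flipped
#'   methylation call.
#' @param level_model ground-truth [beta_mixture()] of baseline levels.
#' @param spacing list with `short_mean`, `long_mean` (mean extra bases of
#'   the two geometric components; every gap is at least 2 bp) and
#'   `island_frac` (probability of the short component).
#' @param chrom chromosome name of the simulated chain.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cpg = 20000, n_dmr = 50, dmr_length = 3600,
                       depth = 10, conversion_error = 0.005,
                       level_model = beta_mixture(0.5, 0.45, 0.05, 8, 8),
                       spacing = list(short_mean = 20, long_mean = 150,
                                      island_frac = 0.6),
                       chrom = "chr1", seed = 1) {
  stopifnot(n_cpg >= 1, n_dmr >= 0, depth > 0,
            conversion_error >= 0, conversion_error < 0.5,
            inherits(level_model, "beta_mixture"))
  structure(list(n_cpg = n_cpg, n_dmr = n_dmr, dmr_length = dmr_length,
                 depth = depth, conversion_error = conversion_error,
                 level_model = level_model, spacing = spacing,
                 chrom = chrom, seed = seed),
            class = "sim_config")
}

#' Simulate a two-sample CpG count table with planted DMRs
#'
#' @param config a [sim_config()].
#' @return A `sim_dataset` list: `table` (a [cpg_table()]), `truth` (data
#'   frame of planted regions: `chrom`, `start`, `end` spanning the first to
#'   last CpG of the region, `direction`, `n_cpg`), `levels` (per-site
#'   methylation levels actually used, columns `theta1`, `theta2`), and the
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  sp <- config$spacing
  short <- stats::rbinom(config$n_cpg - 1, 1, sp$island_frac) == 1
  extra <- integer(config$n_cpg - 1)
  extra[short] <- stats::rgeom(sum(short), 1 / sp$short_mean)
  extra[!short] <- stats::rgeom(sum(!short), 1 / sp$long_mean)
  pos <- cumsum(c(1000L, 2L + extra))
  span <- pos[length(pos)] - pos[1]
  if (config$n_dmr > 0 && config$n_dmr * config$dmr_length > span) {
    stop("planted DMRs (n_dmr * dmr_length) exceed the simulated genome span",
         call. = FALSE)
  }

  # baseline levels: component, then level within component
  mix <- config$level_model
  comp <- sample.int(3, config$n_cpg, replace = TRUE,
                     prob = c(mix$w_H, mix$w_L, mix$w_unif))
  theta <- numeric(config$n_cpg)
  theta[comp == 1] <- stats::rbeta(sum(comp == 1), mix$alpha_H, 1)
  theta[comp == 2] <- stats::rbeta(sum(comp == 2), 1, mix$beta_L)
  theta[comp == 3] <- stats::runif(sum(comp == 3))

  planted <- plant_dmrs(pos, config$n_dmr, config$dmr_length)
  theta2 <- theta
  for (r in seq_len(nrow(planted))) {
    idx <- planted$first_site[r]:planted$last_site[r]
    theta2[idx] <- if (planted$direction[r] == "Up") 0 else 1
  }

  eps <- config$conversion_error
  flip <- function(th) th * (1 - eps) + (1 - th) * eps
  n1 <- stats::rpois(config$n_cpg, config$depth)
  n2 <- stats::rpois(config$n_cpg, config$depth)
  m1 <- stats::rbinom(config$n_cpg, n1, flip(theta))
  m2 <- stats::rbinom(config$n_cpg, n2, flip(theta2))

  table <- cpg_table(rep(config$chrom, config$n_cpg), pos,
                     m1, n1 - m1, m2, n2 - m2, sort = FALSE)
  truth <- data.frame(chrom = rep(config$chrom, nrow(planted)),
                      start = pos[planted$first_site],
                      end = pos[planted$last_site] + 2L,
                      direction = planted$direction,
                      n_cpg = planted$last_site - planted$first_site + 1L,
                      stringsAsFactors = FALSE)
  structure(list(table = table, truth = truth,
                 levels = data.frame(theta1 = theta, theta2 = theta2),
                 config = config),
            class = "sim_dataset")
}

# choose n_dmr non-overlapping regions anchored at CpG sites, each spanning
# the CpGs within dmr_length bp of the anchor; a 10-site buffer keeps
# adjacent planted regions from merging in detection
plant_dmrs <- function(pos, n_dmr, dmr_length, buffer_sites = 10L) {
  out <- data.frame(first_site = integer(), last_site = integer(),
                    direction = character(), stringsAsFactors = FALSE)
  if (n_dmr == 0) return(out)
  n <- length(pos)
  taken <- rep(FALSE, n)
  dirs <- ifelse(stats::rbinom(n_dmr, 1, 0.5) == 1, "Up", "Down")
  placed <- 0L
  attempts <- 0L
  while (placed < n_dmr) {
    attempts <- attempts + 1L
    if (attempts > 200L * n_dmr) {
      stop("could not place ", n_dmr, " non-overlapping DMRs of ",
           dmr_length, " bp; genome span too small", call. = FALSE)
    }
    anchor <- sample.int(n, 1)
    last <- anchor
    while (last < n && pos[last + 1] < pos[anchor] + dmr_length) last <- last + 1L
    if (last - anchor + 1L < 2L) next
    lo <- max(1L, anchor - buffer_sites)
    hi <- min(n, last + buffer_sites)
    if (any(taken[lo:hi])) next
    taken[lo:hi] <- TRUE
    placed <- placed + 1L
    out <- rbind(out, data.frame(first_site = anchor, last_site = last,
                                 direction = dirs[placed],
                                 stringsAsFactors = FALSE))
  }
  out[order(out$first_site), , drop = FALSE]
}

#' Write the planted-DMR truth list as BED
#'
#' @param truth truth data frame from [simulate_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  lines <- sprintf("%s\t%d\t%d\ttrue%d\t0\t%s", truth$chrom, truth$start,
                   truth$end, seq_len(nrow(truth)),
                   ifelse(truth$direction == "Up", "+", "-"))
  writeLines(c("# planted DMRs (synthetic truth)", lines), path)
  invisible(path)
}

#' Read a truth/DMR BED file into the benchmark's interval format
#'
#' @param path BED path written by [write_truth()] or [write_dmrs()].
#' @return Data frame with `chrom`, `start`, `end`, `direction`.
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  data.frame(chrom = f[, 1], start = as.integer(f[, 2]),
             end = as.integer(f[, 3]),
             direction = ifelse(f[, 6] == "+", "Up", "Down"),
             stringsAsFactors = FALSE)
}
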