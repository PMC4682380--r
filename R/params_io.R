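#' Write fitted model parameters to a plain-text file
#'
#' Serializes the two per-sample beta mixtures and the learned HMM
#' transition parameters as `key=value` lines at full precision, so a fit
#' can be reused by later detection runs.
#'
#' @param path output file path.
#' @param mix1,mix2 fitted [beta_mixture()]s.
#' @param hmm an [hmm_params()].
#' @return `path`, invisibly.
#' @export
write_params <- function(path, mix1, mix2, hmm) {
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  lines <- c("# dmrhmm fitted parameters")
  for (s in 1:2) {
    mix <- if (s == 1) mix1 else mix2
    for (f in c("w_H", "w_L", "w_unif", "alpha_H", "beta_L")) {
      lines <- c(lines, paste0("mix", s, ".", f, "=", fmt(mix[[f]])))
    }
  }
  lines <- c(lines,
             paste0("hmm.self.", 1:6, "=", fmt(hmm$self)),
             paste0("hmm.init.", 1:6, "=", fmt(hmm$init)))
  for (i in 1:6) {
    lines <- c(lines, paste0("hmm.exit.", i, ".", 1:6, "=", fmt(hmm$exit[i, ])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameter file written by [write_params()]
#'
#' @param path parameter file path.
#' @return A list with elements `mix1`, `mix2` ([beta_mixture()]s) and
#'   `hmm` ([hmm_params()]).
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  get <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("parameter file missing key: ", k, call. = FALSE)
    vals[i]
  }
  mk_mix <- function(s) {
    beta_mixture(get(paste0("mix", s, ".w_H")), get(paste0("mix", s, ".w_L")),
                 get(paste0("mix", s, ".w_unif")),
                 get(paste0("mix", s, ".alpha_H")), get(paste0("mix", s, ".beta_L")))
  }
  self <- vapply(1:6, function(i) get(paste0("hmm.self.", i)), 0.0)
  init <- vapply(1:6, function(i) get(paste0("hmm.init.", i)), 0.0)
  exit <- matrix(0, 6, 6)
  for (i in 1:6) {
    exit[i, ] <- vapply(1:6, function(j) get(paste0("hmm.exit.", i, ".", j)), 0.0)
  }
  # renormalize away round-trip noise in the last printed digit
  init <- init / sum(init)
  for (i in 1:6) {
    tot <- self[i] + sum(exit[i, ])
    self[i] <- self[i] / tot
    exit[i, ] <- exit[i, ] / tot
  }
  list(mix1 = mk_mix(1), mix2 = mk_mix(2), hmm = hmm_params(self, exit, init))
}

#' Fit all model parameters on a count table
#'
#' Convenience wrapper chaining the full learning stage: subsample covered
#' sites (one shared site set for both samples by default), fit each
#' sample's beta mixture, compute emissions, and learn transitions by
#' Baum-Welch from [default_hmm()].
#'
#' @param table a [cpg_table()].
#' @param n_sites sites subsampled for the mixture fits.
#' @param seed seed for subsampling and the transition jitter.
#' @param shared_sites use one site set for both samples (default) or draw
#'   independently per sample.
#' @param tol_mix,max_iter_mix mixture EM controls.
#' @param tol_hmm,max_iter_hmm Baum-Welch controls.
#' @return A list with `mix1`, `mix2`, `hmm` and the `emissions` matrix used
#'   for the transition fit.
#' @export
fit_model <- function(table, n_sites = 10000, seed = 1, shared_sites = TRUE,
                      tol_mix = 1e-6, max_iter_mix = 500,
                      tol_hmm = 1e-4, max_iter_hmm = 100) {
  if (shared_sites) {
    # one site set for both samples, drawn from sites covered in both so the
    # learning stage treats the two samples symmetrically
    both <- which(table$m1 + table$u1 >= 1 & table$m2 + table$u2 >= 1)
    if (length(both) == 0) stop("no site covered in both samples", call. = FALSE)
    idx <- if (length(both) <= n_sites) both else {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
      sort(sample(both, n_sites))
    }
    c1 <- subsample_sites(table, 1, n_sites, site_idx = idx)
    c2 <- subsample_sites(table, 2, n_sites, site_idx = idx)
  } else {
    c1 <- subsample_sites(table, 1, n_sites, seed = seed)
    c2 <- subsample_sites(table, 2, n_sites, seed = seed + 1)
  }
  mix1 <- fit_beta_mixture(c1, tol = tol_mix, max_iter = max_iter_mix)
  mix2 <- fit_beta_mixture(c2, tol = tol_mix, max_iter = max_iter_mix)
  em <- compute_emissions(table, mix1, mix2)
  chains <- split_chains(table, em)
  hmm <- fit_transitions(chains$em, chains$gaps, init = default_hmm(seed),
                         tol = tol_hmm, max_iter = max_iter_hmm)
  list(mix1 = mix1, mix2 = mix2, hmm = hmm, emissions = em)
}

# per-chromosome emission matrices and gap vectors
split_chains <- function(table, em) {
  idx_list <- chrom_index(table)
  list(em = lapply(idx_list, function(i) unclass(em)[i, , drop = FALSE]),
       gaps = lapply(idx_list, function(i) gap_lengths(table$pos[i])),
       pos = lapply(idx_list, function(i) table$pos[i]),
       chrom = names(idx_list))
}
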