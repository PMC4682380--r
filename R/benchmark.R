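#' Reciprocal overlap of two genomic intervals
#'
#' For half-open intervals `a` and `b` on the same chromosome, returns
#' `min(|a intersect b| / |a|, |a intersect b| / |b|)`: the overlap must
#' cover at least the given fraction of *both* intervals for a prediction to
#' count as correct at that fraction. Intervals on different chromosomes
#' return 0; zero-length intervals are an error.
#'
#' @param a,b intervals: numeric `c(start, end)` or a list / one-row data
#'   frame with `start`, `end` and optionally `chrom`.
#' @return Overlap fraction in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a, b) {
  ai <- as_interval(a)
  bi <- as_interval(b)
  if (ai$end <= ai$start || bi$end <= bi$start) {
    stop("zero-length interval", call. = FALSE)
  }
  if (!is.null(ai$chrom) && !is.null(bi$chrom) && ai$chrom != bi$chrom) {
    return(0)
  }
  inter <- min(ai$end, bi$end) - max(ai$start, bi$start)
  if (inter <= 0) return(0)
  min(inter / (ai$end - ai$start), inter / (bi$end - bi$start))
}

as_interval <- function(x) {
  if (is.numeric(x) && length(x) == 2) {
    list(chrom = NULL, start = x[1], end = x[2])
  } else {
    list(chrom = if (!is.null(x$chrom)) as.character(x$chrom) else NULL,
         start = as.numeric(x$start), end = as.numeric(x$end))
  }
}

#' Top-k DMR detection accuracy under a reciprocal-overlap criterion
#'
#' A planted (truth) region is counted correct if one of the top-`k`
#' predictions reciprocally overlaps it at `>= fraction` (and, when
#' `match_direction` is on, in the same direction). Predictions are walked
#' in rank order and each may match at most one still-unmatched truth region
#' (the one it overlaps best), so no truth region is counted twice. The
#' rate is `correct / k`; benchmarks use `k` equal to the number of planted
#' regions so the rate reads as both precision and recall.
#'
#' @param predicted ranked DMR data frame (`chrom`, `start`, `end`,
#'   `direction`, `score`), best first.
#' @param truth truth data frame (`chrom`, `start`, `end`, `direction`).
#' @param k number of top predictions to assess (`> 0`).
#' @param fraction reciprocal-overlap criterion in `(0, 1]`.
#' @param match_direction require matching direction (default `TRUE`).
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy_at <- function(predicted, truth, k, fraction = 0.5,
                        match_direction = TRUE) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]", call. = FALSE)
  if (nrow(predicted) == 0 || nrow(truth) == 0) return(0)
  preds <- predicted[seq_len(min(k, nrow(predicted))), , drop = FALSE]
  matched <- rep(FALSE, nrow(truth))
  correct <- 0L
  for (p in seq_len(nrow(preds))) {
    best <- 0
    best_t <- NA_integer_
    for (t in which(!matched)) {
      if (preds$chrom[p] != truth$chrom[t]) next
      if (match_direction && preds$direction[p] != truth$direction[t]) next
      ov <- reciprocal_overlap(preds[p, ], truth[t, ])
      if (ov >= fraction && ov > best) {
        best <- ov
        best_t <- t
      }
    }
    if (!is.na(best_t)) {
      matched[best_t] <- TRUE
      correct <- correct + 1L
    }
  }
  correct / k
}

#' Benchmark a prediction set at several overlap criteria
#'
#' @param predicted ranked DMR data frame.
#' @param truth truth data frame.
#' @param k top count (defaults to the number of truth regions).
#' @param fractions reciprocal-overlap criteria to evaluate.
#' @param match_direction require matching direction.
#' @return Data frame with columns `fraction`, `k`, `accuracy`.
#' @export
benchmark_report <- function(predicted, truth, k = nrow(truth),
                             fractions = c(0.5, 0.9, 0.99),
                             match_direction = TRUE) {
  data.frame(fraction = fractions, k = k,
             accuracy = vapply(fractions, function(f)
               accuracy_at(predicted, truth, k, f, match_direction), 0.0))
}
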