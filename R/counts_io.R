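#' @useDynLib dmrhmm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a per-CpG two-sample count table
#'
#' A `cpg_table` is an ordered data frame with one row per CpG site and
#' columns `chrom`, `pos` (0-based coordinate of the plus-strand cytosine),
#' and non-negative integer read counts `m1`, `u1`, `m2`, `u2` (reads
#' supporting / not supporting methylation in samples 1 and 2). Rows are
#' sorted by `(chrom, pos)` and `(chrom, pos)` pairs are unique.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based CpG positions.
#' @param m1,u1,m2,u2 non-negative integer read counts.
#' @param sort sort rows by `(chrom, pos)`? Turn off only when the input is
#'   known sorted.
#' @return A `cpg_table` data frame.
#' @export
cpg_table <- function(chrom, pos, m1, u1, m2, u2, sort = TRUE) {
  tab <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    m1 = as.integer(m1), u1 = as.integer(u1),
    m2 = as.integer(m2), u2 = as.integer(u2),
    stringsAsFactors = FALSE
  )
  validate_counts(tab)
  if (sort) {
    tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
    rownames(tab) <- NULL
  }
  dup <- duplicated(tab[c("chrom", "pos")])
  if (any(dup)) {
    stop("duplicate (chrom, pos) records: ",
         paste0(tab$chrom[dup][1], ":", tab$pos[dup][1]), call. = FALSE)
  }
  class(tab) <- c("cpg_table", "data.frame")
  tab
}

validate_counts <- function(tab) {
  for (col in c("m1", "u1", "m2", "u2")) {
    x <- tab[[col]]
    if (anyNA(x)) stop("non-integer or missing count in column ", col, call. = FALSE)
    if (any(x < 0)) stop("negative count in column ", col, call. = FALSE)
  }
  invisible(tab)
}

#' Read a per-CpG two-sample count table
#'
#' Supported formats:
#' \describe{
#'   \item{`"counts-tsv"`}{one TAB-separated file with 6 columns
#'     `chrom pos m1 u1 m2 u2`; lines starting with `#` are comments.}
#'   \item{`"bedgraph-pair"`}{two files (sample 1, sample 2), each with
#'     columns `chrom start end m u`; the two are joined on `(chrom, start)`
#'     and sites missing from one sample get zero counts there.}
#' }
#'
#' Input positions are taken 0-based unless `one_based = TRUE`. Unsorted
#' input is sorted with a warning; negative, missing or non-integer counts
#' and duplicate sites are errors naming the offending record.
#'
#' @param path file path (`counts-tsv`) or character vector of two paths
#'   (`bedgraph-pair`).
#' @param format input format, see Details.
#' @param one_based interpret the position column as 1-based and shift down.
#' @return A [cpg_table()].
#' @export
read_cpg_table <- function(path, format = c("counts-tsv", "bedgraph-pair"),
                           one_based = FALSE) {
  format <- match.arg(format)
  if (format == "counts-tsv") {
    tab <- read_counts_tsv(path)
  } else {
    if (length(path) != 2) {
      stop("bedgraph-pair format needs two paths (sample 1, sample 2)", call. = FALSE)
    }
    tab <- read_bedgraph_pair(path[1], path[2])
  }
  if (one_based) tab$pos <- tab$pos - 1L
  if (any(tab$pos < 0)) stop("negative position after coordinate adjustment", call. = FALSE)
  if (!identical(order(tab$chrom, tab$pos), seq_len(nrow(tab)))) {
    warning("input not sorted by (chrom, pos); sorting", call. = FALSE)
  }
  cpg_table(tab$chrom, tab$pos, tab$m1, tab$u1, tab$m2, tab$u2)
}

read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  lineno <- seq_along(lines)[keep]
  if (length(body) == 0) {
    return(data.frame(chrom = character(), pos = integer(), m1 = integer(),
                      u1 = integer(), m2 = integer(), u2 = integer()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6)) {
    bad <- which(nf != 6)[1]
    stop(sprintf("line %d: expected 6 TAB-separated columns, got %d",
                 lineno[bad], nf[bad]), call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  num <- suppressWarnings(apply(mat[, 2:6, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 5)
  bad <- which(rowSums(is.na(num)) > 0 | rowSums(num != floor(num)) > 0)
  if (length(bad)) {
    stop(sprintf("line %d: non-integer count or position", lineno[bad[1]]), call. = FALSE)
  }
  bad <- which(rowSums(num[, 2:5, drop = FALSE] < 0) > 0)
  if (length(bad)) {
    stop(sprintf("line %d: negative count", lineno[bad[1]]), call. = FALSE)
  }
  data.frame(chrom = mat[, 1], pos = as.integer(num[, 1]),
             m1 = as.integer(num[, 2]), u1 = as.integer(num[, 3]),
             m2 = as.integer(num[, 4]), u2 = as.integer(num[, 5]),
             stringsAsFactors = FALSE)
}

read_bedgraph_one <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("chrom", "start", "end", "m", "u"),
                           colClasses = c("character", "integer", "integer",
                                          "integer", "integer"))
  if (any(tab$m < 0 | tab$u < 0)) stop("negative count in ", path, call. = FALSE)
  tab
}

read_bedgraph_pair <- function(path1, path2) {
  s1 <- read_bedgraph_one(path1)
  s2 <- read_bedgraph_one(path2)
  key1 <- paste(s1$chrom, s1$start)
  key2 <- paste(s2$chrom, s2$start)
  all_key <- union(key1, key2)
  i1 <- match(all_key, key1)
  i2 <- match(all_key, key2)
  chrom <- ifelse(is.na(i1), s2$chrom[i2], s1$chrom[i1])
  pos <- ifelse(is.na(i1), s2$start[i2], s1$start[i1])
  z <- function(x) ifelse(is.na(x), 0L, x)
  data.frame(chrom = chrom, pos = as.integer(pos),
             m1 = z(s1$m[i1]), u1 = z(s1$u[i1]),
             m2 = z(s2$m[i2]), u2 = z(s2$u[i2]),
             stringsAsFactors = FALSE)
}

#' Merge plus- and minus-strand cytosine counts into per-CpG records
#'
#' A CpG dinucleotide has a cytosine on each strand: the minus-strand C sits
#' one base downstream of the plus-strand C. Counts of a minus-strand record
#' at `pos p + 1` are added to the plus-strand record at `pos p` and reported
#' at the plus-strand coordinate. Unpaired records on either strand are kept
#' as they are (minus-strand orphans keep their own coordinate), with a
#' message reporting how many.
#'
#' @param plus,minus [cpg_table()]s of plus- and minus-strand cytosine counts.
#' @return A merged [cpg_table()].
#' @export
merge_strands <- function(plus, minus) {
  stopifnot(inherits(plus, "cpg_table"), inherits(minus, "cpg_table"))
  if (nrow(minus) == 0) return(plus)
  if (nrow(plus) == 0) return(minus)
  key_plus <- paste(plus$chrom, plus$pos)
  key_partner <- paste(minus$chrom, minus$pos - 1L)
  hit <- match(key_partner, key_plus)
  paired <- !is.na(hit)
  out <- plus
  idx <- hit[paired]
  for (col in c("m1", "u1", "m2", "u2")) {
    out[[col]][idx] <- out[[col]][idx] + minus[[col]][paired]
  }
  orphans <- minus[!paired, , drop = FALSE]
  if (nrow(orphans) > 0) {
    message(nrow(orphans), " minus-strand record(s) without a plus-strand partner retained as-is")
    out <- rbind(as.data.frame(out), as.data.frame(orphans))
  }
  cpg_table(out$chrom, out$pos, out$m1, out$u1, out$m2, out$u2)
}

#' Write ranked DMRs as a BED file
#'
#' Writes BED6-style rows `chrom start end name score strand llr`:
#' `name` is `DMR<rank>` in score order, the BED score column carries the
#' log-likelihood ratio rounded to 2 decimals, `strand` encodes direction
#' (`+` = Up, hypermethylated in sample 1; `-` = Down), and column 7 repeats
#' the score at full precision. Rows with equal scores are ordered by
#' `(chrom, start)`. A `#`-comment header records run parameters.
#'
#' @param dmrs a data frame of DMRs as returned by [extract_dmrs()], ranked
#'   by descending score.
#' @param path output file path.
#' @param params optional named list recorded in the header.
#' @return `path`, invisibly.
#' @export
write_dmrs <- function(dmrs, path, params = NULL) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines("# dmrhmm DMR calls (BED6 + full-precision LLR in column 7)", con)
  if (!is.null(params) && length(params)) {
    writeLines(paste0("# ", names(params), "=",
                      vapply(params, function(p) paste(format(p), collapse = ","), "")),
               con)
  }
  if (nrow(dmrs) == 0) return(invisible(path))
  ord <- order(-dmrs$score, dmrs$chrom, dmrs$start)
  dmrs <- dmrs[ord, , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\tDMR%d\t%s\t%s\t%s",
                   dmrs$chrom, dmrs$start, dmrs$end, seq_len(nrow(dmrs)),
                   formatC(dmrs$score, format = "f", digits = 2),
                   ifelse(dmrs$direction == "Up", "+", "-"),
                   formatC(dmrs$score, format = "g", digits = 17))
  writeLines(lines, con)
  invisible(path)
}

#' Read DMRs back from a BED file written by [write_dmrs()]
#'
#' @param path BED file path.
#' @return A DMR data frame (`chrom`, `start`, `end`, `direction`, `score`).
#' @export
read_dmrs <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      direction = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  data.frame(chrom = fields[, 1], start = as.integer(fields[, 2]),
             end = as.integer(fields[, 3]),
             direction = ifelse(fields[, 6] == "+", "Up", "Down"),
             score = as.numeric(fields[, 7]), stringsAsFactors = FALSE)
}

#' Write a [cpg_table()] in the 6-column TSV count format
#'
#' @param table a [cpg_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cpg_table <- function(table, path) {
  lines <- sprintf("%s\t%d\t%d\t%d\t%d\t%d", table$chrom, table$pos,
                   table$m1, table$u1, table$m2, table$u2)
  writeLines(lines, path)
  invisible(path)
}

# inter-CpG gap lengths (interval positions between consecutive CpG
# cytosines) for one chromosome's positions: d_i = pos_{i+1} - pos_i - 1
gap_lengths <- function(pos) {
  if (length(pos) < 2) return(integer(0))
  as.integer(diff(pos) - 1L)
}

# split a cpg_table into per-chromosome row index lists, preserving order
chrom_index <- function(table) {
  split(seq_len(nrow(table)), table$chrom)
}
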