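#' Per-position Phred and GC-content summary of a read set
#'
#' One pass over the reads accumulates (i) a matrix of Phred score
#' occurrence counts per read position and (ii) a histogram of per-read
#' GC percentages.  GC\% is \code{100 * (G + C) / (A + C + G + T)} with
#' \code{N} excluded from numerator and denominator, rounded half up to
#' an integer; all-\code{N} reads contribute nothing to the histogram.
#'
#' @param reads a [fastq_reads] object.
#' @return An object of class \code{quality_profile}: a list with
#'   \code{phred_counts} (matrix \code{[position, Phred 0-93]}),
#'   \code{gc_histogram} (named counts for GC\% 0--100),
#'   \code{max_read_length} and \code{n_reads}.
#' @export
collect_quality <- function(reads) {
  stopifnot(inherits(reads, "fastq_reads"))
  lens <- nchar(reads$quality)
  max_len <- if (length(lens)) max(lens, 0L) else 0L
  phred_counts <- matrix(0, nrow = max_len, ncol = 94L,
                         dimnames = list(NULL, 0:93))
  for (s in reads$quality) {
    q <- decode_phred(s)
    if (length(q))
      phred_counts[cbind(seq_along(q), q + 1L)] <-
        phred_counts[cbind(seq_along(q), q + 1L)] + 1
  }
  gc <- nchar(gsub("[^GC]", "", reads$sequence))
  acgt <- nchar(gsub("[^ACGT]", "", reads$sequence))
  keep <- acgt > 0L
  gc_bin <- floor(100 * gc[keep] / acgt[keep] + 0.5)  # round half up
  gc_histogram <- stats::setNames(tabulate(gc_bin + 1L, nbins = 101L), 0:100)
  structure(list(phred_counts = phred_counts, gc_histogram = gc_histogram,
                 max_read_length = max_len, n_reads = length(reads)),
            class = "quality_profile")
}

#' @export
print.quality_profile <- function(x, ...) {
  cat("quality_profile: ", x$n_reads, " reads, max length ",
      x$max_read_length, "\n", sep = "")
  invisible(x)
}

#' Median Phred score per read position
#'
#' Computed from the position-by-Phred count matrix; for positions with
#' an even number of observations the lower median (the n/2-th order
#' statistic) is returned, so the result is always an attained integer
#' Phred score.
#'
#' @param qp a [collect_quality()] profile.
#' @return Integer vector of per-position medians, length
#'   \code{max_read_length}.
#' @export
median_phred_by_position <- function(qp) {
  stopifnot(inherits(qp, "quality_profile"))
  if (qp$n_reads == 0L)
    stop("cannot compute medians of an empty profile")
  apply(qp$phred_counts, 1L, function(row) {
    n <- sum(row)
    if (n == 0) return(NA_integer_)
    rank <- (n + n %% 2) / 2          # lower median
    which(cumsum(row) >= rank)[1L] - 1L
  })
}

#' Filter reads on a minimum Phred score
#'
#' A read is kept iff every base has Phred score \code{>= min_phred}
#' (a read with at least one score strictly below the threshold is
#' discarded).  Zero-length reads are discarded with a warning.  Order
#' is preserved and the filter is idempotent.
#'
#' @param reads a [fastq_reads] object.
#' @param min_phred integer threshold in \code{[0, 93]}.
#' @return A list with \code{reads} (the kept [fastq_reads]) and
#'   \code{stats} (\code{n_in}, \code{n_out}, \code{fraction_discarded}).
#' @examples
#' fq <- fastq_reads(c("a", "b"), c("ACGT", "ACGT"),
#'                   list(rep(30L, 4), c(40L, 29L, 40L, 40L)))
#' phred_filter(fq, 30)$stats$n_out  # 1: the second read has a 29
#' @export
phred_filter <- function(reads, min_phred) {
  stopifnot(inherits(reads, "fastq_reads"),
            min_phred >= 0, min_phred <= 93)
  n_in <- length(reads)
  empty <- !nzchar(reads$quality)
  if (any(empty))
    warning(sum(empty), " zero-length read(s) discarded")
  min_q <- rep(-1L, n_in)
  min_q[!empty] <- vapply(reads$quality[!empty],
                          function(s) min(utf8ToInt(s)), integer(1)) - 33L
  keep <- min_q >= min_phred & !empty
  kept <- reads[keep]
  list(reads = kept,
       stats = list(n_in = n_in, n_out = length(kept),
                    fraction_discarded =
                      if (n_in) (n_in - length(kept)) / n_in else 0))
}

#' Filter a FASTQ file on a minimum Phred score
#'
#' Streaming variant of [phred_filter()]: reads \code{in_path} chunk by
#' chunk and writes kept reads to \code{out_path}.
#'
#' @param in_path input FASTQ (\code{.gz} supported).
#' @param out_path output FASTQ (\code{.gz} suffix selects gzip).
#' @param min_phred integer threshold in \code{[0, 93]}.
#' @return The `stats` list of [phred_filter()], invisibly.
#' @export
phred_filter_file <- function(in_path, out_path, min_phred) {
  con <- fastq_connection(out_path, "wt")
  on.exit(close(con))
  n_in <- 0L
  n_out <- 0L
  stream_fastq(in_path, function(fq) {
    res <- phred_filter(fq, min_phred)
    n_in <<- n_in + res$stats$n_in
    n_out <<- n_out + res$stats$n_out
    kept <- res$reads
    if (length(kept)) {
      m <- length(kept)
      out <- character(4L * m)
      out[seq(1L, 4L * m, by = 4L)] <- paste0("@", kept$id)
      out[seq(2L, 4L * m, by = 4L)] <- kept$sequence
      out[seq(3L, 4L * m, by = 4L)] <- "+"
      out[seq(4L, 4L * m, by = 4L)] <- kept$quality
      writeLines(out, con)
    }
  })
  invisible(list(n_in = n_in, n_out = n_out,
                 fraction_discarded = if (n_in) (n_in - n_out) / n_in else 0))
}
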