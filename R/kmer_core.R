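#' k-mer count profile of one sample
#'
#' A dense vector of occurrence counts over all \eqn{4^k} DNA words of
#' length \code{k}, together with read bookkeeping for one sample (one
#' FASTQ file, one lane, or one merged flowcell).  Counts are stored as
#' doubles so that flowcell-level sums remain exact well past 32-bit
#' range.
#'
#' @param k integer word size, between 1 and 12.
#' @param counts numeric vector of length \code{4^k} of non-negative
#'   counts.
#' @param n_reads number of reads seen (including reads shorter than
#'   \code{k}, which contribute no windows).
#' @param label sample identifier.
#' @return An object of class \code{kmer_profile} with fields \code{k},
#'   \code{counts}, \code{n_reads}, \code{n_kmers_total} (the sum of
#'   \code{counts}) and \code{label}.
#' @export
kmer_profile <- function(k, counts, n_reads = NA_real_, label = "") {
  k <- check_k(k)
  counts <- as.numeric(counts)
  if (length(counts) != 4^k)
    stop("counts must have length 4^k = ", 4^k, ", got ", length(counts))
  if (any(counts < 0))
    stop("counts must be non-negative")
  structure(list(k = k, counts = counts, n_reads = as.numeric(n_reads),
                 n_kmers_total = sum(counts), label = as.character(label)),
            class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat("kmer_profile '", x$label, "': k=", x$k, ", ",
      format(x$n_kmers_total, big.mark = ","), " k-mers from ",
      format(x$n_reads, big.mark = ","), " reads\n", sep = "")
  invisible(x)
}

check_k <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > 12L)
    stop("k must be a single integer between 1 and 12")
  k
}

#' Map a DNA word to its profile index and back
#'
#' Canonical indexing of the \eqn{4^k} words: base-4 encoding with
#' \code{A=0, C=1, G=2, T=3}, leftmost base most significant, yielding
#' indices in \code{[0, 4^k)}.  `motif_string()` is the inverse.
#'
#' @param motif a single DNA word over \code{A,C,G,T}.
#' @param index integer index in \code{[0, 4^k)}.
#' @param k word size.
#' @return `motif_index()` an integer index; `motif_string()` the word.
#' @examples
#' motif_index("ACG")        # 0*16 + 1*4 + 2 = 6
#' motif_string(6, k = 3)    # "ACG"
#' @export
motif_index <- function(motif) {
  stopifnot(length(motif) == 1L)
  b <- match(strsplit(toupper(motif), "")[[1]], c("A", "C", "G", "T")) - 1L
  if (anyNA(b))
    stop("motif must contain only A, C, G, T: ", motif)
  sum(b * 4^rev(seq_along(b) - 1L))
}

#' @rdname motif_index
#' @export
motif_string <- function(index, k) {
  k <- check_k(k)
  stopifnot(all(index >= 0), all(index < 4^k))
  vapply(index, function(i) {
    digits <- integer(k)
    for (p in k:1) {
      digits[p] <- i %% 4
      i <- i %/% 4
    }
    paste(c("A", "C", "G", "T")[digits + 1L], collapse = "")
  }, character(1))
}

#' All k-mer strings in index order
#'
#' @param k word size.
#' @return Character vector of length \code{4^k}: the words ordered by
#'   [motif_index()].
#' @export
kmer_names <- function(k) {
  k <- check_k(k)
  b <- c("A", "C", "G", "T")
  out <- b
  if (k > 1L) for (i in 2:k) out <- paste0(rep(out, each = 4L), b)
  out
}

#' Count k-mers in a set of reads
#'
#' Single-pass dense counting: every window of \code{k} consecutive
#' bases consisting only of \code{A,C,G,T} increments exactly one of the
#' \eqn{4^k} counters; windows touching an \code{N} are skipped; reads
#' shorter than \code{k} contribute nothing (but are still counted in
#' \code{n_reads}).  Memory grows with \eqn{4^k}, not with the number of
#' reads.
#'
#' @param reads a [fastq_reads] object (or a plain character vector of
#'   DNA sequences).
#' @param k word size, 1--12.
#' @param label sample identifier stored in the profile.
#' @return A [kmer_profile].
#' @examples
#' fq <- fastq_reads("r", "ACGT", "IIII")
#' p <- count_kmers(fq, k = 2)
#' p$counts[motif_index("AC") + 1]  # 1
#' @export
count_kmers <- function(reads, k, label = "") {
  k <- check_k(k)
  seqs <- if (inherits(reads, "fastq_reads")) reads$sequence
          else normalize_dna(as.character(reads))
  counts <- .Call(C_count_kmers, seqs, k)
  kmer_profile(k, counts, n_reads = length(seqs), label = label)
}

#' Count k-mers of a FASTQ file in bounded memory
#'
#' Streams the file chunk-wise through [stream_fastq()] so that memory
#' use is independent of the number of reads.
#'
#' @inheritParams stream_fastq
#' @inheritParams count_kmers
#' @return A [kmer_profile]; `label` defaults to the file name.
#' @export
count_kmers_file <- function(path, k, label = basename(path),
                             chunk_size = 50000L) {
  k <- check_k(k)
  counts <- numeric(4^k)
  n_reads <- 0
  stream_fastq(path, function(fq) {
    counts <<- counts + .Call(C_count_kmers, fq$sequence, k)
    n_reads <<- n_reads + length(fq)
  }, chunk_size = chunk_size)
  kmer_profile(k, counts, n_reads = n_reads, label = label)
}

#' Merge two k-mer profiles
#'
#' Component-wise sum of counts; \code{n_reads} and
#' \code{n_kmers_total} add.  Merging is associative and commutative, so
#' per-lane profiles can be combined into flowcell profiles in any
#' order, and counting files separately then merging equals counting the
#' concatenated stream.
#'
#' @param a,b [kmer_profile] objects with identical \code{k}.
#' @param label label of the merged profile; defaults to joining the
#'   input labels with \code{"+"}.
#' @return A [kmer_profile].
#' @export
merge_profiles <- function(a, b, label = NULL) {
  stopifnot(inherits(a, "kmer_profile"), inherits(b, "kmer_profile"))
  if (a$k != b$k)
    stop("cannot merge profiles with different k (", a$k, " vs ", b$k, ")")
  if (is.null(label))
    label <- paste(c(a$label, b$label)[nzchar(c(a$label, b$label))],
                   collapse = "+")
  kmer_profile(a$k, a$counts + b$counts,
               n_reads = a$n_reads + b$n_reads, label = label)
}

#' Scale a profile to a common k-mer total
#'
#' Multiplies the count vector by \code{target_total / sum(counts)} so
#' that profiles from samples of different sequencing depth become
#' comparable before the Canberra distance is computed; proportions
#' between components are preserved exactly.
#'
#' @param p a [kmer_profile].
#' @param target_total positive total the scaled counts should sum to.
#' @return Numeric vector of scaled (non-negative real) counts.
#' @export
scale_profile <- function(p, target_total) {
  stopifnot(inherits(p, "kmer_profile"))
  if (!is.numeric(target_total) || length(target_total) != 1L ||
      target_total <= 0)
    stop("target_total must be a single positive number")
  if (p$n_kmers_total <= 0)
    stop("cannot scale an empty (all-zero) profile: ", p$label)
  p$counts * (target_total / p$n_kmers_total)
}

#' Bundle profiles of several samples
#'
#' @param profiles list of [kmer_profile] objects sharing one \code{k}
#'   and carrying unique labels.
#' @param groups optional vector mapping each profile to a group
#'   (flowcell, batch, treatment); recycled names from profile labels.
#' @return An object of class \code{profile_set}.
#' @export
profile_set <- function(profiles, groups = NULL) {
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "kmer_profile")))
  ks <- vapply(profiles, `[[`, numeric(1), "k")
  if (length(unique(ks)) != 1L)
    stop("all profiles in a set must share one k")
  labels <- vapply(profiles, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("profile labels must be unique within a set")
  if (!is.null(groups)) {
    if (length(groups) != length(profiles))
      stop("groups must have one entry per profile")
    groups <- stats::setNames(as.character(groups), labels)
  }
  structure(list(profiles = profiles, labels = labels, groups = groups,
                 k = ks[1]), class = "profile_set")
}

#' @export
length.profile_set <- function(x) length(x$profiles)

#' @export
print.profile_set <- function(x, ...) {
  cat("profile_set: ", length(x), " profiles, k=", x$k, "\n", sep = "")
  invisible(x)
}

#' Read and write k-mer profiles as TSV
#'
#' The on-disk format is a tab-separated table with columns
#' \code{motif} and \code{count}, preceded by comment header lines
#' recording \code{k}, \code{n_reads} and \code{label}.
#'
#' @param p a [kmer_profile].
#' @param path file path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a [kmer_profile].
#' @export
write_profile <- function(p, path) {
  stopifnot(inherits(p, "kmer_profile"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# k=%d", p$k),
               sprintf("# n_reads=%.0f", p$n_reads),
               sprintf("# label=%s", p$label)), con)
  utils::write.table(data.frame(motif = kmer_names(p$k), count = p$counts),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  hdr <- readLines(path, n = 3L)
  get_field <- function(name) sub(paste0("^# ", name, "="), "", grep(
    paste0("^# ", name, "="), hdr, value = TRUE)[1])
  k <- as.integer(get_field("k"))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           colClasses = c("character", "numeric"))
  counts <- numeric(4^k)
  counts[vapply(tab$motif, motif_index, numeric(1)) + 1L] <- tab$count
  kmer_profile(k, counts, n_reads = as.numeric(get_field("n_reads")),
               label = get_field("label"))
}
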