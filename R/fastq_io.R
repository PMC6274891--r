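#' In-memory FASTQ read set
#'
#' A columnar container for a set of sequencing reads: read identifiers,
#' upper-cased DNA sequences over the alphabet \code{A,C,G,T,N}, and base
#' qualities kept in their Phred+33 ASCII encoding.  Qualities are decoded
#' to integer Phred scores on demand by [phred_scores()].
#'
#' Sequences are case-normalised to upper case and every character other
#' than \code{A}, \code{C}, \code{G}, \code{T} (including IUPAC ambiguity
#' codes) is mapped to \code{N}.  The k-mer counter skips windows that
#' touch an \code{N}.
#'
#' @param id character vector of read identifiers (without the leading
#'   \code{@}).
#' @param sequence character vector of DNA sequences.
#' @param quality character vector of Phred+33 encoded quality strings,
#'   one per read, each the same length as its sequence.  Alternatively a
#'   list of integer Phred scores (0--93), which is encoded.
#' @return An object of class \code{fastq_reads}.
#' @examples
#' fq <- fastq_reads("r1", "acgt", list(c(40L, 40L, 40L, 40L)))
#' sequences(fq)      # "ACGT"
#' phred_scores(fq)   # list of integer vectors
#' @export
fastq_reads <- function(id, sequence, quality) {
  id <- as.character(id)
  sequence <- normalize_dna(as.character(sequence))
  if (is.list(quality)) {
    quality <- vapply(quality, encode_phred, character(1))
  }
  quality <- as.character(quality)
  n <- length(id)
  if (length(sequence) != n || length(quality) != n)
    stop("id, sequence and quality must have the same length")
  bad <- which(nchar(sequence) != nchar(quality))
  if (length(bad))
    stop("sequence/quality length mismatch for read(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  structure(list(id = id, sequence = sequence, quality = quality),
            class = "fastq_reads")
}

#' @export
length.fastq_reads <- function(x) length(x$id)

#' @export
print.fastq_reads <- function(x, ...) {
  cat("fastq_reads: ", length(x), " read(s)\n", sep = "")
  if (length(x)) {
    i <- seq_len(min(3L, length(x)))
    cat(paste0("  @", x$id[i], " ", x$sequence[i]), sep = "\n")
    if (length(x) > 3L) cat("  ...\n")
  }
  invisible(x)
}

#' @export
`[.fastq_reads` <- function(x, i) {
  fastq_reads(x$id[i], x$sequence[i], x$quality[i])
}

#' Read sequences and qualities of a read set
#'
#' @param x a [fastq_reads] object.
#' @return `sequences()` returns the character vector of DNA sequences;
#'   `phred_scores()` returns a list of integer Phred score vectors, one
#'   per read.
#' @export
sequences <- function(x) x$sequence

#' @rdname sequences
#' @export
phred_scores <- function(x) lapply(x$quality, decode_phred)

## ---- Phred+33 codec ------------------------------------------------------
## Offset fixed at 33 (Illumina >= 1.8 / CASAVA 1.8.2); Phred+64 input is
## not autodetected -- silent mis-decoding is worse than a hard error.

decode_phred <- function(s) {
  if (!nchar(s)) return(integer(0))
  q <- utf8ToInt(s) - 33L
  if (any(q < 0L))
    stop("quality character below '!' (not Phred+33)")
  q
}

encode_phred <- function(q) {
  if (!length(q)) return("")
  if (any(q < 0L | q > 93L))
    stop("Phred scores must be in [0, 93]")
  intToUtf8(as.integer(q) + 33L)
}

normalize_dna <- function(s) {
  s <- toupper(s)
  gsub("[^ACGT]", "N", s)
}

fastq_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Stream a FASTQ file in chunks
#'
#' Low-level single-pass reader: the file is consumed in chunks of
#' \code{chunk_size} records and each chunk is handed to \code{callback}
#' as a [fastq_reads] object, so memory use is bounded by the chunk size,
#' not the file size.  [read_fastq()], [count_kmers_file()] and the other
#' file-level operations are built on this.
#'
#' @param path path to a FASTQ file; a \code{.gz} suffix selects
#'   transparent gzip decompression.
#' @param callback function of one argument (a [fastq_reads] chunk);
#'   called once per chunk in file order.
#' @param chunk_size number of records per chunk.
#' @return The total number of records processed, invisibly.
#' @export
stream_fastq <- function(path, callback, chunk_size = 50000L) {
  if (!file.exists(path))
    stop("file not found: ", path)
  con <- fastq_connection(path, "rt")
  on.exit(close(con))
  n_seen <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_size, warn = FALSE)
    if (!length(lines)) break
    if (length(lines) %% 4L != 0L)
      stop("truncated FASTQ record at record ",
           n_seen + length(lines) %/% 4L + 1L, " in ", path)
    idx <- seq(1L, length(lines), by = 4L)
    hdr <- lines[idx]
    seqs <- lines[idx + 1L]
    plus <- lines[idx + 2L]
    qual <- lines[idx + 3L]
    bad <- which(substr(hdr, 1L, 1L) != "@")
    if (length(bad))
      stop("missing '@' marker at record ", n_seen + bad[1L], " in ", path)
    bad <- which(substr(plus, 1L, 1L) != "+")
    if (length(bad))
      stop("missing '+' marker at record ", n_seen + bad[1L], " in ", path)
    bad <- which(nchar(seqs) != nchar(qual))
    if (length(bad))
      stop("sequence/quality length mismatch at record ",
           n_seen + bad[1L], " in ", path)
    if (any(vapply(qual[nzchar(qual)],
                   function(s) min(utf8ToInt(s)), integer(1)) < 33L))
      stop("quality character below '!' (not Phred+33) in ", path)
    callback(fastq_reads(sub("^@", "", hdr), seqs, qual))
    n_seen <- n_seen + length(idx)
    if (length(lines) < 4L * chunk_size) break
  }
  invisible(n_seen)
}

#' Read a FASTQ file into memory
#'
#' Parses a 4-line-record FASTQ file (plain or gzip, Phred+33) into a
#' [fastq_reads] object.  Sequences are upper-cased and non-ACGT
#' characters become \code{N}; malformed records raise an error naming
#' the record index.
#'
#' @inheritParams stream_fastq
#' @return A [fastq_reads] object with records in file order.
#' @seealso [stream_fastq()] for bounded-memory chunked processing.
#' @export
read_fastq <- function(path) {
  chunks <- list()
  stream_fastq(path, function(fq) chunks[[length(chunks) + 1L]] <<- fq)
  if (!length(chunks))
    return(fastq_reads(character(0), character(0), character(0)))
  structure(list(id = unlist(lapply(chunks, `[[`, "id"), use.names = FALSE),
                 sequence = unlist(lapply(chunks, `[[`, "sequence"),
                                   use.names = FALSE),
                 quality = unlist(lapply(chunks, `[[`, "quality"),
                                  use.names = FALSE)),
            class = "fastq_reads")
}

#' Write reads to a FASTQ file
#'
#' @param reads a [fastq_reads] object.
#' @param path output path; a \code{.gz} suffix selects gzip compression.
#' @return The number of records written, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "fastq_reads"))
  con <- fastq_connection(path, "wt")
  on.exit(close(con))
  n <- length(reads)
  if (n) {
    out <- character(4L * n)
    out[seq(1L, 4L * n, by = 4L)] <- paste0("@", reads$id)
    out[seq(2L, 4L * n, by = 4L)] <- reads$sequence
    out[seq(3L, 4L * n, by = 4L)] <- "+"
    out[seq(4L, 4L * n, by = 4L)] <- reads$quality
    writeLines(out, con)
  }
  invisible(n)
}
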