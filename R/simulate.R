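#' Configuration of a contamination simulation
#'
#' Bundles every parameter of one two-group separation experiment: a
#' pure-random group of FASTQ files is compared against a group in
#' which a fraction of reads carries a fixed DNA 6-mer, and the
#' clustering pipeline is asked to separate them.
#'
#' Defaults define the study conditions: 8 files per group, 10,000
#' uniform-random 100-nt reads per file, counting at k = 6, one fixed
#' 6-mer, constant Phred 40 qualities.  With 8 files per group the
#' analytic permutation-null mean of the Contralaterality Score is
#' about 40.5\%, matching the pure-random anchor of the method.
#'
#' @param n_files_per_group FASTQ files (samples) per group.
#' @param reads_per_file reads per file.
#' @param read_length read length in nt.
#' @param k word size used by the counting/clustering pipeline.
#' @param motifs character vector of fixed DNA 6-mers to spike in;
#'   contamination applies to group 2 only.
#' @param contamination_fraction fraction of group-2 reads carrying a
#'   motif, in \code{[0, 1]}.
#' @param quality constant Phred score given to every simulated base.
#' @param seed master seed; all randomness derives from it.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_files_per_group = 8L,
                       reads_per_file = 10000L,
                       read_length = 100L,
                       k = 6L,
                       motifs = "ACGTCA",
                       contamination_fraction = 0,
                       quality = 40L,
                       seed = 1L) {
  stopifnot(n_files_per_group >= 2L, reads_per_file >= 1L,
            read_length >= 1L,
            contamination_fraction >= 0, contamination_fraction <= 1,
            quality >= 0, quality <= 93)
  k <- check_k(k)
  motifs <- toupper(as.character(motifs))
  if (!length(motifs) || any(nchar(motifs) != 6L) ||
      any(grepl("[^ACGT]", motifs)))
    stop("motifs must be DNA 6-mers over A, C, G, T")
  structure(list(n_files_per_group = as.integer(n_files_per_group),
                 reads_per_file = as.integer(reads_per_file),
                 read_length = as.integer(read_length),
                 k = k, motifs = motifs,
                 contamination_fraction = contamination_fraction,
                 quality = as.integer(quality),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_files_per_group, " files/group x ",
      x$reads_per_file, " reads x ", x$read_length, " nt, k=", x$k,
      ", contamination ", 100 * x$contamination_fraction, "% (",
      paste(x$motifs, collapse = ","), "), seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Generate uniform-random FASTQ reads
#'
#' Each base is drawn i.i.d. uniformly from \code{{A, C, G, T}}; every
#' base gets the same constant Phred score.  The output is a function of
#' the R random number state only, so a fixed seed reproduces the reads
#' (and any file written from them) byte for byte.
#'
#' @param n_reads number of reads.
#' @param read_length length of every read in nt.
#' @param quality constant Phred score (0--93) for all bases.
#' @param id_prefix read identifiers become
#'   \code{<id_prefix>_1 ... <id_prefix>_n}.
#' @return A [fastq_reads] object.
#' @export
random_fastq <- function(n_reads, read_length, quality = 40L,
                         id_prefix = "sim") {
  stopifnot(n_reads >= 1L, read_length >= 1L)
  codes <- sample.int(4L, n_reads * read_length, replace = TRUE)
  big <- rawToChar(as.raw(c(0x41, 0x43, 0x47, 0x54))[codes])  # A C G T
  starts <- (seq_len(n_reads) - 1L) * read_length + 1L
  seqs <- substring(big, starts, starts + read_length - 1L)
  qual <- strrep(encode_phred(quality), read_length)
  structure(list(id = paste0(id_prefix, "_", seq_len(n_reads)),
                 sequence = seqs,
                 quality = rep(qual, n_reads)),
            class = "fastq_reads")
}

#' Spike fixed motifs into a fraction of reads
#'
#' Each read is independently selected with probability
#' \code{fraction}; in a selected read one motif (chosen uniformly from
#' \code{motifs}) overwrites the bases at a uniformly chosen valid
#' offset.  Overwriting (rather than inserting) keeps read length and
#' total k-mer counts constant, so the contamination signal is purely a
#' shift in motif frequencies.
#'
#' @param reads a [fastq_reads] object.
#' @param motifs character vector of DNA motifs.
#' @param fraction probability that a read is contaminated, in
#'   \code{[0, 1]}.
#' @return A [fastq_reads] object of the same length and read lengths.
#' @export
contaminate <- function(reads, motifs, fraction) {
  stopifnot(inherits(reads, "fastq_reads"),
            fraction >= 0, fraction <= 1, length(motifs) >= 1L)
  motifs <- toupper(as.character(motifs))
  if (any(grepl("[^ACGT]", motifs)))
    stop("motifs must be over A, C, G, T")
  n <- length(reads)
  if (fraction == 0 || n == 0L) return(reads)
  sel <- which(stats::runif(n) < fraction)
  if (!length(sel)) return(reads)
  mot <- motifs[sample.int(length(motifs), length(sel), replace = TRUE)]
  room <- nchar(reads$sequence[sel]) - nchar(mot) + 1L
  if (any(room < 1L))
    stop("motif longer than read")
  offset <- 1L + floor(stats::runif(length(sel)) * room)
  seqs <- reads$sequence
  substr(seqs[sel], offset, offset + nchar(mot) - 1L) <- mot
  structure(list(id = reads$id, sequence = seqs, quality = reads$quality),
            class = "fastq_reads")
}

## One replicate: generate both groups, run the full pipeline, return CS.
simulate_replicate_cs <- function(cfg, seed) {
  set.seed(seed)
  m <- cfg$n_files_per_group
  profiles <- vector("list", 2L * m)
  groups <- character(2L * m)
  for (g in 1:2) {
    for (f in seq_len(m)) {
      label <- sprintf("g%d_f%02d", g, f)
      reads <- random_fastq(cfg$reads_per_file, cfg$read_length,
                            quality = cfg$quality, id_prefix = label)
      if (g == 2L && cfg$contamination_fraction > 0)
        reads <- contaminate(reads, cfg$motifs,
                             cfg$contamination_fraction)
      i <- (g - 1L) * m + f
      profiles[[i]] <- count_kmers(reads, cfg$k, label = label)
      groups[i] <- sprintf("group%d", g)
    }
  }
  ps <- profile_set(profiles, groups = groups)
  hc <- hierarchical_cluster(distance_matrix(ps))
  gt <- grouped_tree(hc, stats::setNames(groups, ps$labels))
  contralaterality_score(gt)
}

#' Run the two-group separation experiment
#'
#' Per replicate: group 1 gets pure uniform-random FASTQ files, group 2
#' the same with \code{contamination_fraction} of its reads carrying a
#' fixed 6-mer; k-mers are counted, totals scaled, Canberra distances
#' clustered, and the Contralaterality Score read off the leaf order.
#' Power is the fraction of replicates whose CS falls below the
#' significance threshold.
#'
#' Each replicate runs under its own sub-seed drawn once from the
#' master seed, so the whole experiment -- and every individual
#' replicate -- is bit-reproducible.
#'
#' @param cfg a [sim_config()].
#' @param reps number of replicates.
#' @param cs_threshold significance threshold on CS (percent); the
#'   default 10 corresponds to one-sided p < 0.05 under the
#'   pure-random null.
#' @return An object of class \code{sim_result}: \code{cs_values},
#'   \code{percentiles} (5/25/50/75/95), \code{power},
#'   \code{cs_threshold}, \code{config}.
#' @export
run_separation_experiment <- function(cfg, reps = 100L,
                                      cs_threshold = 10) {
  stopifnot(inherits(cfg, "sim_config"), reps >= 1L)
  set.seed(cfg$seed)
  rep_seeds <- sample.int(2147483646L, reps)
  cs <- vapply(rep_seeds, function(s) simulate_replicate_cs(cfg, s),
               numeric(1))
  structure(list(cs_values = cs,
                 percentiles = stats::quantile(
                   cs, c(0.05, 0.25, 0.5, 0.75, 0.95)),
                 power = mean(cs < cs_threshold),
                 cs_threshold = cs_threshold,
                 config = cfg),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result: ", length(x$cs_values), " replicates at ",
      100 * x$config$contamination_fraction, "% contamination\n",
      "  mean CS ", signif(mean(x$cs_values), 4), "%, median ",
      signif(stats::median(x$cs_values), 4), "%, power(CS < ",
      x$cs_threshold, ") = ", signif(x$power, 3), "\n", sep = "")
  invisible(x)
}

#' Power curve over contamination fractions
#'
#' Runs [run_separation_experiment()] once per contamination fraction
#' and tabulates power and CS percentiles, reproducing the
#' percentile-band structure of the method's sensitivity analysis.
#' Fraction \code{i} runs under sub-seed \code{cfg$seed + i - 1}, so
#' fractions are independent and a single-fraction curve reduces
#' exactly to [run_separation_experiment()].
#'
#' @param cfg a [sim_config()]; its contamination fraction is replaced
#'   by each entry of \code{fractions} in turn.
#' @param fractions contamination fractions in \code{[0, 1]}.
#' @param reps replicates per fraction.
#' @param cs_threshold significance threshold on CS (percent).
#' @return A data frame with one row per fraction: \code{fraction},
#'   \code{power}, \code{mean_cs} and CS percentiles \code{p5} to
#'   \code{p95}.
#' @export
power_curve <- function(cfg, fractions, reps = 100L, cs_threshold = 10) {
  stopifnot(inherits(cfg, "sim_config"),
            all(fractions >= 0), all(fractions <= 1))
  rows <- lapply(seq_along(fractions), function(i) {
    cfg_i <- cfg
    cfg_i$contamination_fraction <- fractions[i]
    cfg_i$seed <- as.integer((cfg$seed + i - 1L) %% 2147483647L)
    res <- run_separation_experiment(cfg_i, reps = reps,
                                     cs_threshold = cs_threshold)
    q <- res$percentiles
    data.frame(fraction = fractions[i], power = res$power,
               mean_cs = mean(res$cs_values),
               p5 = q[[1]], p25 = q[[2]], median = q[[3]],
               p75 = q[[4]], p95 = q[[5]])
  })
  do.call(rbind, rows)
}
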