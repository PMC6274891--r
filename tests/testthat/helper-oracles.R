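# Independent brute-force oracles used across the suite.

# Naive k-mer counting: enumerate every substring of every read and tally,
# skipping windows containing anything but A/C/G/T.
oracle_count_kmers <- function(seqs, k) {
  counts <- numeric(4^k)
  names(counts) <- kmer_names(k)
  for (s in toupper(seqs)) {
    L <- nchar(s)
    if (L < k) next
    for (i in seq_len(L - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("^[ACGT]+$", w))
        counts[w] <- counts[w] + 1
    }
  }
  unname(counts)
}

# Naive Canberra with the 0/0 -> 0 convention, term by term.
oracle_canberra <- function(x, y) {
  d <- 0
  for (i in seq_along(x)) {
    den <- abs(x[i]) + abs(y[i])
    if (den > 0) d <- d + abs(x[i] - y[i]) / den
  }
  d
}

# Scale-then-all-pairs distance matrix, as a plain matrix.
oracle_distance_matrix <- function(profiles, target_total = NULL) {
  totals <- vapply(profiles, `[[`, numeric(1), "n_kmers_total")
  if (is.null(target_total)) target_total <- max(totals)
  scaled <- lapply(profiles, function(p) p$counts * target_total / sum(p$counts))
  n <- length(profiles)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- oracle_canberra(scaled[[i]], scaled[[j]])
  m
}

# Naive O(n^3) complete-linkage agglomeration; returns sorted merge heights.
oracle_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# Exact E[CS] under a uniformly random leaf permutation of two groups of
# size n: the group-1 count in the first half is Hypergeometric(2n, n, n).
oracle_expected_cs <- function(n) {
  x <- 0:n
  p <- stats::dhyper(x, n, n, n)
  100 * sum(p * pmin(x, n - x)) / n
}

# Build an hclust tree whose top-level structure we control, by clustering
# points on a line: leaves at the given 1-d coordinates, complete linkage.
tree_from_coords <- function(coords, labels) {
  stats::hclust(stats::dist(coords), method = "complete") -> hc
  hc$labels <- labels
  hc
}

random_profile <- function(k, label, lambda = 20) {
  kmer_profile(k, stats::rpois(4^k, lambda) + 1, n_reads = NA, label = label)
}
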