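#' Attach group labels to a dendrogram
#'
#' Combines a clustering tree with a mapping from leaf label to one of
#' exactly two groups (e.g. flowcell A vs flowcell B), the input for the
#' batch-effect diagnostics.
#'
#' @param dendrogram an [stats::hclust] tree with leaf labels.
#' @param group_of named vector: names are the leaf labels, values the
#'   group ids; exactly two distinct groups, both non-empty.
#' @return An object of class \code{grouped_tree}.
#' @export
grouped_tree <- function(dendrogram, group_of) {
  stopifnot(inherits(dendrogram, "hclust"))
  labels <- dendrogram$labels
  if (is.null(labels))
    labels <- as.character(seq_along(dendrogram$order))
  if (is.null(names(group_of)))
    stop("group_of must be a named vector (leaf label -> group)")
  miss <- setdiff(labels, names(group_of))
  if (length(miss))
    stop("leaves without a group: ", paste(miss, collapse = ", "))
  group_of <- stats::setNames(as.character(group_of[labels]), labels)
  if (length(unique(group_of)) != 2L)
    stop("exactly two groups are required, got ",
         length(unique(group_of)))
  structure(list(dendrogram = dendrogram, group_of = group_of),
            class = "grouped_tree")
}

#' @export
print.grouped_tree <- function(x, ...) {
  cat("grouped_tree: ", length(x$group_of), " leaves, groups {",
      paste(unique(x$group_of), collapse = ", "), "}\n", sep = "")
  invisible(x)
}

## Leaf index sets of every internal node of an hclust merge tree,
## bottom-up (row i of $merge only references rows < i).
node_leaf_sets <- function(hc) {
  m <- hc$merge
  n_nodes <- nrow(m)
  sets <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    left <- if (m[i, 1] < 0) -m[i, 1] else sets[[m[i, 1]]]
    right <- if (m[i, 2] < 0) -m[i, 2] else sets[[m[i, 2]]]
    sets[[i]] <- c(left, right)
  }
  sets
}

#' Contralaterality Score of a two-group dendrogram
#'
#' Quantifies how well the clustering separates two equal-sized groups:
#' take the first half of the tree's left-to-right leaf order, count the
#' leaves \code{a} belonging to group 1, and report
#' \code{CS = 100 * min(a, n - a) / n} (n leaves per group).  CS is 0
#' for perfect top-level separation, 50 for complete mixing, and is
#' invariant both to swapping the group labels and to mirror-flipping
#' the tree.
#'
#' @param gt a [grouped_tree()] with two groups of equal size
#'   \code{n >= 2}.
#' @return CS as a percentage in \code{[0, 50]}.
#' @export
contralaterality_score <- function(gt) {
  stopifnot(inherits(gt, "grouped_tree"))
  groups <- gt$group_of
  sizes <- table(groups)
  if (length(sizes) != 2L || sizes[1] != sizes[2])
    stop("CS requires two groups of equal size (got ",
         paste(sizes, collapse = " and "), ")")
  n <- as.integer(sizes[1])
  if (n < 2L)
    stop("CS requires at least 2 samples per group")
  ord <- leaf_order(gt$dendrogram)
  first_half <- groups[ord[seq_len(n)]]
  a <- sum(first_half == names(sizes)[1])
  100 * min(a, n - a) / n
}

#' Contralaterality Score of a bare leaf permutation
#'
#' The same statistic as [contralaterality_score()] computed directly
#' from a vector of group memberships in left-to-right order, bypassing
#' any tree.  Used for the analytic null cross-check: under a uniformly
#' random permutation of 2n leaves the count of group-1 leaves in the
#' first half is hypergeometric, giving E[CS] (about 40.5\% for n = 8).
#'
#' @param groups_in_order group ids of the 2n leaves, left to right.
#' @return CS as a percentage in \code{[0, 50]}.
#' @export
cs_of_order <- function(groups_in_order) {
  sizes <- table(groups_in_order)
  if (length(sizes) != 2L || sizes[1] != sizes[2])
    stop("CS requires two groups of equal size")
  n <- as.integer(sizes[1])
  a <- sum(groups_in_order[seq_len(n)] == names(sizes)[1])
  100 * min(a, n - a) / n
}

#' Null distribution of the Contralaterality Score
#'
#' Simulates the CS under the no-signal hypothesis: both groups are
#' pure uniform-random FASTQ (contamination 0), and each replicate runs
#' the full count / scale / Canberra / cluster pipeline before the CS is
#' read off the leaf order.  The empirical 5th percentile of the
#' returned sample is the one-sided p < 0.05 significance threshold.
#'
#' @param n_per_group files per group (default 8, the study-condition
#'   size whose permutation-null CS mean is about 40.5).
#' @param sim a [sim_config()]; its contamination fraction is forced
#'   to 0.
#' @param reps number of replicates (at least 100 for a stable 5th
#'   percentile).
#' @param seed master seed; the run is bit-reproducible given it.
#' @return Numeric vector of \code{reps} CS values.
#' @export
cs_null_distribution <- function(n_per_group = 8L, sim = sim_config(),
                                 reps = 200L, seed = 1L) {
  stopifnot(reps >= 1L)
  sim$n_files_per_group <- as.integer(n_per_group)
  sim$contamination_fraction <- 0
  sim$seed <- as.integer(seed)
  run_separation_experiment(sim, reps = reps)$cs_values
}

#' Semi-quantitative batch-effect class of a two-group tree
#'
#' Grades the separation of the two groups in the clustering tree on
#' the ordered scale \code{b1a > b1b > b2a > b2b > es}:
#' \describe{
#'   \item{b1a}{strong batch effect -- both children of the root are
#'     pure single-group subtrees (top-level separation).}
#'   \item{b1b}{the root split is pure except for exactly one misplaced
#'     leaf.}
#'   \item{b2a}{one of the four depth-2 subtrees is pure and contains
#'     an entire group.}
#'   \item{b2b}{one of the four depth-2 subtrees is pure and contains
#'     all but one member of a group.}
#'   \item{es}{no detectable batch effect (groups interleaved).}
#' }
#'
#' @param gt a [grouped_tree()]; at least 4 leaves.
#' @return A single character value, one of
#'   \code{c("b1a", "b1b", "b2a", "b2b", "es")}.
#' @export
classify_batch_effect <- function(gt) {
  stopifnot(inherits(gt, "grouped_tree"))
  hc <- gt$dendrogram
  labels <- hc$labels
  groups <- gt$group_of[labels]
  if (length(labels) < 4L)
    stop("batch classification needs at least 4 leaves")
  sets <- node_leaf_sets(hc)
  root <- nrow(hc$merge)
  child_set <- function(ref) if (ref < 0) -ref else sets[[ref]]
  left <- child_set(hc$merge[root, 1])
  right <- child_set(hc$merge[root, 2])
  gids <- unique(groups)
  ## misplaced leaves under the better of the two group->side assignments
  m1 <- sum(groups[left] != gids[1]) + sum(groups[right] != gids[2])
  m2 <- sum(groups[left] != gids[2]) + sum(groups[right] != gids[1])
  if (min(m1, m2) == 0L) return("b1a")
  if (min(m1, m2) == 1L) return("b1b")
  ## depth-2 subtrees: children of the root's children (a leaf child
  ## stands for itself)
  depth2 <- list()
  for (ref in hc$merge[root, ]) {
    if (ref < 0) {
      depth2 <- c(depth2, list(-ref))
    } else {
      depth2 <- c(depth2, list(child_set(hc$merge[ref, 1])),
                  list(child_set(hc$merge[ref, 2])))
    }
  }
  group_size <- table(groups)
  b2b_seen <- FALSE
  for (s in depth2) {
    gs <- groups[s]
    if (length(unique(gs)) != 1L) next
    full <- group_size[[gs[1]]]
    if (length(s) == full) return("b2a")
    if (length(s) == full - 1L) b2b_seen <- TRUE
  }
  if (b2b_seen) "b2b" else "es"
}

#' Size of the largest single-group subtree
#'
#' The maximum number of leaves over all subtrees (including single
#' leaves) whose leaves all belong to the given group -- the statistic
#' used to compare raw and mapped reads at flowcell level.
#'
#' @param gt a [grouped_tree()].
#' @param group a group id present in the tree.
#' @return Integer subtree size (at least 1).
#' @export
largest_pure_subtree <- function(gt, group) {
  stopifnot(inherits(gt, "grouped_tree"))
  groups <- gt$group_of[gt$dendrogram$labels]
  if (!group %in% groups)
    stop("unknown group: ", group)
  best <- 1L
  for (s in node_leaf_sets(gt$dendrogram)) {
    if (length(s) > best && all(groups[s] == group))
      best <- length(s)
  }
  best
}

#' Compare the k-mer spectra of two batches
#'
#' Scales both profiles to a common total, log10-transforms with a
#' pseudocount (nullomers would otherwise give \code{log10(0)}), and
#' reports per-motif log-differences plus summary statistics.  Because
#' both profiles are scaled first, the comparison is invariant to
#' sequencing depth.
#'
#' @param a,b [kmer_profile] objects with identical \code{k}.
#' @param target_total common total to scale to; default the larger
#'   \code{n_kmers_total}.
#' @param pseudocount added before \code{log10}; default 1 keeps integer
#'   counts interpretable.
#' @return An object of class \code{spectrum_comparison}: scaled counts,
#'   \code{log_a}, \code{log_b}, per-motif \code{diff = log_a - log_b},
#'   and summaries \code{mean_diff}, \code{sd_diff}, \code{mean_abs_diff},
#'   \code{sd_abs_diff}.
#' @export
spectrum_comparison <- function(a, b, target_total = NULL,
                                pseudocount = 1) {
  stopifnot(inherits(a, "kmer_profile"), inherits(b, "kmer_profile"))
  if (a$k != b$k)
    stop("profiles must share one k")
  stopifnot(pseudocount > 0)
  if (is.null(target_total))
    target_total <- max(a$n_kmers_total, b$n_kmers_total)
  scaled_a <- scale_profile(a, target_total)
  scaled_b <- scale_profile(b, target_total)
  log_a <- log10(scaled_a + pseudocount)
  log_b <- log10(scaled_b + pseudocount)
  diff <- log_a - log_b
  structure(list(k = a$k, labels = c(a$label, b$label),
                 target_total = target_total, pseudocount = pseudocount,
                 scaled_a = scaled_a, scaled_b = scaled_b,
                 log_a = log_a, log_b = log_b, diff = diff,
                 mean_diff = mean(diff), sd_diff = stats::sd(diff),
                 mean_abs_diff = mean(abs(diff)),
                 sd_abs_diff = stats::sd(abs(diff))),
            class = "spectrum_comparison")
}

#' @export
print.spectrum_comparison <- function(x, ...) {
  cat("spectrum_comparison (k=", x$k, "): ", x$labels[1], " vs ",
      x$labels[2], "\n  mean |log10 diff| = ",
      signif(x$mean_abs_diff, 3), ", sd(diff) = ", signif(x$sd_diff, 3),
      "\n", sep = "")
  invisible(x)
}

#' How many k-mers carry a given contamination-equivalent signal
#'
#' Sorts the motifs by the absolute difference of their scaled counts
#' (largest first) and accumulates those differences until they amount
#' to \code{fraction * total_reads} excess motif occurrences --- the
#' footprint that contaminating that fraction of reads with one motif
#' per read would leave.  The returned count says whether an observed
#' batch effect is driven by a few strongly shifted k-mers or by
#' widespread small differences.
#'
#' @param sc a [spectrum_comparison()].
#' @param total_reads reads per batch the fraction refers to.
#' @param fraction target contamination fraction in \code{(0, 1)}.
#' @return Integer: the number of motifs (in decreasing-difference
#'   order) needed to reach the target.  Errors if the total observed
#'   difference cannot reach it, stating the maximum attainable
#'   fraction.
#' @export
kmers_to_contamination_fraction <- function(sc, total_reads, fraction) {
  stopifnot(inherits(sc, "spectrum_comparison"),
            total_reads > 0, fraction > 0, fraction < 1)
  diffs <- sort(abs(sc$scaled_a - sc$scaled_b), decreasing = TRUE)
  target <- fraction * total_reads
  acc <- cumsum(diffs)
  if (acc[length(acc)] < target)
    stop("unreachable fraction: maximum attainable is ",
         signif(acc[length(acc)] / total_reads, 4))
  which(acc >= target)[1L]
}
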