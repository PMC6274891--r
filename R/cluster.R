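#' Canberra distance between scaled k-mer count vectors
#'
#' The Canberra distance is a weighted L1 metric,
#' \deqn{d(x, y) = \sum_i |x_i - y_i| / (|x_i| + |y_i|),}
#' summed over all \eqn{4^k} components, with the convention that a
#' \code{0/0} term contributes 0 (no term dropping, no renormalisation,
#' so the sum always runs over the full fixed dimension).  Each term
#' lies in \code{[0, 1]}, which makes the distance sensitive to
#' differences between small counts -- the property that lets rare
#' k-mers contribute to sample separation.
#'
#' @param x,y non-negative numeric vectors of equal length (scaled
#'   counts).
#' @return `canberra_distance()`: a single non-negative number in
#'   \code{[0, length(x)]}.  `canberra_term()`: the per-component term
#'   \code{|x - y| / (|x| + |y|)} (vectorised), in \code{[0, 1]}.
#' @examples
#' canberra_term(2, 1)                   # 1/3
#' canberra_distance(c(1, 0), c(0, 1))   # 2
#' @export
canberra_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors must have equal length")
  .Call(C_canberra, as.numeric(x), as.numeric(y))
}

#' @rdname canberra_distance
#' @export
canberra_term <- function(x, y) {
  num <- abs(x - y)
  den <- abs(x) + abs(y)
  ifelse(den > 0, num / den, 0)
}

#' Pairwise Canberra distances of a profile set
#'
#' Every profile is first scaled to a common k-mer total (by default the
#' maximum total in the set, so counts are scaled up rather than
#' shrunk), removing the systematic offset caused by different
#' sequencing depths; the Canberra distance is then computed for every
#' pair.
#'
#' @param ps a [profile_set()] with at least two non-empty profiles.
#' @param target_total common total to scale to; default
#'   \code{max(n_kmers_total)} over the set.
#' @return A [stats::dist] object labelled with the profile labels.
#' @export
distance_matrix <- function(ps, target_total = NULL) {
  stopifnot(inherits(ps, "profile_set"))
  n <- length(ps)
  if (n < 2L)
    stop("need at least two profiles")
  totals <- vapply(ps$profiles, `[[`, numeric(1), "n_kmers_total")
  if (any(totals <= 0))
    stop("all-zero profile(s): ",
         paste(ps$labels[totals <= 0], collapse = ", "))
  if (is.null(target_total)) target_total <- max(totals)
  scaled <- lapply(ps$profiles, scale_profile, target_total = target_total)
  d <- numeric(n * (n - 1L) / 2L)
  idx <- 1L
  for (j in seq_len(n - 1L)) {        # dist stores columns j < i
    for (i in (j + 1L):n) {
      d[idx] <- .Call(C_canberra, scaled[[i]], scaled[[j]])
      idx <- idx + 1L
    }
  }
  structure(d, Size = n, Labels = ps$labels, Diag = FALSE, Upper = FALSE,
            method = "canberra", class = "dist")
}

#' Hierarchical clustering of a sample distance matrix
#'
#' Standard agglomerative clustering via [stats::hclust()].  The result
#' is deterministic for a given distance matrix, and its left-to-right
#' leaf order (\code{order} element / [leaf_order()]) is the permutation
#' consumed by the batch diagnostics.
#'
#' @param dm a [stats::dist] object, e.g. from [distance_matrix()].
#' @param linkage agglomeration rule: \code{"complete"} (default),
#'   \code{"average"} or \code{"single"}.
#' @return An [stats::hclust] tree.
#' @export
hierarchical_cluster <- function(dm,
                                 linkage = c("complete", "average",
                                             "single")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(dm, "dist"))
  if (anyNA(dm) || any(!is.finite(dm)))
    stop("distance matrix contains NA/NaN/Inf")
  if (attr(dm, "Size") < 2L)
    stop("need at least two samples")
  stats::hclust(dm, method = linkage)
}

#' Left-to-right leaf labels of a dendrogram
#'
#' @param dg an [stats::hclust] tree with labels.
#' @return Character vector: the leaf labels in the order the tree is
#'   drawn (no crossing branches).
#' @export
leaf_order <- function(dg) {
  stopifnot(inherits(dg, "hclust"))
  if (is.null(dg$labels)) as.character(dg$order)
  else unname(dg$labels[dg$order])
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths follow the midpoint convention of
#' [ape::as.phylo.hclust()]: node depths are half the merge heights, so
#' two leaves merged at height 2 become \code{"(A:1,B:1);"}.  Labels
#' containing Newick metacharacters are single-quoted.
#'
#' @param dg an [stats::hclust] tree.
#' @param path optional file to write to.
#' @return The Newick string (invisibly if \code{path} is given).
#' @export
to_newick <- function(dg, path = NULL) {
  stopifnot(inherits(dg, "hclust"))
  phy <- ape::as.phylo(dg)
  ## write.tree rewrites metacharacters in labels; protect such labels
  ## with placeholders and splice the single-quoted originals back in
  meta <- grepl("[][():;,'[:space:]]", phy$tip.label)
  orig <- phy$tip.label[meta]
  holders <- sprintf(".kmbtip%d.", seq_along(orig))
  phy$tip.label[meta] <- holders
  txt <- ape::write.tree(phy)
  for (i in seq_along(orig))
    txt <- sub(holders[i],
               paste0("'", gsub("'", "''", orig[i]), "'"), txt,
               fixed = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    invisible(txt)
  } else txt
}
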