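# interval sets are feature data.frames (0-based half-open) or anything with
# start/end columns; all arithmetic goes through IRanges
as_iranges <- function(x) {
  if (inherits(x, "IRanges")) return(IRanges::reduce(x))
  if (NROW(x) == 0L) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(x$start + 1L, x$end))
}

#' Jaccard index of two genomic interval sets
#'
#' Intersection length over union length in bp, after merging each set.
#' Defined as 0 when both sets are empty.
#'
#' @param a,b interval sets: feature data.frames with `start`/`end`
#'   (0-based half-open) on one sequence.
#' @return dimensionless scalar in \[0, 1\].
#' @examples
#' a <- data.frame(start = 0, end = 100)
#' b <- data.frame(start = 50, end = 150)
#' jaccard(a, b)   # 50 / 150
#' @export
jaccard <- function(a, b) {
  ra <- as_iranges(a); rb <- as_iranges(b)
  inter <- sum(IRanges::width(IRanges::intersect(ra, rb)))
  uni <- sum(IRanges::width(IRanges::union(ra, rb)))
  if (uni == 0) 0 else inter / uni
}

#' Jaccard interval-permutation test
#'
#' Tests whether a query interval set overlaps (or avoids) a reference set
#' more than expected by chance. The null relocates each query interval to a
#' uniform, wrap-free position on the genome (length-preserving, independent
#' placements; overlaps among relocated intervals are allowed), recomputes
#' the Jaccard index, and reports a one-sided plus-one permutation p-value
#' in the observed direction: `overlap` if the observed J exceeds the null
#' median, `avoidance` otherwise.
#'
#' @param query,reference interval sets (feature data.frames, 0-based
#'   half-open; the reference stays fixed).
#' @param genome_length genome length in bp.
#' @param n_perm number of relocations (default 999).
#' @param seed integer seed.
#' @return object of class `JaccardTestResult`: list with `observed`,
#'   `null` (numeric vector), `p_value`, `direction`.
#' @export
jaccard_permutation_test <- function(query, reference, genome_length,
                                     n_perm = 999L, seed = NULL) {
  widths <- if (NROW(query)) query$end - query$start else integer()
  if (any(widths > genome_length))
    stop("query interval longer than the genome", call. = FALSE)
  obs <- jaccard(query, reference)
  if (NROW(query) == 0L) {
    res <- list(observed = 0, null = rep(0, n_perm), p_value = 1,
                direction = "overlap", n_perm = n_perm)
    class(res) <- "JaccardTestResult"
    return(res)
  }
  rref <- as_iranges(reference)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(r) {
    starts <- floor(runif(length(widths)) * (genome_length - widths + 1))
    rq <- IRanges::reduce(IRanges::IRanges(starts + 1L, starts + widths))
    inter <- sum(IRanges::width(IRanges::intersect(rq, rref)))
    uni <- sum(IRanges::width(IRanges::union(rq, rref)))
    if (uni == 0) 0 else inter / uni
  }, numeric(1)))
  direction <- if (obs > stats::median(null)) "overlap" else "avoidance"
  extreme <- if (direction == "overlap") sum(null >= obs) else sum(null <= obs)
  res <- list(observed = obs, null = null,
              p_value = (1 + extreme) / (1 + n_perm),
              direction = direction, n_perm = n_perm)
  class(res) <- "JaccardTestResult"
  res
}

#' @export
print.JaccardTestResult <- function(x, ...) {
  cat(sprintf("Jaccard permutation test: J = %.4f (null median %.4f)\n",
              x$observed, stats::median(x$null)))
  cat(sprintf("  direction: %s, P = %.4g (%d permutations)\n",
              x$direction, x$p_value, x$n_perm))
  invisible(x)
}

#' Hypergeometric enrichment of gene clusters against gene groups
#'
#' For every (cluster, group) pair, the upper cumulative hypergeometric
#' tail P\[X >= k\] with k the observed overlap, drawn from a universe of N
#' genes with K group members and n cluster members. Raw p-values are
#' reported (enrichment reading, no multiple-testing correction by default);
#' a Benjamini–Hochberg adjusted column can be requested.
#'
#' @param universe character vector of all gene ids.
#' @param clusters named character/factor vector or list mapping gene id to
#'   cluster label (subset of the universe).
#' @param groups mapping gene id to group label (subset of the universe).
#' @param bh also compute Benjamini–Hochberg adjusted p-values.
#' @return data.frame with columns `cluster`, `group`, `N`, `K`, `n`, `k`,
#'   `p_value` (and `p_bh` if requested).
#' @export
hypergeom_enrichment <- function(universe, clusters, groups, bh = FALSE) {
  cl <- as_label_map(clusters, "clusters")
  gr <- as_label_map(groups, "groups")
  off <- setdiff(c(names(cl), names(gr)), universe)
  if (length(off))
    stop("ids outside the universe: ",
         paste(utils::head(off, 5L), collapse = ", "), call. = FALSE)
  N <- length(unique(universe))
  out <- NULL
  for (c_lab in sort(unique(unname(cl)))) {
    c_ids <- names(cl)[cl == c_lab]
    for (g_lab in sort(unique(unname(gr)))) {
      g_ids <- names(gr)[gr == g_lab]
      k <- length(intersect(c_ids, g_ids))
      p <- stats::phyper(k - 1, length(g_ids), N - length(g_ids),
                         length(c_ids), lower.tail = FALSE)
      out <- rbind(out, data.frame(cluster = c_lab, group = g_lab, N = N,
                                   K = length(g_ids), n = length(c_ids),
                                   k = k, p_value = p,
                                   stringsAsFactors = FALSE))
    }
  }
  if (bh) out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}

as_label_map <- function(x, what) {
  if (is.list(x)) {
    # list of id vectors, names = labels
    lab <- rep(names(x), lengths(x))
    ids <- unlist(x, use.names = FALSE)
    x <- stats::setNames(lab, ids)
  }
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop(what, " must be a named vector (id -> label) or a named list",
         call. = FALSE)
  stats::setNames(as.character(x), names(x))
}

#' Hierarchical clustering of profile matrices
#'
#' Agglomerative clustering of matrix rows on Euclidean distances, cut into
#' `k_cut` clusters. `"ward"` uses Ward's minimum-variance criterion
#' (hclust's `ward.D2`, i.e. Ward on Euclidean distances); `"complete"`
#' uses complete linkage. Used for species-by-motif SNR matrices (Ward for
#' species, complete linkage for dinucleotides, cut at k = 4) and for
#' per-CDS spectra.
#'
#' @param mat numeric matrix, rows = entities to cluster; no missing values.
#' @param linkage `"ward"` or `"complete"`.
#' @param k_cut number of clusters.
#' @return named integer vector of cluster labels (names = rownames), with
#'   the `hclust` tree as attribute `"tree"`.
#' @export
cluster_profiles <- function(mat, linkage = c("ward", "complete"), k_cut) {
  linkage <- match.arg(linkage)
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("matrix contains missing values", call. = FALSE)
  if (k_cut > nrow(mat))
    stop("k_cut exceeds the number of rows", call. = FALSE)
  method <- if (linkage == "ward") "ward.D2" else "complete"
  tree <- stats::hclust(stats::dist(mat, method = "euclidean"), method = method)
  labels <- stats::cutree(tree, k = k_cut)
  if (!is.null(rownames(mat))) names(labels) <- rownames(mat)
  attr(labels, "tree") <- tree
  labels
}
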