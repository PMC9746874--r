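#' Randomly split cells into two balanced pseudo-groups
#'
#' Under the null of a random split of exchangeable cells, the two groups
#' share every gene's expression distribution; this is the first step of
#' the semi-simulation benchmark.
#'
#' @param counts Genes x cells count matrix with cell colnames.
#' @param seed RNG seed; the split is deterministic given the seed.
#' @return Named integer vector of group labels (1/2) over the cells;
#'   group sizes differ by at most one.
#' @export
split_cells <- function(counts, seed = NULL) {
  cells <- colnames(counts)
  n <- length(cells)
  if (n < 2) stop("need at least 2 cells to split")
  if (!is.null(seed)) set.seed(seed)
  n1 <- ceiling(n / 2)
  g <- rep(2L, n)
  g[sample.int(n, n1)] <- 1L
  names(g) <- cells
  g
}

#' Select mean-matched gene pairs for swapping
#'
#' Genes are ranked by their group-2 mean count (over all group-2 cells,
#' zeros included). The "low" set is the first `k` genes with mean strictly
#' above the anchor `s1`; the "high" set is the first `k` genes with mean
#' strictly above `s2 = fc * s1` that are not already in the low set.
#' Pairs are matched by rank order, so the i-th low gene exchanges with the
#' i-th high gene and the construction is deterministic.
#'
#' @param group2_means Named numeric vector of per-gene mean counts in
#'   group 2.
#' @param s1 Lower mean-count anchor (> 0).
#' @param fc Fold-change-like strength (> 1); sets `s2 = fc * s1`.
#' @param k Number of genes per set.
#' @return A data frame with columns `low_gene`, `high_gene` (k rows) and
#'   attributes `s1` and `s2`.
#' @export
select_swap_genes <- function(group2_means, s1, fc, k) {
  stopifnot(fc > 1, k >= 1, s1 > 0)
  if (is.null(names(group2_means))) stop("group2_means must be named by gene")
  ord <- order(group2_means, names(group2_means))
  mu <- group2_means[ord]
  s2 <- fc * s1
  low_pool <- names(mu)[mu > s1]
  if (length(low_pool) < k)
    stop("only ", length(low_pool), " genes have mean above s1 = ", s1,
         "; choose a smaller s1 or k")
  low <- low_pool[seq_len(k)]
  high_pool <- setdiff(names(mu)[mu > s2], low)
  if (length(high_pool) < k)
    stop("only ", length(high_pool), " genes have mean above s2 = ", s2,
         " outside the low set; choose a smaller s1 or k")
  high <- high_pool[seq_len(k)]
  structure(
    data.frame(low_gene = low, high_gene = high, stringsAsFactors = FALSE),
    s1 = s1, s2 = s2
  )
}

#' Build a semi-simulated DE benchmark by swapping gene pairs
#'
#' Splits the source cells into two random balanced groups, then creates
#' known DE genes by exchanging the group-2 expression vectors of `k`
#' mean-matched gene pairs: a "low" set anchored just above `s1` and a
#' "high" set anchored just above `s2 = fc * s1` (see
#' [select_swap_genes()]). Group-1 columns are left untouched, so each
#' swapped gene's fold change between the groups is governed by `fc` while
#' all unswapped genes remain exact nulls.
#'
#' @param counts Source genes x cells count matrix (real data or
#'   [simulate_pbmc_like_source()] output).
#' @param fc DE strength (> 1); the paper's levels are 1.5 (weak), 2
#'   (moderate) and 2.5 (strong).
#' @param k Genes per selection set (default 200, giving `2k` true DE
#'   genes).
#' @param s1 Lower anchor, or `"auto"` (default): the median of the
#'   positive group-2 gene means.
#' @param seed RNG seed controlling the cell split.
#' @param null_mode If `TRUE`, skip swapping: the result is an exact null
#'   with an empty truth set.
#' @return An object of class `semisim_dataset`: list with `counts`,
#'   `groups`, `truth_de`, `pairs`, `s1_used`, `s2_used`, `fc`.
#' @examples
#' src <- simulate_pbmc_like_source(500, 200, sparsity_target = 0.85,
#'                                  seed = 1)
#' ds <- make_semisim(src, fc = 2.5, k = 20, seed = 1)
#' length(ds$truth_de)
#' @export
make_semisim <- function(counts, fc = 2.5, k = 200, s1 = "auto", seed = NULL,
                         null_mode = FALSE) {
  counts <- as_count_matrix(counts)
  groups <- split_cells(counts, seed = seed)

  if (null_mode) {
    return(structure(
      list(counts = counts, groups = groups, truth_de = character(0),
           pairs = NULL, s1_used = NA_real_, s2_used = NA_real_, fc = fc),
      class = "semisim_dataset"
    ))
  }
  stopifnot(fc > 1, k >= 1)
  g2 <- names(groups)[groups == 2L]
  mu2 <- Matrix::rowSums(counts[, g2, drop = FALSE]) / length(g2)
  if (identical(s1, "auto")) {
    s1 <- median(mu2[mu2 > 0])
  } else {
    s1 <- as.numeric(s1)
    if (!is.finite(s1) || s1 <= 0) stop("s1 must be positive or \"auto\"")
  }
  pairs <- select_swap_genes(mu2, s1 = s1, fc = fc, k = k)

  # exchange the paired rows inside group 2 via a row permutation of the
  # group-2 submatrix (orders of magnitude faster than sparse subassignment)
  perm <- seq_len(nrow(counts))
  ilow <- match(pairs$low_gene, rownames(counts))
  ihigh <- match(pairs$high_gene, rownames(counts))
  perm[ilow] <- ihigh
  perm[ihigh] <- ilow
  g1 <- names(groups)[groups == 1L]
  c2 <- counts[perm, g2, drop = FALSE]
  rownames(c2) <- rownames(counts)
  swapped <- methods::cbind2(counts[, g1, drop = FALSE], c2)
  swapped <- swapped[, colnames(counts), drop = FALSE]

  structure(
    list(counts = swapped, groups = groups,
         truth_de = c(pairs$low_gene, pairs$high_gene),
         pairs = pairs,
         s1_used = s1, s2_used = attr(pairs, "s2"), fc = fc),
    class = "semisim_dataset"
  )
}
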