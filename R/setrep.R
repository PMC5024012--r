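#' Exact hypergeometric over/under-representation p-value
#'
#' For a cell of size `n` drawn from a population of `N` genes of which
#' `K` belong to the gene set, with `k` set members observed in the cell:
#' the over-representation p-value is `P(X >= k)` and the
#' under-representation p-value `P(X <= k)` under
#' `X ~ Hypergeometric(N, K, n)`, computed exactly.
#'
#' @param k Observed successes in the cell.
#' @param n Cell size.
#' @param K Successes in the population.
#' @param N Population size.
#' @param alternative `"over"` or `"under"`.
#' @return Exact tail probability.
#' @export
hypergeometric_test <- function(k, n, K, N,
                                alternative = c("over", "under")) {
  alternative <- match.arg(alternative)
  if (k < 0 || n < 0 || K < 0 || N < 1 ||
      k > min(n, K) || n > N || K > N)
    stop("invalid contingency cell: need 0 <= k <= min(n, K), n <= N, ",
         "K <= N")
  if (alternative == "over")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  else
    stats::phyper(k, K, N - K, n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `adjusted_i` is the minimum over ranks `j >=
#' rank(i)` of `m * p_(j) / j`, capped at 1, returned in input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Partition genes into four expression-level classes
#'
#' Genes are ranked by mean expression and split into four classes
#' delimited by the quartiles (low, low-to-moderate, moderate-to-high,
#' high). Class sizes differ by at most one; when the gene count is not a
#' multiple of four the remainder is allocated to the lowest classes
#' first, so e.g. 4805 genes give sizes 1202, 1201, 1201, 1201. Ties in
#' the means are broken by stable gene-id order.
#'
#' @param means Named numeric vector of per-gene mean expression (>= 4
#'   genes).
#' @return Data frame `gene_id`, `class` (ordered factor `low`,
#'   `low_moderate`, `moderate_high`, `high`), plus attribute
#'   `boundaries` with the three quartile values.
#' @export
quartile_classes <- function(means) {
  if (length(means) < 4L) stop("need at least 4 genes")
  if (is.null(names(means))) stop("'means' must be named by gene id")
  ord <- order(means, names(means))
  n <- length(means)
  sizes <- rep(n %/% 4L, 4L)
  rem <- n %% 4L
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  lev <- c("low", "low_moderate", "moderate_high", "high")
  cls <- rep(lev, sizes)
  out <- data.frame(gene_id = names(means)[ord],
                    class = factor(cls, levels = lev),
                    stringsAsFactors = FALSE)
  out <- out[match(names(means), out$gene_id), ]
  rownames(out) <- NULL
  cuts <- cumsum(sizes)[1:3]
  attr(out, "boundaries") <- stats::setNames(
    means[ord][cuts], c("Q1", "Q2", "Q3"))
  out
}

#' Gene-set representation analysis across a partition
#'
#' For each (gene set, partition cell) pair, computes the exact
#' hypergeometric over- and under-representation p-values of the observed
#' overlap against the population of all partitioned genes, applies
#' Benjamini-Hochberg correction within the declared family, and calls
#' each cell `over` (observed above expectation with significant over-p),
#' `under`, or `ns`.
#'
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#'   Members outside the partition population are dropped; a set fully
#'   disjoint from the population is an error.
#' @param partition Named character vector mapping gene id to cell label,
#'   e.g. from [group_membership()] or [quartile_classes()].
#' @param alpha Adjusted-p threshold for calls (default 0.05).
#' @param family BH family: `"per_set"` (default; across cells and both
#'   tails of one set), `"per_cell"` (across sets and tails within a
#'   cell -- the by-column mode used for expression-class tables), or
#'   `"global"`.
#' @return Data frame with `set_id`, `cell_id`, `k`, `n`, `K`, `N`,
#'   `expected`, `p_over`, `p_under`, `p_over_adjusted`,
#'   `p_under_adjusted`, `call`.
#' @export
representation_analysis <- function(sets, partition, alpha = 0.05,
                                    family = c("per_set", "per_cell",
                                               "global")) {
  family <- match.arg(family)
  if (is.null(names(partition))) stop("'partition' must be named")
  pop <- names(partition)
  N <- length(pop)
  cells <- sort(unique(as.character(partition)))
  rows <- list()
  for (s in names(sets)) {
    members <- intersect(sets[[s]], pop)
    if (!length(members))
      stop("gene set '", s, "' is disjoint from the partition population")
    K <- length(members)
    for (cell in cells) {
      cell_genes <- pop[partition == cell]
      n <- length(cell_genes)
      k <- length(intersect(members, cell_genes))
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = s, cell_id = cell, k = k, n = n, K = K, N = N,
        expected = K * n / N,
        p_over = hypergeometric_test(k, n, K, N, "over"),
        p_under = hypergeometric_test(k, n, K, N, "under"),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  fam <- switch(family,
                per_set = res$set_id,
                per_cell = res$cell_id,
                global = rep("all", nrow(res)))
  res$p_over_adjusted <- res$p_under_adjusted <- NA_real_
  for (f in unique(fam)) {
    idx <- fam == f
    adj <- bh_adjust(c(res$p_over[idx], res$p_under[idx]))
    res$p_over_adjusted[idx] <- adj[seq_len(sum(idx))]
    res$p_under_adjusted[idx] <- adj[-seq_len(sum(idx))]
  }
  res$call <- "ns"
  res$call[res$k > res$expected &
             res$p_over_adjusted < alpha] <- "over"
  res$call[res$k < res$expected &
             res$p_under_adjusted < alpha] <- "under"
  res
}
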