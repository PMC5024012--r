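#' P-value of a Pearson correlation
#'
#' Two-sided test of zero correlation via
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on n - 2 degrees of freedom.
#' `|r| = 1` is returned as the smallest representable positive double.
#'
#' @param r Correlation coefficient in `[-1, 1]`.
#' @param n Number of paired observations (>= 4).
#' @return P-value in (0, 1].
#' @export
correlation_pvalue <- function(r, n) {
  if (n < 4L) stop("'n' must be >= 4")
  if (abs(r) > 1) stop("|r| must be <= 1")
  if (abs(r) == 1) return(.Machine$double.xmin)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Assign genes to coexpression groups by template matching
#'
#' Each candidate gene is correlated with every group template (the
#' per-sample mean profile of the group); the best template is the one
#' with maximal correlation (ties broken towards the larger group, then
#' lexicographic label). Best-candidate p-values are Benjamini-Hochberg
#' adjusted in one family across all candidate genes, and a gene is
#' assigned iff its adjusted p is below `alpha` and its correlation is
#' positive (groups are defined by positively correlated profiles).
#'
#' @param x A [coex_experiment] or matrix holding the candidate genes on
#'   the same sample basis as the templates.
#' @param genes Candidate gene ids (e.g. low-confidence variable genes).
#' @param templates Named list of per-sample template vectors, e.g. from
#'   [group_templates()]; names are group labels.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Data frame with `gene_id`, `best_group`, `r`, `p`,
#'   `p_adjusted`, `status` (`assigned`/`unassigned`).
#' @export
template_match <- function(x, genes, templates, alpha = 0.05) {
  m <- .values(x)[genes, , drop = FALSE]
  if (!length(templates)) stop("no templates supplied")
  labs <- names(templates)
  if (is.null(labs) || anyDuplicated(labs))
    stop("templates must carry unique names")
  tm <- do.call(cbind, templates)
  if (nrow(tm) != ncol(m))
    stop("templates are not on the same sample basis as the genes")
  group_sizes <- attr(templates, "group_sizes")
  if (is.null(group_sizes)) group_sizes <- stats::setNames(
    rep(0L, length(labs)), labs)

  best_group <- character(length(genes))
  best_r <- best_p <- rep(NA_real_, length(genes))
  status <- rep("unassigned", length(genes))
  for (i in seq_along(genes)) {
    g <- m[i, ]
    ok <- !is.na(g) & rowSums(is.na(tm)) == 0L
    if (sum(ok) < 4L) {
      best_group[i] <- NA_character_
      next
    }
    r <- suppressWarnings(as.vector(stats::cor(g[ok], tm[ok, ,
                                                         drop = FALSE])))
    r[is.na(r)] <- 0
    top <- which(r == max(r))
    if (length(top) > 1L) {
      top <- top[order(-group_sizes[labs[top]], labs[top])]
      top <- top[1L]
    }
    best_group[i] <- labs[top]
    best_r[i] <- r[top]
    best_p[i] <- correlation_pvalue(r[top], sum(ok))
  }
  adj <- rep(NA_real_, length(genes))
  tested <- !is.na(best_p)
  adj[tested] <- bh_adjust(best_p[tested])
  status[tested & adj < alpha & best_r > 0] <- "assigned"
  data.frame(gene_id = genes, best_group = best_group, r = best_r,
             p = best_p, p_adjusted = adj, status = status,
             stringsAsFactors = FALSE)
}
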