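#' Build an unweighted signed correlation-threshold network
#'
#' Connects two genes whenever the absolute Pearson correlation of their
#' expression profiles strictly exceeds `threshold` (default 0.9); each
#' edge carries the sign of the correlation. Zero-variance genes are kept
#' as isolated nodes with a message.
#'
#' @param x A [coex_experiment] or matrix (use the technical-replicate-
#'   averaged matrix for network construction).
#' @param genes Node set; must all be present in the matrix.
#' @param threshold Absolute-correlation cutoff in (0, 1).
#' @return An object of class `coexpression_network`: list with `nodes`,
#'   `edges` (data.frame `gene_a`, `gene_b`, `sign`, `r`; pairs stored
#'   with `gene_a < gene_b`) and `threshold`.
#' @export
build_network <- function(x, genes, threshold = 0.9) {
  m <- .values(x)
  missing_genes <- setdiff(genes, rownames(m))
  if (length(missing_genes))
    stop("gene(s) not in matrix: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  if (threshold <= 0 || threshold >= 1)
    stop("'threshold' must be in (0, 1)")
  m <- m[genes, , drop = FALSE]
  if (ncol(m) < 4L) stop("need at least 4 samples per correlation")
  v <- apply(m, 1L, stats::var, na.rm = TRUE)
  if (any(v == 0))
    message("zero-variance gene(s) kept as isolated nodes: ",
            paste(utils::head(genes[v == 0], 5), collapse = ", "))
  r <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  hit <- which(abs(r) > threshold & upper.tri(r), arr.ind = TRUE)
  edges <- data.frame(
    gene_a = genes[hit[, 1L]], gene_b = genes[hit[, 2L]],
    sign = ifelse(r[hit] > 0, "+", "-"), r = r[hit],
    stringsAsFactors = FALSE)
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = genes, edges = edges, threshold = threshold),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("coexpression_network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges (|r| >", x$threshold, ")\n")
  invisible(x)
}

#' Node degrees with tie-aware ranks
#'
#' Degree is the number of incident edges (both signs counted). Ranks are
#' 1-based; genes with equal degree share the minimum rank and the
#' following ranks are skipped accordingly (so degrees 53, 43, 40, 40, 39
#' rank 1, 2, 3, 3, 5).
#'
#' @param network A `coexpression_network`.
#' @return Data frame `gene_id`, `degree`, `rank`, sorted by decreasing
#'   degree (ties by gene id).
#' @export
degree_rank <- function(network) {
  nodes <- network$nodes
  if (!length(nodes))
    return(data.frame(gene_id = character(0), degree = integer(0),
                      rank = integer(0)))
  deg <- table(factor(c(network$edges$gene_a, network$edges$gene_b),
                      levels = nodes))
  deg <- as.integer(deg)
  rk <- rank(-deg, ties.method = "min")
  ord <- order(-deg, nodes)
  data.frame(gene_id = nodes[ord], degree = deg[ord],
             rank = as.integer(rk[ord]), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Intersect two signed networks
#'
#' The intersection keeps edges present in both networks with the same
#' sign; shared pairs with conflicting signs are dropped with a message.
#' Nodes are those incident to at least one shared edge.
#'
#' @param netA,netB `coexpression_network` objects (same threshold
#'   semantics).
#' @return A `coexpression_network`; `r` of a shared edge is taken from
#'   `netA`.
#' @export
intersect_networks <- function(netA, netB) {
  key <- function(e) paste(e$gene_a, e$gene_b, sep = "\r")
  ka <- key(netA$edges)
  kb <- key(netB$edges)
  shared <- intersect(ka, kb)
  ia <- match(shared, ka)
  ib <- match(shared, kb)
  same <- netA$edges$sign[ia] == netB$edges$sign[ib]
  if (any(!same))
    message("dropping ", sum(!same), " shared pair(s) with conflicting ",
            "edge signs")
  edges <- netA$edges[ia[same], , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  structure(list(nodes = nodes, edges = edges,
                 threshold = netA$threshold),
            class = "coexpression_network")
}

#' Signed neighborhood of a gene
#'
#' Partitions the neighbors of a gene by the sign of the connecting edge;
#' the two sets feed neighborhood representation analysis.
#'
#' @param network A `coexpression_network`.
#' @param gene Gene id present in the network.
#' @return List with `positive` and `negative` gene-id vectors.
#' @export
signed_neighbors <- function(network, gene) {
  if (!gene %in% network$nodes)
    stop("gene '", gene, "' is not in the network")
  e <- network$edges
  inc <- e$gene_a == gene | e$gene_b == gene
  other <- ifelse(e$gene_a[inc] == gene, e$gene_b[inc], e$gene_a[inc])
  list(positive = sort(other[e$sign[inc] == "+"]),
       negative = sort(other[e$sign[inc] == "-"]))
}

#' Scale-free topology fit
#'
#' Bins the positive node degrees on a log10 scale, regresses log10
#' frequency on log10 mean degree per bin, and reports the slope and R^2
#' of the fit -- the usual check that a coexpression network's degree
#' distribution approximates a power law.
#'
#' @param network A `coexpression_network` (or an integer vector of
#'   degrees).
#' @param n_bins Number of logarithmic bins (default 10).
#' @return List with `bins` (data.frame `degree`, `frequency`), `slope`
#'   and `r_squared`.
#' @export
scale_free_fit <- function(network, n_bins = 10) {
  deg <- if (inherits(network, "coexpression_network"))
    degree_rank(network)$degree else as.integer(network)
  deg <- deg[deg > 0]
  if (length(unique(deg)) < 3L)
    stop("scale-free fit needs at least 3 distinct positive degrees")
  breaks <- 10^seq(log10(min(deg)), log10(max(deg)),
                   length.out = n_bins + 1L)
  breaks[1L] <- breaks[1L] * (1 - 1e-9)
  bin <- cut(deg, breaks, include.lowest = TRUE)
  kmean <- tapply(deg, bin, mean)
  freq <- tapply(deg, bin, length) / length(deg)
  keep <- !is.na(kmean) & freq > 0
  xs <- log10(kmean[keep])
  ys <- log10(freq[keep])
  if (sum(keep) < 3L) stop("too few occupied bins for a fit")
  fit <- stats::lm(ys ~ xs)
  list(bins = data.frame(degree = unname(kmean[keep]),
                         frequency = unname(freq[keep])),
       slope = unname(stats::coef(fit)[2L]),
       r_squared = summary(fit)$r.squared)
}

#' Write a network edge list to TSV
#'
#' @param network A `coexpression_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
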