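#' Gene-gene Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlations between gene expression
#' profiles.
#'
#' @param x A [coex_experiment] or genes x samples matrix.
#' @param genes Optional character vector restricting the genes.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x, genes = NULL) {
  m <- .values(x)
  if (!is.null(genes)) {
    missing_genes <- setdiff(genes, rownames(m))
    if (length(missing_genes))
      stop("gene(s) not in matrix: ",
           paste(utils::head(missing_genes, 5), collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  if (ncol(m) < 3L) stop("correlations need at least 3 samples")
  v <- apply(m, 1L, stats::var, na.rm = TRUE)
  if (any(v == 0 | is.na(v)))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(m)[v == 0 | is.na(v)], 5),
               collapse = ", "))
  r <- stats::cor(t(m), use = "pairwise.complete.obs")
  diag(r) <- 1
  r
}

#' Soft-thresholded adjacency
#'
#' Unsigned weighted adjacency `a_ij = |r_ij|^beta` with zero diagonal.
#' The unsigned form lets anticorrelated genes share a module, which is
#' what produces the two coexpression groups per module downstream.
#'
#' @param corr Correlation matrix from [correlation_matrix()].
#' @param beta Soft-thresholding power (>= 1); 14 and 18 are the reference
#'   choices for the tissue and seasonal experiments respectively.
#' @param signed If `TRUE`, use the signed transform
#'   `((1 + r)/2)^beta` instead (off by default).
#' @return Adjacency matrix with entries in `[0, 1]` and zero diagonal.
#' @export
soft_threshold_adjacency <- function(corr, beta, signed = FALSE) {
  if (beta < 1) stop("'beta' must be >= 1")
  if (!isSymmetric(unname(corr)) || any(abs(corr) > 1 + 1e-8))
    stop("'corr' is not a valid correlation matrix")
  a <- if (signed) ((1 + corr) / 2)^beta else abs(corr)^beta
  a[a > 1] <- 1
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k` the adjacency row sums and `TOM_ii = 1`; the dissimilarity used for
#' module clustering is `1 - TOM`.
#'
#' @param adjacency Symmetric adjacency with zero diagonal, entries in
#'   `[0, 1]`.
#' @return Symmetric TOM similarity matrix with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency)))
    stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  if (any(adjacency < 0 | adjacency > 1))
    stop("adjacency entries must be in [0, 1]")
  k <- rowSums(adjacency)
  shared <- adjacency %*% adjacency
  denom <- outer(k, k, pmin) + 1 - adjacency
  tom <- (shared + adjacency) / denom
  diag(tom) <- 1
  # numerical guard: theory bounds TOM in [0, 1]
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  (tom + t(tom)) / 2
}

#' Module eigengene
#'
#' First principal component of the gene-standardised member submatrix:
#' a one-vector-per-sample summary of the module's expression profile.
#' The sign is oriented so that the majority of member genes correlate
#' positively with it (ties broken by making the lexicographically first
#' member positive).
#'
#' @param x A [coex_experiment] or matrix.
#' @param members Character vector of member gene ids (>= 2).
#' @return List with `eigengene` (named per-sample vector, unit norm) and
#'   `var_explained` (fraction of variance carried by the first
#'   component).
#' @export
module_eigengene <- function(x, members) {
  m <- .values(x)[members, , drop = FALSE]
  if (nrow(m) < 2L) stop("a module needs at least 2 members")
  if (ncol(m) < 3L) stop("need at least 3 samples")
  if (anyNA(m)) {
    mu <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 1L]]
  }
  s <- t(scale(t(m)))
  if (anyNA(s)) stop("zero-variance member(s): ",
                     paste(members[apply(m, 1, stats::sd) == 0],
                           collapse = ", "))
  sv <- svd(s)
  if (sv$d[1L] == 0) stop("degenerate (rank-0) module submatrix")
  e <- sv$v[, 1L]
  names(e) <- colnames(m)
  memcor <- as.vector(s %*% e)
  pos <- sum(memcor > 0)
  neg <- sum(memcor < 0)
  flip <- if (pos != neg) neg > pos else {
    first <- members[order(members)][1L]
    memcor[match(first, rownames(s))] < 0
  }
  if (flip) e <- -e
  list(eigengene = e, var_explained = sv$d[1L]^2 / sum(sv$d^2))
}

#' Split a module into its two anticorrelated groups
#'
#' Assigns each member gene to group `a` if its Pearson correlation with
#' the module eigengene is `>= 0` and to group `b` otherwise, and computes
#' the per-sample mean profile (template) of each group. An empty group is
#' allowed (single-profile module) and reported with a message.
#'
#' @param x A [coex_experiment] or matrix containing the members.
#' @param members Character vector of member gene ids.
#' @param eigengene Per-sample eigengene vector (from
#'   [module_eigengene()]); computed if `NULL`.
#' @return List with `group_a`, `group_b` (gene id vectors),
#'   `template_a`, `template_b` (per-sample means; `NULL` if the group is
#'   empty) and `eigengene_cor` (named per-member correlations).
#' @export
split_module <- function(x, members, eigengene = NULL) {
  m <- .values(x)[members, , drop = FALSE]
  if (is.null(eigengene))
    eigengene <- module_eigengene(x, members)$eigengene
  r <- apply(m, 1L, function(g)
    stats::cor(g, eigengene, use = "pairwise.complete.obs"))
  ga <- members[r >= 0]
  gb <- members[r < 0]
  if (!length(gb))
    message("module has a single expression profile (group b empty)")
  tmpl <- function(g) if (length(g))
    colMeans(m[g, , drop = FALSE], na.rm = TRUE) else NULL
  list(group_a = ga, group_b = gb,
       template_a = tmpl(ga), template_b = tmpl(gb),
       eigengene_cor = r)
}

#' Detect expression modules
#'
#' The module-detection chain: soft-thresholded unsigned adjacency from
#' the gene correlation matrix, topological overlap, average-linkage
#' hierarchical clustering on `1 - TOM`, and a static cut at
#' `cut_height`. Clusters smaller than `min_module_size` are pooled into
#' an unassigned bin. Modules are labelled `M1, M2, ...` (or another
#' `prefix`) by decreasing size and each is split into its two
#' anticorrelated coexpression groups (`a`/`b`) with mean-profile
#' templates.
#'
#' @param x A [coex_experiment]; correlations and templates are computed
#'   on these samples (average technical replicates first where relevant).
#' @param genes Genes to cluster (e.g. high-confidence variable genes);
#'   at least `2 * min_module_size`.
#' @param beta Soft-thresholding power.
#' @param cut_height Static cut height on the `1 - TOM` dendrogram,
#'   in (0, 1].
#' @param min_module_size Minimum genes per module.
#' @param prefix Module label prefix (`"M"` for tissue modules, `"T"` for
#'   temporal clusters).
#' @return An object of class `module_set`: list with `modules` (each
#'   with `module_id`, `members`, `eigengene`, `var_explained`, groups and
#'   templates), `membership` (data.frame gene/module/group/
#'   eigengene_cor) and `unassigned` (gene ids).
#' @export
detect_modules <- function(x, genes, beta = 14, cut_height = 0.5,
                           min_module_size = 30, prefix = "M") {
  if (min_module_size < 3L) stop("'min_module_size' must be >= 3")
  if (cut_height <= 0 || cut_height > 1)
    stop("'cut_height' must be in (0, 1]")
  if (length(genes) < 2L * min_module_size)
    stop("need at least 2 * min_module_size genes")
  corr <- correlation_matrix(x, genes)
  adj <- soft_threshold_adjacency(corr, beta)
  tom <- topological_overlap(adj)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  if (length(keep) == 1L && length(sizes) == 1L)
    warning("all genes fall in a single module at this cut height")
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  unassigned <- genes[!(cl %in% as.integer(keep))]
  modules <- lapply(seq_along(keep), function(j) {
    members <- genes[cl == as.integer(keep[j])]
    eig <- module_eigengene(x, members)
    sp <- split_module(x, members, eig$eigengene)
    list(module_id = paste0(prefix, j), members = members,
         eigengene = eig$eigengene, var_explained = eig$var_explained,
         group_a = sp$group_a, group_b = sp$group_b,
         template_a = sp$template_a, template_b = sp$template_b,
         eigengene_cor = sp$eigengene_cor)
  })
  membership <- do.call(rbind, lapply(modules, function(mod)
    data.frame(gene_id = c(mod$group_a, mod$group_b),
               module = mod$module_id,
               group = rep(c("a", "b"),
                           c(length(mod$group_a), length(mod$group_b))),
               eigengene_cor =
                 mod$eigengene_cor[c(mod$group_a, mod$group_b)],
               stringsAsFactors = FALSE)))
  if (length(unassigned))
    membership <- rbind(membership,
                        data.frame(gene_id = unassigned,
                                   module = "unassigned", group = NA,
                                   eigengene_cor = NA,
                                   stringsAsFactors = FALSE))
  rownames(membership) <- NULL
  structure(list(modules = modules, membership = membership,
                 unassigned = unassigned,
                 params = list(beta = beta, cut_height = cut_height,
                               min_module_size = min_module_size)),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("module_set:", length(x$modules), "modules,",
      length(x$unassigned), "unassigned genes\n")
  for (mod in x$modules)
    cat(sprintf("  %s: %d genes (a: %d, b: %d), var explained %.2f\n",
                mod$module_id, length(mod$members), length(mod$group_a),
                length(mod$group_b), mod$var_explained))
  invisible(x)
}

#' Extract group templates from a module set
#'
#' @param mset A `module_set` from [detect_modules()].
#' @return Named list of per-sample template vectors, one per non-empty
#'   group (`M1a`, `M1b`, ...).
#' @export
group_templates <- function(mset) {
  out <- list()
  sizes <- integer(0)
  for (mod in mset$modules) {
    if (length(mod$group_a)) {
      out[[paste0(mod$module_id, "a")]] <- mod$template_a
      sizes[paste0(mod$module_id, "a")] <- length(mod$group_a)
    }
    if (length(mod$group_b)) {
      out[[paste0(mod$module_id, "b")]] <- mod$template_b
      sizes[paste0(mod$module_id, "b")] <- length(mod$group_b)
    }
  }
  attr(out, "group_sizes") <- sizes
  out
}

#' Group membership as a gene -> group partition
#'
#' @param mset A `module_set`.
#' @return Named character vector mapping gene id to group label
#'   (`M1a` ...), omitting unassigned genes.
#' @export
group_membership <- function(mset) {
  mm <- mset$membership[mset$membership$module != "unassigned", ]
  stats::setNames(paste0(mm$module, mm$group), mm$gene_id)
}

#' Correlation between coexpression groups and tissues
#'
#' For every non-empty group, the group eigengene (the module eigengene
#' for group `a`, its negation for group `b`) is correlated with the 0/1
#' indicator of each tissue. A tissue-tissue correlation matrix is also
#' computed from the groups x tissues matrix of per-tissue mean eigengene
#' values.
#'
#' @param mset A `module_set` from [detect_modules()].
#' @param meta Sample metadata with a `tissue` column aligned to the
#'   eigengene samples (any grouping column may be named via `field`).
#' @param field Metadata column to correlate against (default
#'   `"tissue"`).
#' @return List with `group_tissue` (data.frame `group`, `tissue`, `R`)
#'   and `tissue_tissue` (correlation matrix across tissues).
#' @export
group_tissue_correlation <- function(mset, meta, field = "tissue") {
  if (is.null(meta[[field]])) stop("metadata lacks a '", field, "' field")
  tis <- factor(meta[[field]])
  if (nlevels(tis) < 2L) stop("at least 2 ", field, " levels required")
  eig <- list()
  for (mod in mset$modules) {
    if (length(mod$group_a))
      eig[[paste0(mod$module_id, "a")]] <- mod$eigengene
    if (length(mod$group_b))
      eig[[paste0(mod$module_id, "b")]] <- -mod$eigengene
  }
  rows <- list()
  for (g in names(eig)) for (tl in levels(tis))
    rows[[length(rows) + 1L]] <-
      data.frame(group = g, tissue = tl,
                 R = stats::cor(eig[[g]], as.numeric(tis == tl)),
                 stringsAsFactors = FALSE)
  gt <- do.call(rbind, rows)
  per_tissue <- vapply(levels(tis), function(tl)
    vapply(eig, function(e) mean(e[tis == tl]), 0),
    numeric(length(eig)))
  tt <- stats::cor(per_tissue)
  list(group_tissue = gt, tissue_tissue = tt)
}
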