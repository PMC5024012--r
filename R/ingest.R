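#' Read an expression matrix from TSV
#'
#' The expected layout is a header row of sample ids, one row per gene with
#' the gene id in the first column and log2 intensities in the remaining
#' columns. Blank cells are read as missing.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix with gene ids as row names and sample ids as
#'   column names.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("matrix file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  samples <- header[-1L]
  if (anyDuplicated(samples))
    stop("duplicated sample id(s) in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  body <- fields[-1L]
  ncols <- lengths(body)
  if (any(ncols != length(header)))
    stop("ragged row(s) at line(s): ",
         paste(utils::head(which(ncols != length(header)) + 1L, 5),
               collapse = ", "))
  ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicated gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cells <- vapply(body, function(f) f[-1L], character(length(samples)))
  cells <- if (is.null(dim(cells))) matrix(cells, nrow = length(samples))
           else cells
  cells[cells == ""] <- NA_character_
  suppressWarnings(num <- as.numeric(cells))
  bad <- which(is.na(num) & !is.na(cells))
  if (length(bad)) {
    bad1 <- bad[1L]
    stop("non-numeric cell '", cells[bad1], "' at row ",
         ids[(bad1 - 1L) %/% length(samples) + 1L], ", column ",
         samples[(bad1 - 1L) %% length(samples) + 1L])
  }
  m <- matrix(num, nrow = length(ids), ncol = length(samples),
              byrow = TRUE, dimnames = list(ids, samples))
  m
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_matrix()]: `read_matrix(write_matrix(m, f))` reproduces
#' labels and values exactly (values are written with full precision).
#'
#' @param m Numeric matrix with dimnames, or a [coex_experiment].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  m <- .values(m)
  txt <- apply(m, 1L, function(r) {
    s <- sprintf("%.17g", r)
    s[is.na(r)] <- ""
    paste(s, collapse = "\t")
  })
  writeLines(c(paste(c("gene_id", colnames(m)), collapse = "\t"),
               paste(rownames(m), txt, sep = "\t")), path)
  invisible(path)
}

#' Read / write sample metadata
#'
#' Plain TSV with a `sample_id` column and any subset of the design fields
#' (`tissue`, `tree`, `dye`, `species`, `timepoint`).
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, colClasses = "character",
                            check.names = FALSE)
  if (is.null(meta$sample_id)) stop("metadata lacks a 'sample_id' column")
  meta
}

#' @rdname read_metadata
#' @param meta Data frame of per-sample metadata.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then tab-separated gene ids.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  fields <- fields[lengths(fields) > 0L]
  if (any(lengths(fields) < 3L))
    stop("GMT line(s) with fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicated gene-set names")
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Collapse probe-level data to gene level
#'
#' Two collapse rules are supported. `"mean"` averages the probe rows of
#' each gene per sample. `"any_significant"` implements the one-or-more
#' significant probes rule used for gene-level significance calls: a gene
#' is called significant iff at least one of its probes is.
#'
#' @param x Probe-level numeric matrix (rule `"mean"`) or a named logical
#'   vector of per-probe significance (rule `"any_significant"`).
#' @param map Data frame with columns `probe_id`, `gene_id` (many probes to
#'   one gene); every probe in `x` must be mapped.
#' @param rule `"mean"` or `"any_significant"`.
#' @return Gene-level matrix, or a named logical vector of gene calls.
#' @export
collapse_probes <- function(x, map, rule = c("mean", "any_significant")) {
  rule <- match.arg(rule)
  if (!all(c("probe_id", "gene_id") %in% names(map)))
    stop("'map' needs columns probe_id and gene_id")
  if (anyDuplicated(map$probe_id))
    stop("probe(s) mapped to more than one gene")
  probes <- if (rule == "mean") rownames(.values(x)) else names(x)
  missing_probes <- setdiff(probes, map$probe_id)
  if (length(missing_probes))
    stop("unmapped probe(s): ",
         paste(utils::head(missing_probes, 5), collapse = ", "))
  gene_of <- map$gene_id[match(probes, map$probe_id)]
  if (rule == "any_significant") {
    calls <- tapply(as.logical(x), gene_of, any)
    return(calls[unique(gene_of)])
  }
  m <- .values(x)
  out <- rowsum(m, gene_of, reorder = FALSE) /
    as.vector(table(factor(gene_of, levels = unique(gene_of))))
  out
}

#' Flag genes detected above background
#'
#' A simple detection rule standing in for platform-specific positive-probe
#' calling: a gene is detected if the maximum of its per-tissue mean
#' expression strictly exceeds the `background_quantile` of all values in
#' the matrix, i.e. it is detected in at least one tissue.
#'
#' @param x A [coex_experiment] with a `tissue` metadata field.
#' @param background_quantile Fraction in (0,1); default 0.1.
#' @return Character vector of detected gene ids. Genes whose values are
#'   all missing are reported undetected with a message.
#' @export
detect_expressed <- function(x, background_quantile = 0.1) {
  if (background_quantile <= 0 || background_quantile >= 1)
    stop("'background_quantile' must be strictly between 0 and 1")
  m <- .values(x)
  meta <- .meta(x)
  if (is.null(meta$tissue)) stop("metadata lacks a 'tissue' field")
  thr <- stats::quantile(m, background_quantile, na.rm = TRUE, names = FALSE)
  tf <- factor(meta$tissue)
  tissue_means <- vapply(levels(tf), function(t)
    rowMeans(m[, tf == t, drop = FALSE], na.rm = TRUE),
    numeric(nrow(m)))
  allmiss <- rowSums(!is.na(m)) == 0L
  if (any(allmiss))
    message("detect_expressed: ", sum(allmiss),
            " gene(s) with no non-missing values are undetected")
  best <- suppressWarnings(apply(tissue_means, 1L, max, na.rm = TRUE))
  rownames(m)[!allmiss & is.finite(best) & best > thr]
}

#' Average dye-swap technical replicates
#'
#' Collapses the two dye technical replicates of each biological replicate
#' (same tissue and tree) to their arithmetic mean, yielding one column per
#' biological replicate. Any additive per-gene dye main effect cancels
#' exactly in the averaged matrix. Unpaired technical replicates are kept
#' as-is with a warning. The `dye` metadata field is dropped.
#'
#' @param x A [coex_experiment] whose metadata has `tissue`, `tree` and
#'   `dye` fields (for temporal designs, `species`/`timepoint` and `tree`).
#' @return A [coex_experiment] with one column per biological replicate.
#' @export
average_technical_replicates <- function(x) {
  m <- .values(x)
  meta <- .meta(x)
  if (is.null(meta$dye) || length(unique(meta$dye)) < 2L) return(x)
  keys <- c("tissue", "species", "timepoint", "tree")
  keys <- intersect(keys, names(meta))
  if (!length(keys)) stop("metadata lacks replicate-identifying fields")
  unit <- do.call(paste, c(meta[keys], sep = "."))
  counts <- table(unit)
  if (any(counts == 1L))
    warning("unpaired technical replicate(s): ",
            paste(names(counts)[counts == 1L], collapse = ", "),
            "; single value used")
  units <- unique(unit)
  out <- vapply(units, function(u)
    rowMeans(m[, unit == u, drop = FALSE], na.rm = TRUE),
    numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m), ncol = length(units))
  dimnames(out) <- list(rownames(m), units)
  meta2 <- meta[match(units, unit), setdiff(names(meta), "dye"),
                drop = FALSE]
  meta2$sample_id <- units
  coex_experiment(out, meta2)
}

#' Hierarchical clustering of samples
#'
#' Clusters samples by Euclidean distance and Ward linkage (the `ward.D2`
#' implementation of Ward's criterion in [stats::hclust()]), the standard
#' QC view in which biological replicates of a tissue are expected to form
#' pure clades. Missing values are imputed with the per-gene mean first
#' (with a message).
#'
#' @param x A [coex_experiment] or numeric matrix (genes x samples).
#' @param linkage Only `"ward"` is supported.
#' @return An object of class `hclust` over samples.
#' @seealso [export_newick()] to serialise the dendrogram.
#' @export
cluster_samples <- function(x, linkage = "ward") {
  linkage <- match.arg(linkage, "ward")
  m <- .values(x)
  if (ncol(m) < 3L) stop("sample clustering needs at least 3 samples")
  if (anyNA(m)) {
    message("cluster_samples: imputing missing values with per-gene means")
    mu <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 1L]]
  }
  stats::hclust(stats::dist(t(m)), method = "ward.D2")
}

#' Export a dendrogram as Newick
#'
#' @param hc An `hclust` object, e.g. from [cluster_samples()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
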