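#' Construct an expression experiment
#'
#' Bundles a genes x samples matrix of log2 intensities with its per-sample
#' design metadata. This is the substrate of every stage of the pipeline:
#' classification, module detection, template matching and network
#' construction all consume a `coex_experiment`.
#'
#' @param values Numeric matrix, genes in rows, samples in columns; both
#'   dimensions must carry unique names. `NA` marks a missing measurement;
#'   all non-missing values must be finite.
#' @param meta Data frame with one row per sample. Must contain a
#'   `sample_id` column matching `colnames(values)` (order is aligned
#'   automatically); any subset of `tissue`, `tree`, `dye`, `species`,
#'   `timepoint` may be populated depending on the design.
#'
#' @return An object of class `coex_experiment`: a list with elements
#'   `values` and `meta`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(sample_id = paste0("s", 1:4),
#'                    tissue = rep(c("xylem", "apex"), each = 2))
#' x <- coex_experiment(m, meta)
coex_experiment <- function(values, meta) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have row (gene) and column (sample) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  bad <- !is.na(values) & !is.finite(values)
  if (any(bad))
    stop("non-finite expression values for gene(s): ",
         paste(utils::head(rownames(values)[rowSums(bad) > 0], 5),
               collapse = ", "))
  if (!is.data.frame(meta) || is.null(meta$sample_id))
    stop("'meta' must be a data.frame with a 'sample_id' column")
  meta$sample_id <- as.character(meta$sample_id)
  if (!setequal(meta$sample_id, colnames(values)) ||
      nrow(meta) != ncol(values))
    stop("metadata sample ids do not match matrix columns")
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "coex_experiment")
}

#' @export
print.coex_experiment <- function(x, ...) {
  cat("coex_experiment:", nrow(x$values), "genes x",
      ncol(x$values), "samples\n")
  fields <- intersect(c("tissue", "tree", "dye", "species", "timepoint"),
                      names(x$meta))
  for (f in fields) {
    lev <- unique(as.character(x$meta[[f]]))
    cat(" ", f, ": ", paste(utils::head(lev, 8), collapse = ", "),
        if (length(lev) > 8) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.coex_experiment <- function(x) dim(x$values)

# internal: accept either a coex_experiment or a bare matrix
.values <- function(x) {
  if (inherits(x, "coex_experiment")) x$values else x
}

.meta <- function(x) {
  if (!inherits(x, "coex_experiment"))
    stop("a coex_experiment (with sample metadata) is required here")
  x$meta
}
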