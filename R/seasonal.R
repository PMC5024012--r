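#' Two-way fixed-effects ANOVA for one gene
#'
#' Standard two-way ANOVA with species and time as crossed fixed factors
#' (with interaction), for a balanced layout with replication; used to
#' call temporally variable genes in the seasonal experiment.
#'
#' @param profile Numeric vector of one gene's values.
#' @param species,time Factors (or coercible) aligned with `profile`.
#' @return Data frame with rows `species`, `time`, `species_time`,
#'   `residual`: `ss`, `df`, `ms`, `F`, `p`. An all-equal profile reports
#'   `p = 1` for every effect.
#' @export
two_way_anova <- function(profile, species, time) {
  if (anyNA(profile)) stop("profile has missing values")
  species <- factor(species)
  time <- factor(time)
  if (nlevels(species) < 2L || nlevels(time) < 2L)
    stop("both factors need at least 2 levels")
  if (any(table(species, time) == 0L))
    stop("empty species x time cell")
  if (stats::var(profile) == 0) {
    return(data.frame(
      effect = c("species", "time", "species_time", "residual"),
      ss = 0, df = c(nlevels(species) - 1L, nlevels(time) - 1L,
                     (nlevels(species) - 1L) * (nlevels(time) - 1L),
                     length(profile) - nlevels(species) * nlevels(time)),
      ms = 0, F = c(0, 0, 0, NA), p = c(1, 1, 1, NA),
      stringsAsFactors = FALSE))
  }
  fit <- stats::lm(profile ~ species * time)
  av <- stats::anova(fit)
  data.frame(effect = c("species", "time", "species_time", "residual"),
             ss = av$`Sum Sq`, df = av$Df, ms = av$`Mean Sq`,
             F = av$`F value`, p = av$`Pr(>F)`,
             stringsAsFactors = FALSE)
}

#' Call temporally variable genes
#'
#' Runs the two-way species x time ANOVA on every probe (or gene, if
#' `probe_map` is `NULL`), Benjamini-Hochberg adjusts the time-effect
#' p-values across all probes in one family, and collapses to gene level
#' with the any-probe rule: a gene is temporally variable iff one or more
#' of its probes is significant at the adjusted `alpha`.
#'
#' @param x A [coex_experiment] with `species` and `timepoint` metadata;
#'   rows are probes when `probe_map` is given, genes otherwise.
#' @param probe_map Optional data.frame `probe_id`, `gene_id`.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param effect Which adjusted p-value drives the call: `"time"`
#'   (default) or `"species_time"`.
#' @return Data frame with one row per gene: `gene_id`, `species_p`,
#'   `time_p`, `interaction_p` (minimum adjusted p across the gene's
#'   probes), `variable` (logical).
#' @export
call_temporally_variable <- function(x, probe_map = NULL, alpha = 0.05,
                                     effect = c("time", "species_time")) {
  effect <- match.arg(effect)
  m <- .values(x)
  meta <- .meta(x)
  if (is.null(meta$species) || is.null(meta$timepoint))
    stop("metadata needs 'species' and 'timepoint' fields")
  species <- factor(meta$species)
  time <- factor(meta$timepoint)
  raw <- t(vapply(seq_len(nrow(m)), function(i) {
    av <- two_way_anova(m[i, ], species, time)
    stats::setNames(av$p[1:3], av$effect[1:3])
  }, numeric(3)))
  adj <- apply(raw, 2L, bh_adjust)
  rownames(adj) <- rownames(m)
  probe_sig <- stats::setNames(adj[, effect] < alpha, rownames(m))
  if (is.null(probe_map))
    probe_map <- data.frame(probe_id = rownames(m),
                            gene_id = rownames(m),
                            stringsAsFactors = FALSE)
  gene_call <- collapse_probes(probe_sig, probe_map,
                               rule = "any_significant")
  gene_of <- probe_map$gene_id[match(rownames(m), probe_map$probe_id)]
  agg <- function(col) as.vector(tapply(adj[, col], gene_of, min)[
    names(gene_call)])
  data.frame(gene_id = names(gene_call),
             species_p = agg("species"),
             time_p = agg("time"),
             interaction_p = agg("species_time"),
             variable = as.vector(gene_call),
             stringsAsFactors = FALSE)
}

#' Cluster temporally variable genes
#'
#' Applies the module-detection chain of [detect_modules()] to the
#' temporally variable genes (reference soft-thresholding power 18),
#' labelling the resulting temporal clusters `T1, T2, ...` with `a`/`b`
#' groups. Correlations and templates are computed on the
#' replicate-averaged per-timepoint samples if averaging was applied
#' beforehand.
#'
#' @param x A [coex_experiment].
#' @param genes Temporally variable gene ids.
#' @param beta Soft-thresholding power (default 18).
#' @param cut_height,min_module_size As in [detect_modules()].
#' @return A `module_set` with `T`-labelled clusters.
#' @export
temporal_clusters <- function(x, genes, beta = 18, cut_height = 0.5,
                              min_module_size = 30) {
  detect_modules(x, genes, beta = beta, cut_height = cut_height,
                 min_module_size = min_module_size, prefix = "T")
}

#' Classify temporal clusters by preferred season
#'
#' Automatic stand-in for profile inspection: a group's preferred
#' time-point is the argmax of its template averaged within time-points;
#' groups peaking at one of the `early` time-points are called
#' June-July-preferential, groups peaking at the `late` time-point(s)
#' September-preferential.
#'
#' @param mset A `module_set` of temporal clusters.
#' @param meta Sample metadata with `timepoint`, aligned with the
#'   templates.
#' @param early Indices of the early (June-July) time-points in the
#'   ordered unique time-point labels (default 1:2).
#' @param late Indices of the late time-point(s) (default: the last).
#' @return List with `june_july` and `september`, character vectors of
#'   group labels (`T1a`, ...).
#' @export
season_preference <- function(mset, meta, early = NULL, late = NULL) {
  if (is.null(meta$timepoint)) stop("metadata lacks 'timepoint'")
  tps <- unique(as.character(meta$timepoint))
  if (is.null(early)) early <- seq_len(min(2L, length(tps) - 1L))
  if (is.null(late)) late <- length(tps)
  templates <- group_templates(mset)
  pref <- vapply(templates, function(tmpl) {
    per_tp <- vapply(tps, function(tp)
      mean(tmpl[meta$timepoint == tp]), 0)
    which.max(per_tp)
  }, 0L)
  list(june_july = names(pref)[pref %in% early],
       september = names(pref)[pref %in% late])
}

#' Integrate temporal clusters with tissue-based coexpression groups
#'
#' Runs a representation analysis of every temporal cluster group
#' (treated as a gene set) across the tissue-based coexpression-group
#' partition, then phases genes: members of June-July-preferential
#' clusters that fall in tissue groups where those clusters are
#' significantly overrepresented are called `earlywood`; members of
#' September-preferential clusters in their overrepresented tissue groups
#' are called `latewood`; everything else is `none`.
#'
#' @param temporal_membership Named character vector gene -> temporal
#'   group label (e.g. [group_membership()] of the temporal
#'   `module_set`).
#' @param tissue_membership Named character vector gene -> tissue-based
#'   group label.
#' @param june_july,september Character vectors of temporal group labels
#'   (e.g. from [season_preference()]).
#' @param alpha Adjusted-p threshold of the overrepresentation calls.
#' @return List with `phase` (named character vector over the genes of
#'   the shared universe: `earlywood` / `latewood` / `none`) and
#'   `representation` (the underlying [representation_analysis()] table).
#' @export
phase_integration <- function(temporal_membership, tissue_membership,
                              june_july, september, alpha = 0.05) {
  universe <- intersect(names(temporal_membership),
                        names(tissue_membership))
  if (!length(universe))
    stop("temporal and tissue analyses share no genes")
  if (length(intersect(june_july, september)))
    stop("a temporal cluster cannot be both June-July and September ",
         "preferential")
  tm <- temporal_membership[universe]
  sets <- split(universe, tm)
  sets <- sets[names(sets) %in% c(june_july, september)]
  partition <- tissue_membership[universe]
  rep_tab <- representation_analysis(sets, partition,
                                     alpha = alpha, family = "per_set")
  phase <- stats::setNames(rep("none", length(universe)), universe)
  over <- rep_tab[rep_tab$call == "over", , drop = FALSE]
  for (i in seq_len(nrow(over))) {
    cluster_genes <- sets[[over$set_id[i]]]
    in_cell <- cluster_genes[
      tissue_membership[cluster_genes] == over$cell_id[i]]
    lab <- if (over$set_id[i] %in% june_july) "earlywood" else "latewood"
    phase[in_cell] <- lab
  }
  list(phase = phase, representation = rep_tab)
}
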