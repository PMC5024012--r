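#' Describe a multi-tissue dye-swap experimental design
#'
#' The reference design has seven vegetative tissues, four biological
#' replicates (trees) per tissue and two dye-swap technical replicates per
#' biological replicate, i.e. 56 arrays.
#'
#' @param tissues Character vector of unique tissue labels.
#' @param n_trees Biological replicates per tissue (>= 2).
#' @param n_dyes Technical dye replicates per biological replicate (1 or 2).
#' @return A `tissue_design` list.
#' @export
tissue_design <- function(tissues = spruce_tissues(), n_trees = 4,
                          n_dyes = 2) {
  tissues <- as.character(tissues)
  if (anyDuplicated(tissues)) stop("tissue labels must be unique")
  if (length(tissues) < 2L) stop("at least 2 tissues are required")
  if (n_trees < 2L) stop("'n_trees' must be >= 2")
  if (!n_dyes %in% c(1L, 2L)) stop("'n_dyes' must be 1 or 2")
  structure(list(tissues = tissues, n_trees = as.integer(n_trees),
                 n_dyes = as.integer(n_dyes)), class = "tissue_design")
}

#' Labels of the seven reference vegetative tissues
#'
#' Shoot apex, young foliage, shoot/root secondary xylem, shoot/root
#' phelloderm and root tips -- the tissue panel the default simulated
#' experiment emulates.
#'
#' @return Character vector of length 7.
#' @export
spruce_tissues <- function() {
  c("apex", "foliage", "xylem_shoot", "xylem_root",
    "phelloderm_shoot", "phelloderm_root", "root_tip")
}

#' Specify a planted expression module
#'
#' A planted module is a pair of anticorrelated gene groups: group `a`
#' genes follow `amplitude * tissue_profile` (log2 shifts added to a
#' gene-specific baseline) and group `b` genes follow its negation.
#'
#' @param module_id Unique label, e.g. `"M1"`.
#' @param n_genes_a,n_genes_b Gene counts in the two groups (>= 1).
#' @param tissue_profile Numeric vector of per-tissue mean shifts (log2),
#'   one entry per tissue of the design.
#' @param amplitude Positive effect-size multiplier (log2 units).
#' @return A `module_spec` list.
#' @export
module_spec <- function(module_id, n_genes_a, n_genes_b, tissue_profile,
                        amplitude = 1) {
  if (n_genes_a < 1L || n_genes_b < 1L)
    stop("group sizes must be >= 1")
  if (amplitude <= 0) stop("'amplitude' must be > 0")
  structure(list(module_id = as.character(module_id),
                 n_genes_a = as.integer(n_genes_a),
                 n_genes_b = as.integer(n_genes_b),
                 tissue_profile = as.numeric(tissue_profile),
                 amplitude = as.numeric(amplitude)),
            class = "module_spec")
}

#' Draw near-orthogonal planted module profiles
#'
#' Builds `k` module specifications whose tissue profiles are columns of a
#' random orthonormal basis (centred, scaled to unit standard deviation),
#' so distinct planted modules are close to uncorrelated.
#'
#' @param k Number of modules (<= number of tissues - 1).
#' @param n_genes_a,n_genes_b Group sizes shared by all modules.
#' @param amplitude Effect size (log2), shared by all modules.
#' @param tissues Tissue labels of the target design.
#' @param seed Integer seed for the profile draw.
#' @return List of [module_spec()] objects labelled `M1 ... Mk`.
#' @export
random_module_specs <- function(k, n_genes_a, n_genes_b, amplitude = 2,
                                tissues = spruce_tissues(), seed = 1) {
  nt <- length(tissues)
  if (k > nt - 1L) stop("at most ", nt - 1L, " near-orthogonal modules")
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(nt * k), nt, k)))
  lapply(seq_len(k), function(j) {
    p <- q[, j] - mean(q[, j])
    p <- p / stats::sd(p)
    module_spec(paste0("M", j), n_genes_a, n_genes_b, p, amplitude)
  })
}

# deterministic per-gene sub-stream seed derived from the global seed
.gene_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 69069 + i * 104729) %%
               2147483646 + 1)
}

#' Simulate a multi-tissue dye-swap expression experiment
#'
#' Generates a genes x arrays log2 matrix with known planted structure:
#' anticorrelated module gene pairs, tissue-invariant genes, and
#' assumption-violating genes. The noise model is independent Gaussian on
#' the log2 scale, with a Gaussian tree random intercept shared by the two
#' dye replicates of a biological replicate (mirroring the nested random
#' effect of the downstream ANOVA) and an optional per-gene additive dye
#' effect split symmetrically across the two dyes. Violators come in two
#' kinds, exercising both screening branches: heavy-tailed (Cauchy, i.e.
#' t with 1 df, emulating spike-like spot artifacts) noise
#' and a strong additive dye main effect.
#'
#' All draws descend deterministically from `seed` via per-gene
#' sub-streams, so the same call reproduces the identical matrix.
#'
#' @param design A [tissue_design()].
#' @param modules List of [module_spec()]; profile lengths must equal the
#'   number of tissues and module ids must be unique.
#' @param n_invariant Number of planted invariant genes.
#' @param n_violators Number of assumption violators (alternating
#'   heavy-tail / dye-effect kinds).
#' @param baseline_range Log2 interval baselines are drawn uniformly from.
#' @param noise_sd,dye_effect_sd,tree_effect_sd Non-negative log2
#'   standard deviations of measurement noise, per-gene dye effect, and
#'   tree random intercept.
#' @param violator_dye_effect Additive log2 dye shift planted in
#'   dye-effect violators.
#' @param seed Integer seed.
#' @return List with `experiment` (a [coex_experiment]) and `truth`, a
#'   data.frame with one row per gene: `gene_id`, `class`
#'   (`module`/`invariant`/`violator`), `module_id`, `group` (`a`/`b`),
#'   `violator_type` and `baseline`.
#' @export
generate_tissue_experiment <- function(design, modules,
                                       n_invariant,
                                       n_violators = 0,
                                       baseline_range = c(6, 12),
                                       noise_sd = 0.2,
                                       dye_effect_sd = 0,
                                       tree_effect_sd = 0.1,
                                       violator_dye_effect = 1,
                                       seed = 1) {
  stopifnot(inherits(design, "tissue_design"))
  if (n_invariant < 0L || n_violators < 0L)
    stop("gene counts must be non-negative")
  if (noise_sd < 0 || dye_effect_sd < 0 || tree_effect_sd < 0)
    stop("standard deviations must be non-negative")
  ids <- vapply(modules, `[[`, "", "module_id")
  if (anyDuplicated(ids)) stop("duplicate module ids")
  nt <- length(design$tissues)
  for (m in modules)
    if (length(m$tissue_profile) != nt)
      stop("tissue_profile of ", m$module_id, " has wrong length")

  grid <- expand.grid(dye = paste0("d", seq_len(design$n_dyes)),
                      tree = paste0("t", seq_len(design$n_trees)),
                      tissue = design$tissues,
                      stringsAsFactors = FALSE)[, 3:1]
  meta <- data.frame(sample_id = paste(grid$tissue, grid$tree, grid$dye,
                                       sep = "."),
                     grid, stringsAsFactors = FALSE)
  tissue_idx <- match(grid$tissue, design$tissues)
  unit_idx <- as.integer(factor(paste(grid$tissue, grid$tree),
                                levels = unique(paste(grid$tissue,
                                                      grid$tree))))
  dye_sign <- if (design$n_dyes == 2L)
    ifelse(grid$dye == "d1", 0.5, -0.5) else rep(0, nrow(grid))

  truth <- list()
  add_gene <- function(id, class, module_id = NA_character_,
                       group = NA_character_,
                       violator_type = NA_character_) {
    list(gene_id = id, class = class, module_id = module_id,
         group = group, violator_type = violator_type)
  }
  for (m in modules) {
    for (j in seq_len(m$n_genes_a))
      truth[[length(truth) + 1L]] <-
        add_gene(sprintf("%sa_%03d", m$module_id, j), "module",
                 m$module_id, "a")
    for (j in seq_len(m$n_genes_b))
      truth[[length(truth) + 1L]] <-
        add_gene(sprintf("%sb_%03d", m$module_id, j), "module",
                 m$module_id, "b")
  }
  for (j in seq_len(n_invariant))
    truth[[length(truth) + 1L]] <-
      add_gene(sprintf("inv_%04d", j), "invariant")
  vtypes <- rep(c("heavy_tail", "dye_effect"), length.out = n_violators)
  for (j in seq_len(n_violators))
    truth[[length(truth) + 1L]] <-
      add_gene(sprintf("viol_%03d", j), "violator",
               violator_type = vtypes[j])
  truth <- do.call(rbind.data.frame, c(truth, stringsAsFactors = FALSE))
  if (anyDuplicated(truth$gene_id)) stop("internal: duplicated gene ids")

  shift_of <- function(row) {
    if (row$class != "module") return(rep(0, nt))
    m <- modules[[match(row$module_id, ids)]]
    s <- m$amplitude * m$tissue_profile
    if (row$group == "b") -s else s
  }

  ns <- nrow(grid)
  values <- matrix(NA_real_, nrow(truth), ns,
                   dimnames = list(truth$gene_id, meta$sample_id))
  baselines <- numeric(nrow(truth))
  n_units <- max(unit_idx)
  for (i in seq_len(nrow(truth))) {
    set.seed(.gene_seed(seed, i))
    row <- truth[i, ]
    baselines[i] <- stats::runif(1, baseline_range[1], baseline_range[2])
    tree_eff <- stats::rnorm(n_units, 0, tree_effect_sd)
    dye_eff <- if (identical(row$violator_type, "dye_effect"))
      violator_dye_effect else stats::rnorm(1, 0, dye_effect_sd)
    noise <- if (identical(row$violator_type, "heavy_tail"))
      stats::rt(ns, df = 1) * noise_sd else stats::rnorm(ns, 0, noise_sd)
    values[i, ] <- baselines[i] + shift_of(row)[tissue_idx] +
      tree_eff[unit_idx] + dye_sign * dye_eff + noise
  }
  truth$baseline <- baselines
  list(experiment = coex_experiment(values, meta), truth = truth)
}

#' Specify a planted temporal cluster
#'
#' As [module_spec()], but the profile runs over time-points of a seasonal
#' experiment instead of tissues.
#'
#' @param cluster_id Unique label, e.g. `"T1"`.
#' @param n_genes_a,n_genes_b Group sizes (>= 1; `n_genes_b` may be 0 for
#'   a single-profile cluster).
#' @param time_profile Per-timepoint mean shifts (log2).
#' @param amplitude Positive effect size (log2).
#' @return A `temporal_cluster_spec` list.
#' @export
temporal_cluster_spec <- function(cluster_id, n_genes_a, n_genes_b,
                                  time_profile, amplitude = 1) {
  if (n_genes_a < 1L || n_genes_b < 0L) stop("invalid group sizes")
  if (amplitude <= 0) stop("'amplitude' must be > 0")
  structure(list(cluster_id = as.character(cluster_id),
                 n_genes_a = as.integer(n_genes_a),
                 n_genes_b = as.integer(n_genes_b),
                 time_profile = as.numeric(time_profile),
                 amplitude = as.numeric(amplitude)),
            class = "temporal_cluster_spec")
}

#' Default planted seasonal profiles
#'
#' Two canonical growing-season patterns over four time-points
#' (June, July, August, September): a "stable then step change" profile
#' that holds June-August and drops sharply in September, and a
#' "progressive" profile that declines through August before the September
#' change. Their `b` groups are the mirrored (latewood-preferential)
#' patterns.
#'
#' @param n_genes_a,n_genes_b Group sizes per cluster.
#' @param amplitude Effect size (log2).
#' @return List of two [temporal_cluster_spec()] objects.
#' @export
default_temporal_clusters <- function(n_genes_a = 60, n_genes_b = 60,
                                      amplitude = 2) {
  list(temporal_cluster_spec("T1", n_genes_a, n_genes_b,
                             c(0.5, 0.5, 0.5, -1.5), amplitude),
       temporal_cluster_spec("T2", n_genes_a, n_genes_b,
                             c(0.9, 0.6, -0.1, -1.4), amplitude))
}

#' Simulate a two-species seasonal xylem experiment
#'
#' Emulates a secondary-xylem time course: two species sampled at four
#' time-points with several trees per cell, planted temporal clusters
#' (each an anticorrelated pair of gene groups), and a remainder of
#' temporally invariant genes. Truth records cluster membership and the
#' seasonal phase implied by each profile (preferred time-point in
#' June/July = earlywood-like, September = latewood-like).
#'
#' @param n_genes Total genes; cluster member counts must sum to at most
#'   this (remainder = temporally invariant).
#' @param cluster_specs List of [temporal_cluster_spec()].
#' @param species Character vector of species labels (>= 1).
#' @param timepoints Character vector of >= 2 time-point labels; profiles
#'   must have this length.
#' @param n_trees Trees per species x time-point cell.
#' @param baseline_range,noise_sd,species_effect_sd As in
#'   [generate_tissue_experiment()]; `species_effect_sd` is a per-gene
#'   Gaussian species main effect.
#' @param seed Integer seed.
#' @return List with `experiment` and `truth` (`gene_id`, `class`,
#'   `cluster_id`, `group`, `phase`, `baseline`).
#' @export
generate_temporal_experiment <- function(n_genes,
                                         cluster_specs =
                                           default_temporal_clusters(),
                                         species = c("white_spruce",
                                                     "norway_spruce"),
                                         timepoints = c("jun", "jul",
                                                        "aug", "sep"),
                                         n_trees = 6,
                                         baseline_range = c(6, 12),
                                         noise_sd = 0.2,
                                         species_effect_sd = 0,
                                         seed = 1) {
  if (length(timepoints) < 2L) stop("at least 2 timepoints are required")
  if (noise_sd < 0 || species_effect_sd < 0)
    stop("standard deviations must be non-negative")
  ids <- vapply(cluster_specs, `[[`, "", "cluster_id")
  if (anyDuplicated(ids)) stop("duplicate cluster ids")
  ntp <- length(timepoints)
  for (cs in cluster_specs)
    if (length(cs$time_profile) != ntp)
      stop("time_profile of ", cs$cluster_id, " has wrong length")
  n_planted <- sum(vapply(cluster_specs,
                          function(cs) cs$n_genes_a + cs$n_genes_b, 0L))
  if (n_planted > n_genes)
    stop("cluster member counts exceed 'n_genes'")

  grid <- expand.grid(tree = paste0("t", seq_len(n_trees)),
                      timepoint = timepoints, species = species,
                      stringsAsFactors = FALSE)[, 3:1]
  meta <- data.frame(sample_id = paste(grid$species, grid$timepoint,
                                       grid$tree, sep = "."),
                     grid, stringsAsFactors = FALSE)
  tp_idx <- match(grid$timepoint, timepoints)
  sp_sign <- if (length(species) == 2L)
    ifelse(grid$species == species[1L], 0.5, -0.5)
  else rep(0, nrow(grid))

  phase_of <- function(profile) {
    pref <- which.max(profile)
    if (pref <= min(2L, ntp - 1L)) "earlywood"
    else if (pref == ntp) "latewood"
    else "none"
  }

  truth <- list()
  for (cs in cluster_specs) {
    for (j in seq_len(cs$n_genes_a))
      truth[[length(truth) + 1L]] <-
        list(gene_id = sprintf("%sa_%03d", cs$cluster_id, j),
             class = "cluster", cluster_id = cs$cluster_id, group = "a",
             phase = phase_of(cs$time_profile))
    for (j in seq_len(cs$n_genes_b))
      truth[[length(truth) + 1L]] <-
        list(gene_id = sprintf("%sb_%03d", cs$cluster_id, j),
             class = "cluster", cluster_id = cs$cluster_id, group = "b",
             phase = phase_of(-cs$time_profile))
  }
  for (j in seq_len(n_genes - n_planted))
    truth[[length(truth) + 1L]] <-
      list(gene_id = sprintf("tinv_%04d", j), class = "invariant",
           cluster_id = NA_character_, group = NA_character_,
           phase = "none")
  truth <- do.call(rbind.data.frame, c(truth, stringsAsFactors = FALSE))

  ns <- nrow(grid)
  values <- matrix(NA_real_, nrow(truth), ns,
                   dimnames = list(truth$gene_id, meta$sample_id))
  baselines <- numeric(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    set.seed(.gene_seed(seed + 500000L, i))
    row <- truth[i, ]
    baselines[i] <- stats::runif(1, baseline_range[1], baseline_range[2])
    shift <- rep(0, ntp)
    if (row$class == "cluster") {
      cs <- cluster_specs[[match(row$cluster_id, ids)]]
      shift <- cs$amplitude * cs$time_profile
      if (row$group == "b") shift <- -shift
    }
    sp_eff <- stats::rnorm(1, 0, species_effect_sd)
    values[i, ] <- baselines[i] + shift[tp_idx] + sp_sign * sp_eff +
      stats::rnorm(ns, 0, noise_sd)
  }
  truth$baseline <- baselines
  list(experiment = coex_experiment(values, meta), truth = truth)
}

#' Write a simulated experiment to disk
#'
#' Writes the expression matrix, sample metadata and truth table as TSV.
#'
#' @param sim Result of [generate_tissue_experiment()] or
#'   [generate_temporal_experiment()].
#' @param prefix Path prefix; files `<prefix>_matrix.tsv`,
#'   `<prefix>_meta.tsv`, `<prefix>_truth.tsv` are created.
#' @return Character vector of the three paths, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  paths <- paste0(prefix, c("_matrix.tsv", "_meta.tsv", "_truth.tsv"))
  write_matrix(sim$experiment$values, paths[1])
  write_metadata(sim$experiment$meta, paths[2])
  utils::write.table(sim$truth, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
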