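#' Default pipeline configuration
#'
#' Returns the full configuration list of [run_pipeline()] with the
#' reference thresholds (variable/invariant split at adjusted p 0.05,
#' high confidence at 0.0001, template assignment at 0.05, network
#' cutoff |r| > 0.9, soft-thresholding powers 14 and 18 for the tissue
#' and seasonal experiments) and a synthetic scenario sized for a desk
#' run.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    tissue = list(n_modules = 3L, n_genes_a = 50L, n_genes_b = 50L,
                  amplitude = 2, n_invariant = 500L, n_violators = 20L,
                  noise_sd = 0.2, tree_effect_sd = 0.1,
                  dye_effect_sd = 0, n_trees = 4L, n_dyes = 2L),
    temporal = list(n_genes = 400L, noise_sd = 0.2, n_trees = 6L),
    thresholds = list(alpha_screen = 0.05, alpha_variable = 0.05,
                      alpha_high = 1e-4, alpha_template = 0.05,
                      alpha_enrich = 0.05, network_threshold = 0.9,
                      beta_tissue = 14, beta_temporal = 18,
                      cut_height = 0.5, min_module_size = 20L))
}

#' Read and validate a pipeline configuration
#'
#' @param path Path to a YAML (or JSON) configuration file; missing
#'   entries are filled from [default_config()].
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  merge_cfg <- function(base, new) {
    for (nm in names(new))
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(new[[nm]]))
        merge_cfg(base[[nm]], new[[nm]]) else new[[nm]]
    base
  }
  validate_config(merge_cfg(default_config(), cfg))
}

#' @rdname read_pipeline_config
#' @param cfg Configuration list.
#' @export
validate_config <- function(cfg) {
  th <- cfg$thresholds
  chk <- function(v, lo, hi, nm) {
    if (is.null(v) || !is.numeric(v) || v < lo || v > hi)
      stop("config: '", nm, "' must be in [", lo, ", ", hi, "]")
  }
  chk(th$alpha_variable, 0, 1, "alpha_variable")
  chk(th$alpha_high, 0, 1, "alpha_high")
  chk(th$alpha_template, 0, 1, "alpha_template")
  chk(th$network_threshold, 1e-12, 1 - 1e-12, "network_threshold")
  chk(th$beta_tissue, 1, Inf, "beta_tissue")
  chk(th$beta_temporal, 1, Inf, "beta_temporal")
  chk(th$cut_height, 1e-12, 1, "cut_height")
  if (is.null(cfg$seed) || cfg$seed != round(cfg$seed))
    stop("config: 'seed' must be an integer")
  cfg
}

.pipe_log <- function(quiet, stage, ...) {
  if (!quiet) message("[", stage, "] ", ...)
}

#' Run the full synthetic-to-networks pipeline
#'
#' Orchestrates every stage in dependency order: simulate the tissue and
#' seasonal experiments, classify genes (screening + balanced mixed
#' ANOVA), detect modules from high-confidence genes on the
#' replicate-averaged matrix, assign low-confidence genes by template
#' matching, partition invariant genes into expression quartiles, build
#' the signed correlation network of the largest module with hub
#' statistics, and run the seasonal analysis through phase integration.
#' To couple the two experiments the seasonal genes are relabelled with
#' tissue-experiment gene ids (planted temporal groups onto planted
#' tissue module groups), emulating genes measured in both experiments.
#' All stage outputs are written as TSV under `out_dir` along with a JSON
#' `manifest.json` holding the configuration, seed, package version and
#' MD5 hash of every output file. Re-running with the same configuration
#' reproduces identical files.
#'
#' @param cfg Configuration list (see [default_config()]) or path to a
#'   YAML file.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- cfg$thresholds
  tc <- cfg$tissue
  out <- function(f) file.path(out_dir, f)

  .pipe_log(quiet, "simulate", "tissue experiment: ",
            tc$n_modules, " modules, ", tc$n_invariant, " invariant, ",
            tc$n_violators, " violators")
  design <- tissue_design(n_trees = tc$n_trees, n_dyes = tc$n_dyes)
  mods <- random_module_specs(tc$n_modules, tc$n_genes_a, tc$n_genes_b,
                              amplitude = tc$amplitude,
                              seed = cfg$seed)
  sim1 <- generate_tissue_experiment(
    design, mods, n_invariant = tc$n_invariant,
    n_violators = tc$n_violators, noise_sd = tc$noise_sd,
    dye_effect_sd = tc$dye_effect_sd,
    tree_effect_sd = tc$tree_effect_sd, seed = cfg$seed)
  write_simulation(sim1, out("expt1"))

  sim2 <- generate_temporal_experiment(
    cfg$temporal$n_genes, n_trees = cfg$temporal$n_trees,
    noise_sd = cfg$temporal$noise_sd, seed = cfg$seed)
  # couple the experiments: planted temporal groups reuse the ids of
  # planted tissue module groups (then invariant ids), as if the same
  # genes had been profiled in both designs
  tissue_ids <- c(sim1$truth$gene_id[sim1$truth$class == "module"],
                  sim1$truth$gene_id[sim1$truth$class == "invariant"])
  n2 <- nrow(sim2$truth)
  if (n2 > length(tissue_ids))
    stop("config: temporal n_genes exceeds the shared gene universe")
  map <- tissue_ids[seq_len(n2)]
  rownames(sim2$experiment$values) <- map
  sim2$truth$gene_id <- map
  write_simulation(sim2, out("expt2"))

  .pipe_log(quiet, "classify", nrow(sim1$experiment$values),
            " genes through screening + mixed ANOVA")
  cls <- classify_genes(sim1$experiment,
                        alpha_screen = th$alpha_screen,
                        alpha_variable = th$alpha_variable,
                        alpha_high = th$alpha_high)
  utils::write.table(cls$screen, out("screen.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cls$classification, out("classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- table(cls$classification$category)
  .pipe_log(quiet, "classify", paste(names(counts), counts,
                                     sep = "=", collapse = ", "))

  avg1 <- average_technical_replicates(sim1$experiment)
  hc_genes <- cls$classification$gene_id[
    cls$classification$category == "variable_high"]
  .pipe_log(quiet, "modules", length(hc_genes),
            " high-confidence genes, beta=", th$beta_tissue)
  mset <- detect_modules(avg1, hc_genes, beta = th$beta_tissue,
                         cut_height = th$cut_height,
                         min_module_size = th$min_module_size)
  utils::write.table(mset$membership, out("modules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  eig <- do.call(rbind, lapply(mset$modules, function(mod) mod$eigengene))
  rownames(eig) <- vapply(mset$modules, `[[`, "", "module_id")
  write_matrix(eig, out("eigengenes.tsv"))
  templates <- group_templates(mset)
  write_matrix(do.call(rbind, templates), out("templates.tsv"))

  lc_genes <- cls$classification$gene_id[
    cls$classification$category == "variable_low"]
  assign_res <- NULL
  if (length(lc_genes)) {
    .pipe_log(quiet, "assign", length(lc_genes),
              " low-confidence genes against ", length(templates),
              " templates")
    assign_res <- template_match(avg1, lc_genes, templates,
                                 alpha = th$alpha_template)
    utils::write.table(assign_res, out("assignments.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  inv_genes <- cls$classification$gene_id[
    cls$classification$category == "invariant"]
  quart <- NULL
  if (length(inv_genes) >= 4L) {
    .pipe_log(quiet, "enrich", "quartile classes over ",
              length(inv_genes), " invariant genes")
    means <- rowMeans(sim1$experiment$values[inv_genes, , drop = FALSE])
    quart <- quartile_classes(means)
    utils::write.table(quart, out("quartiles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  net <- NULL
  if (length(mset$modules)) {
    genes1 <- mset$modules[[1L]]$members
    .pipe_log(quiet, "network", "|r| > ", th$network_threshold, " on ",
              length(genes1), " genes of ",
              mset$modules[[1L]]$module_id)
    net <- build_network(avg1, genes1,
                         threshold = th$network_threshold)
    write_network(net, out("network_edges.tsv"))
    utils::write.table(degree_rank(net), out("network_degrees.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  .pipe_log(quiet, "seasonal", "two-way ANOVA on ",
            nrow(sim2$experiment$values), " genes")
  calls <- call_temporally_variable(sim2$experiment,
                                    alpha = th$alpha_variable)
  utils::write.table(calls, out("temporal_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  seasonal_res <- NULL
  var_genes <- calls$gene_id[calls$variable]
  avg2 <- average_technical_replicates(sim2$experiment)
  min_t <- min(th$min_module_size,
               max(3L, floor(length(var_genes) / 4L)))
  if (length(var_genes) >= 2L * min_t) {
    tset <- temporal_clusters(avg2, var_genes, beta = th$beta_temporal,
                              cut_height = th$cut_height,
                              min_module_size = min_t)
    utils::write.table(tset$membership, out("temporal_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pref <- season_preference(tset, avg2$meta)
    tissue_groups <- group_membership(mset)
    if (!is.null(assign_res)) {
      ok <- assign_res$status == "assigned"
      tissue_groups <- c(tissue_groups,
                         stats::setNames(assign_res$best_group[ok],
                                         assign_res$gene_id[ok]))
    }
    shared <- intersect(names(group_membership(tset)),
                        names(tissue_groups))
    if (length(shared)) {
      ph <- phase_integration(group_membership(tset), tissue_groups,
                              june_july = pref$june_july,
                              september = pref$september,
                              alpha = th$alpha_enrich)
      phase_tab <- data.frame(gene_id = names(ph$phase),
                              phase = unname(ph$phase),
                              stringsAsFactors = FALSE)
      utils::write.table(phase_tab, out("phases.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(ph$representation,
                         out("phase_representation.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      seasonal_res <- list(clusters = tset, preference = pref,
                           phase = ph)
    } else {
      .pipe_log(quiet, "seasonal",
                "no genes shared with tissue groups; phase skipped")
    }
  } else {
    .pipe_log(quiet, "seasonal", "too few variable genes (",
              length(var_genes), ") for clustering; stage skipped")
  }

  files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(package = "coexmap",
                   version = as.character(utils::packageVersion(
                     "coexmap")),
                   seed = cfg$seed, config = cfg,
                   files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(config = cfg, sim_tissue = sim1, sim_temporal = sim2,
                 classification = cls, modules = mset,
                 assignments = assign_res, quartiles = quart,
                 network = net, seasonal = seasonal_res,
                 manifest = manifest))
}
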