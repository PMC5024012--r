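# shared fixtures: small planted experiments and truth-comparison helpers

# adjusted Rand index between two label vectors (mclust implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# a standard 2-module tissue simulation used by several files
two_module_sim <- function(noise_sd = 0.2, n_invariant = 100,
                           n_violators = 0, seed = 7, amplitude = 2) {
  mods <- random_module_specs(2, 50, 50, amplitude = amplitude, seed = 3)
  generate_tissue_experiment(tissue_design(), mods,
                             n_invariant = n_invariant,
                             n_violators = n_violators,
                             noise_sd = noise_sd, seed = seed)
}

# run classification + module detection, return everything needed for
# truth comparison
detect_from_sim <- function(sim, beta = 14, min_module_size = 20) {
  cls <- classify_genes(sim$experiment)
  avg <- average_technical_replicates(sim$experiment)
  hc <- cls$classification$gene_id[
    cls$classification$category == "variable_high"]
  mset <- detect_modules(avg, hc, beta = beta,
                         min_module_size = min_module_size)
  list(cls = cls, avg = avg, mset = mset)
}

# ARI of detected module labels vs planted module ids, over planted
# module genes that entered detection
module_recovery_ari <- function(sim, mset) {
  mm <- mset$membership
  truth_mod <- sim$truth$module_id[match(mm$gene_id, sim$truth$gene_id)]
  keep <- !is.na(truth_mod)
  ari(truth_mod[keep], mm$module[keep])
}

# map detected group labels to planted module/group by majority overlap
group_label_map <- function(sim, mset) {
  mm <- mset$membership[mset$membership$module != "unassigned", ]
  truth <- sim$truth[match(mm$gene_id, sim$truth$gene_id), ]
  detected <- paste0(mm$module, mm$group)
  planted <- paste0(truth$module_id, truth$group)
  tab <- table(detected, planted)
  vapply(rownames(tab), function(d)
    colnames(tab)[which.max(tab[d, ])], "")
}
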