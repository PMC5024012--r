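test_that("two-way ANOVA matches a longhand balanced computation and is
          symmetric in species", {
  species <- rep(c("A", "B"), each = 8)
  time <- rep(rep(c("t1", "t2"), each = 4), 2)
  set.seed(3)
  y <- rnorm(16) + rep(c(0, 2), each = 8)
  av <- two_way_anova(y, species, time)
  # longhand balanced two-factor sums of squares
  grand <- mean(y)
  ms <- tapply(y, species, mean)
  mt <- tapply(y, time, mean)
  mc <- tapply(y, paste(species, time), mean)
  ss_sp <- 8 * sum((ms - grand)^2)
  ss_t <- 8 * sum((mt - grand)^2)
  exp_c <- outer(ms - grand, mt - grand, `+`) + grand
  ss_int <- 4 * sum((mc[paste(rep(c("A", "B"), each = 2),
                              rep(c("t1", "t2"), 2))] -
                       as.vector(t(exp_c)))^2)
  expect_equal(av$ss[1], ss_sp)
  expect_equal(av$ss[2], ss_t)
  expect_equal(av$ss[3], ss_int)
  expect_equal(sum(av$ss), sum((y - grand)^2))
  # swapping species labels leaves the time p unchanged
  sw <- two_way_anova(y, ifelse(species == "A", "B", "A"), time)
  expect_equal(sw$p[2], av$p[2])
  # degenerate all-equal profile
  flat <- two_way_anova(rep(1, 16), species, time)
  expect_true(all(flat$p[1:3] == 1))
  expect_error(two_way_anova(y[1:8], rep(c("A", "B"), each = 4),
                             c("t1", "t2", "t1", "t2", rep("t1", 4))),
               "empty")
  expect_error(two_way_anova(y[1:8], rep("A", 8),
                             rep(c("t1", "t2"), 4)), "2 levels")
})

test_that("temporal calls follow the any-probe rule and the alpha
          boundary", {
  sim <- generate_temporal_experiment(
    480, cluster_specs = default_temporal_clusters(amplitude = 3),
    noise_sd = 0.1, seed = 3)
  # probe-level: pair a planted probe with a null probe per gene
  m <- sim$experiment$values
  planted <- sim$truth$gene_id[sim$truth$class == "cluster"]
  null_probes <- sim$truth$gene_id[sim$truth$class == "invariant"]
  stopifnot(length(null_probes) >= length(planted))
  pm <- data.frame(
    probe_id = c(planted, null_probes[seq_along(planted)]),
    gene_id = rep(paste0("gene", seq_along(planted)), 2))
  sub <- coex_experiment(m[pm$probe_id, ], sim$experiment$meta)
  calls <- call_temporally_variable(sub, probe_map = pm)
  # one significant probe of two suffices
  expect_true(all(calls$variable))
  # alpha = 0 calls nothing
  calls0 <- call_temporally_variable(sub, probe_map = pm, alpha = 0)
  expect_false(any(calls0$variable))
})

test_that("planted step-change genes are all recovered and the null
          rate is controlled", {
  sim <- generate_temporal_experiment(
    400, cluster_specs = default_temporal_clusters(amplitude = 3),
    noise_sd = 0.1, seed = 5)
  calls <- call_temporally_variable(sim$experiment)
  truth <- sim$truth[match(calls$gene_id, sim$truth$gene_id), ]
  expect_true(all(calls$variable[truth$class == "cluster"]))
  # BH under a sparse-signal mixture keeps null false calls rare
  expect_lte(mean(calls$variable[truth$class == "invariant"]), 0.05)
})

test_that("two-way time p-values are calibrated under a pure null", {
  sim <- generate_temporal_experiment(
    500, cluster_specs = list(), noise_sd = 0.2, seed = 9)
  meta <- sim$experiment$meta
  p <- vapply(seq_len(500), function(i)
    two_way_anova(sim$experiment$values[i, ], meta$species,
                  meta$timepoint)$p[2], 0)
  for (alpha in c(0.01, 0.05)) {
    tol <- 3 * sqrt(alpha * (1 - alpha) / 500)
    expect_lt(abs(mean(p < alpha) - alpha), tol)
  }
  # and BH across a global null calls essentially nothing
  calls <- call_temporally_variable(sim$experiment)
  expect_lte(mean(calls$variable), 0.01)
})

test_that("temporal clustering recovers planted clusters and splits
          anticorrelated pairs", {
  sim <- generate_temporal_experiment(300, noise_sd = 0.2, seed = 7)
  calls <- call_temporally_variable(sim$experiment)
  vg <- calls$gene_id[calls$variable]
  tset <- temporal_clusters(sim$experiment, vg, min_module_size = 20)
  truth <- sim$truth
  mm <- tset$membership
  tmod <- truth$cluster_id[match(mm$gene_id, truth$gene_id)]
  keep <- !is.na(tmod)
  expect_gte(ari(tmod[keep], mm$module[keep]), 0.9)
  # each detected cluster holds two anticorrelated groups
  for (mod in tset$modules) {
    expect_gt(length(mod$group_a), 0)
    expect_gt(length(mod$group_b), 0)
    expect_lt(cor(mod$template_a, mod$template_b), -0.8)
  }
})

test_that("a single planted profile yields one module with an empty
          group", {
  cs <- list(temporal_cluster_spec("T1", 40, 0, c(1, 1, 1, -1.5),
                                   amplitude = 2))
  sim <- generate_temporal_experiment(60, cluster_specs = cs,
                                      noise_sd = 0.1, seed = 11)
  calls <- call_temporally_variable(sim$experiment)
  vg <- calls$gene_id[calls$variable]
  expect_warning(
    expect_message(
      tset <- temporal_clusters(sim$experiment, vg,
                                min_module_size = 10),
      "single expression profile"),
    "single module")
  expect_length(tset$modules, 1L)
  expect_length(tset$modules[[1]]$group_b, 0L)
})

test_that("season preference reads templates and phase integration
          calls planted earlywood/latewood genes", {
  sim <- generate_temporal_experiment(300, noise_sd = 0.2, seed = 13)
  calls <- call_temporally_variable(sim$experiment)
  vg <- calls$gene_id[calls$variable]
  tset <- temporal_clusters(sim$experiment, vg, min_module_size = 20)
  pref <- season_preference(tset, sim$experiment$meta)
  # planted 'a' groups peak in June, 'b' groups in September
  truth <- sim$truth
  for (g in pref$june_july) {
    members <- group_membership(tset)
    members <- names(members)[members == g]
    phases <- truth$phase[match(members, truth$gene_id)]
    expect_gte(mean(phases == "earlywood"), 0.9)
  }
  # construct a tissue partition where earlywood genes sit in one group
  tm <- group_membership(tset)
  genes <- names(tm)
  early_true <- truth$gene_id[truth$phase == "earlywood"]
  tissue_groups <- setNames(
    ifelse(genes %in% early_true, "M2a", "M5b"), genes)
  # add background genes so overrepresentation is meaningful
  extra <- setdiff(truth$gene_id, genes)
  tissue_groups <- c(tissue_groups,
                     setNames(rep(c("M2a", "M5b"),
                                  length.out = length(extra)), extra))
  tm_all <- c(tm, setNames(rep("Tnone", length(extra)), extra))
  ph <- phase_integration(tm, tissue_groups,
                          june_july = pref$june_july,
                          september = pref$september)
  called_early <- names(ph$phase)[ph$phase == "earlywood"]
  expect_gt(length(called_early), 0)
  expect_true(all(called_early %in% early_true))
  # earlywood and latewood calls are disjoint by construction
  called_late <- names(ph$phase)[ph$phase == "latewood"]
  expect_length(intersect(called_early, called_late), 0)
  # invariant to the ordering of the cluster label vectors
  ph2 <- phase_integration(tm, tissue_groups,
                           june_july = rev(pref$june_july),
                           september = rev(pref$september))
  expect_identical(ph$phase, ph2$phase)
  expect_error(phase_integration(tm, tissue_groups,
                                 june_july = c("T1a"),
                                 september = c("T1a")),
               "cannot be both")
})
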