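test_that("correlation matrix matches hand computation and flags
          degenerate genes", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8),
             g3 = c(4, 3, 2, 1))
  colnames(m) <- paste0("s", 1:4)
  r <- correlation_matrix(m)
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r["g1", "g2"], 1)     # duplicate up to scale
  expect_equal(r["g1", "g3"], -1)    # negation
  # 3 genes x 4 samples hand computation via the definition
  m2 <- rbind(a = c(1, 3, 2, 5), b = c(2, 1, 4, 3), c = c(5, 4, 1, 1))
  hand <- function(x, y) {
    xc <- x - mean(x); yc <- y - mean(y)
    sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  }
  r2 <- correlation_matrix(m2)
  expect_equal(r2["a", "b"], hand(m2["a", ], m2["b", ]))
  expect_equal(r2["a", "c"], hand(m2["a", ], m2["c", ]))
  expect_equal(r2["b", "c"], hand(m2["b", ], m2["c", ]))
  expect_error(correlation_matrix(rbind(m, g4 = rep(1, 4))), "g4")
})

test_that("soft-threshold adjacency follows |r|^beta", {
  r <- matrix(c(1, 0.5, -1, 0.5, 1, 0, -1, 0, 1), 3, 3)
  a <- soft_threshold_adjacency(r, 14)
  expect_equal(a[1, 3], 1)                 # |r| = 1 stays 1
  expect_equal(a[1, 2], 0.5^14)
  expect_equal(unname(diag(a)), rep(0, 3))
  expect_equal(soft_threshold_adjacency(r, 1)[1, 2], 0.5)
  # monotone decreasing in beta for |r| < 1
  expect_lt(soft_threshold_adjacency(r, 18)[1, 2], a[1, 2])
  expect_error(soft_threshold_adjacency(r, 0.5), ">= 1")
})

test_that("topological overlap matches the formula by brute force", {
  # complete graph: all overlaps are 1
  n <- 5
  a1 <- matrix(1, n, n); diag(a1) <- 0
  t1 <- topological_overlap(a1)
  expect_true(all(abs(t1 - 1) < 1e-12))
  # two nodes with no connection and no shared neighbors
  a2 <- matrix(0, 4, 4)
  a2[1, 2] <- a2[2, 1] <- 1
  a2[3, 4] <- a2[4, 3] <- 1
  expect_equal(topological_overlap(a2)[1, 3], 0)
  # mixed-weight toy against an explicit triple-loop evaluation
  set.seed(8)
  a3 <- matrix(runif(16, 0, 0.9), 4, 4)
  a3 <- (a3 + t(a3)) / 2; diag(a3) <- 0
  got <- topological_overlap(a3)
  k <- rowSums(a3)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    l <- 0
    for (u in 1:4) if (u != i && u != j) l <- l + a3[i, u] * a3[u, j]
    expect_equal(got[i, j],
                 (l + a3[i, j]) / (min(k[i], k[j]) + 1 - a3[i, j]))
  }
  expect_true(all(got >= 0 & got <= 1))
})

test_that("module eigengene is the top principal component", {
  base <- c(1, 5, 2, 8, 3, 9)
  m <- rbind(g1 = base, g2 = 2 * base + 3, g3 = base - 1)
  colnames(m) <- paste0("s", 1:6)
  eig <- module_eigengene(m, rownames(m))
  expect_equal(eig$var_explained, 1)
  expect_equal(abs(cor(eig$eigengene, base)), 1)
  # perfectly anticorrelated halves still explain everything
  m2 <- rbind(g1 = base, g2 = base, g3 = -base, g4 = -base)
  colnames(m2) <- paste0("s", 1:6)
  eig2 <- module_eigengene(m2, rownames(m2))
  expect_equal(eig2$var_explained, 1)
  # maximality: no unit-norm member combination beats the eigengene
  set.seed(9)
  m3 <- matrix(rnorm(8 * 10), 8, 10,
               dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  eig3 <- module_eigengene(m3, rownames(m3))
  s <- t(scale(t(m3)))
  ev <- eigen(crossprod(s), symmetric = TRUE)$values
  expect_equal(eig3$var_explained, ev[1] / sum(ev))
  expect_error(module_eigengene(m3, "g1"), "at least 2")
})

test_that("module splitting respects the sign rule and truth", {
  base <- c(1, 5, 2, 8, 3, 9)
  # with a 2-vs-2 tie the lexicographically first member ("a1") fixes
  # the positive orientation
  m <- rbind(a1 = base + 0.01, a2 = base - 0.02, z1 = -base,
             z2 = -base + 0.05)
  colnames(m) <- paste0("s", 1:6)
  sp <- split_module(m, c("a1", "a2", "z1", "z2"))
  expect_setequal(sp$group_a, c("a1", "a2"))
  expect_setequal(sp$group_b, c("z1", "z2"))
  expect_equal(sp$template_a,
               colMeans(m[c("a1", "a2"), ]))
  # zero correlation lands in group a by the stated tie rule
  e <- c(-1, 1, -1, 1)
  m2 <- rbind(x = c(1, 1, -1, -1), y = e)
  colnames(m2) <- paste0("s", 1:4)
  sp2 <- split_module(m2, c("x", "y"), eigengene = e)
  expect_true("x" %in% sp2$group_a)
  # single-gene group template equals that gene's profile
  expect_equal(split_module(m, c("a1", "z1"))$template_a,
               m["a1", ])
})

test_that("planted modules are recovered with high adjusted Rand
          index", {
  sim <- two_module_sim(noise_sd = 0.2, n_invariant = 100, seed = 7)
  res <- detect_from_sim(sim)
  expect_length(res$mset$modules, 2L)
  expect_gte(module_recovery_ari(sim, res$mset), 0.9)
  # group split matches planted groups up to the a/b label swap
  mapping <- group_label_map(sim, res$mset)
  mm <- res$mset$membership[res$mset$membership$module != "unassigned", ]
  truth <- sim$truth[match(mm$gene_id, sim$truth$gene_id), ]
  agree <- mapping[paste0(mm$module, mm$group)] ==
    paste0(truth$module_id, truth$group)
  expect_gte(mean(agree), 0.95)
})

test_that("noise-only genes stay unassigned", {
  mods <- random_module_specs(1, 30, 30, seed = 2)
  sim <- generate_tissue_experiment(tissue_design(), mods,
                                    n_invariant = 200, noise_sd = 0.2,
                                    tree_effect_sd = 0, seed = 19)
  avg <- average_technical_replicates(sim$experiment)
  noise_genes <- sim$truth$gene_id[sim$truth$class == "invariant"]
  genes <- c(sim$truth$gene_id[sim$truth$class == "module"],
             noise_genes)
  mset <- detect_modules(avg, genes, beta = 14, min_module_size = 20)
  mm <- mset$membership
  frac_unassigned <- mean(
    mm$module[match(noise_genes, mm$gene_id)] == "unassigned")
  expect_gte(frac_unassigned, 0.9)
})

test_that("module detection is invariant to consistent sample
          relabelling", {
  sim <- two_module_sim(noise_sd = 0.2, n_invariant = 0, seed = 5)
  avg <- average_technical_replicates(sim$experiment)
  genes <- rownames(avg$values)
  m1 <- detect_modules(avg, genes, min_module_size = 10)
  set.seed(2)
  perm <- sample(ncol(avg$values))
  x2 <- coex_experiment(avg$values[, perm], avg$meta[perm, ])
  m2 <- detect_modules(x2, genes, min_module_size = 10)
  expect_identical(m1$membership$module, m2$membership$module)
  expect_identical(m1$membership$group, m2$membership$group)
})

test_that("group-tissue correlations point at the planted tissue", {
  # plant a module shifted only in shoot xylem
  prof <- c(0, 0, 1, 0, 0, 0, 0)
  mods <- list(module_spec("M1", 30, 30, prof, amplitude = 2))
  sim <- generate_tissue_experiment(tissue_design(), mods, 0,
                                    noise_sd = 0.2, seed = 23)
  avg <- average_technical_replicates(sim$experiment)
  mset <- detect_modules(avg, rownames(avg$values),
                         min_module_size = 10)
  gt <- group_tissue_correlation(mset, avg$meta)
  # the group matching planted 'a' peaks in xylem_shoot
  mapping <- group_label_map(sim, mset)
  a_lab <- names(mapping)[mapping == "M1a"]
  sub <- gt$group_tissue[gt$group_tissue$group == a_lab, ]
  expect_equal(sub$tissue[which.max(sub$R)], "xylem_shoot")
  expect_true(all(abs(gt$group_tissue$R) <= 1))
  # a template equal to a tissue indicator correlates perfectly
  ind <- as.numeric(avg$meta$tissue == "apex")
  expect_equal(cor(ind, ind), 1)
  # tissue-tissue matrix is a valid correlation matrix
  expect_true(all(abs(gt$tissue_tissue) <= 1 + 1e-12))
  expect_equal(unname(diag(gt$tissue_tissue)),
               rep(1, ncol(gt$tissue_tissue)))
})
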