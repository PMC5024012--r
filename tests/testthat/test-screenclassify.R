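test_that("Anderson-Darling test accepts normal shapes and rejects
          two-point samples", {
  # exact standard-normal quantiles at plotting positions look normal
  q <- qnorm(((1:50) - 0.5) / 50)
  expect_gt(ad_normality_test(q)$p, 0.5)
  # a two-point distribution is grossly non-normal
  expect_lt(ad_normality_test(rep(c(0, 1), 25))$p, 0.01)
  expect_error(ad_normality_test(rep(1, 20)), "degenerate")
  expect_error(ad_normality_test(rnorm(5)), "at least 8")
})

test_that("Anderson-Darling p-values are calibrated under the null", {
  set.seed(11)
  p <- replicate(400, ad_normality_test(rnorm(56))$p)
  # 3 binomial sd around 0.05 at n = 400
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("Levene test matches its definition and the car reference", {
  expect_equal(levene_test(list(c(1, 2, 3), c(1, 2, 3))),
               list(W = 0, p = 1))
  set.seed(21)
  g1 <- rnorm(20, sd = 0.1)
  g2 <- rnorm(20, sd = 10)
  expect_lt(levene_test(list(g1, g2))$p, 0.01)
  # permuting values within a group leaves W unchanged
  lv <- levene_test(list(g1, g2))
  expect_equal(levene_test(list(sample(g1), g2))$W, lv$W)
  # agreement with car::leveneTest for both centres
  y <- c(rnorm(15, sd = 1), rnorm(12, sd = 2), rnorm(18, sd = 0.5))
  grp <- factor(rep(1:3, c(15, 12, 18)))
  ref_mean <- car::leveneTest(y, grp, center = mean)
  got <- levene_test(split(y, grp), center = "mean")
  expect_equal(got$W, ref_mean$`F value`[1])
  expect_equal(got$p, ref_mean$`Pr(>F)`[1])
  ref_med <- car::leveneTest(y, grp, center = median)
  got_med <- levene_test(split(y, grp), center = "median")
  expect_equal(got_med$W, ref_med$`F value`[1])
})

test_that("Levene rejection agrees with a permutation oracle", {
  set.seed(31)
  g1 <- rnorm(20, sd = 1)
  g2 <- rnorm(20, sd = 4)
  obs <- levene_test(list(g1, g2))$W
  pool <- c(g1, g2)
  perm <- replicate(2000, {
    idx <- sample(40, 20)
    levene_test(list(pool[idx], pool[-idx]))$W
  })
  p_perm <- mean(perm >= obs)
  expect_lt(levene_test(list(g1, g2))$p, 0.01)
  expect_lt(p_perm, 0.01)
})

test_that("balanced mixed ANOVA reproduces a by-hand EMS computation on
          a 2x2x2 toy", {
  meta <- expand.grid(dye = c("d1", "d2"), tree = c("t1", "t2"),
                      tissue = c("A", "B"),
                      stringsAsFactors = FALSE)
  y <- c(3, 5, 4, 8, 10, 9, 12, 11)
  # independent longhand computation of every sum of squares
  grand <- mean(y)
  mA <- mean(y[meta$tissue == "A"]); mB <- mean(y[meta$tissue == "B"])
  ss_tissue <- 4 * ((mA - grand)^2 + (mB - grand)^2)
  unit <- paste(meta$tissue, meta$tree)
  mu <- tapply(y, unit, mean)
  mt <- c("A t1" = mA, "A t2" = mA, "B t1" = mB, "B t2" = mB)
  ss_tree <- 2 * sum((mu - mt[names(mu)])^2)
  m1 <- mean(y[meta$dye == "d1"]); m2 <- mean(y[meta$dye == "d2"])
  ss_dye <- 4 * ((m1 - grand)^2 + (m2 - grand)^2)
  cellm <- tapply(y, paste(meta$tissue, meta$dye), mean)
  exp_td <- c("A d1" = mA + m1 - grand, "A d2" = mA + m2 - grand,
              "B d1" = mB + m1 - grand, "B d2" = mB + m2 - grand)
  ss_td <- 2 * sum((cellm - exp_td[names(cellm)])^2)
  ss_res <- sum((y - grand)^2) - ss_tissue - ss_tree - ss_dye - ss_td

  fit <- fit_mixed_anova(y, meta)
  expect_equal(fit$ss, c(ss_tissue, ss_tree, ss_dye, ss_td, ss_res))
  expect_equal(fit$df, c(1, 2, 1, 1, 2))
  expect_equal(fit$F[1], (ss_tissue / 1) / (ss_tree / 2))
  expect_equal(fit$F[3], (ss_dye / 1) / (ss_res / 2))
  expect_equal(fit$p[1],
               pf(fit$F[1], 1, 2, lower.tail = FALSE))
})

test_that("mixed ANOVA agrees with aov's error-stratum decomposition", {
  set.seed(41)
  meta <- expand.grid(dye = c("d1", "d2"), tree = paste0("t", 1:4),
                      tissue = letters[1:7],
                      stringsAsFactors = FALSE)
  y <- rnorm(56) + rep(rnorm(7), each = 8)
  fit <- fit_mixed_anova(y, meta)
  ref <- summary(aov(y ~ tissue * dye +
                       Error(factor(paste(tissue, tree))),
                     data = cbind(meta, y = y)))
  s1 <- ref$`Error: factor(paste(tissue, tree))`[[1]]
  s2 <- ref$`Error: Within`[[1]]
  expect_equal(fit$ss[fit$effect == "tissue"], s1["tissue", "Sum Sq"])
  expect_equal(fit$ss[fit$effect == "tree_in_tissue"],
               s1["Residuals", "Sum Sq"])
  expect_equal(fit$ss[fit$effect == "dye"], s2["dye", "Sum Sq"])
  expect_equal(fit$ss[fit$effect == "tissue_dye"],
               s2["tissue:dye", "Sum Sq"])
  expect_equal(fit$ss[fit$effect == "residual"],
               s2["Residuals", "Sum Sq"])
  # F ratio for tissue uses the tree-within-tissue stratum
  expect_equal(fit$F[1], s1["tissue", "F value"])
  expect_equal(fit$p[1], s1["tissue", "Pr(>F)"])
})

test_that("mixed ANOVA handles degenerate and unbalanced input", {
  meta <- expand.grid(dye = c("d1", "d2"), tree = c("t1", "t2"),
                      tissue = c("A", "B"),
                      stringsAsFactors = FALSE)
  fit <- fit_mixed_anova(rep(2, 8), meta)
  expect_equal(fit$ss, rep(0, 5))
  expect_true(all(fit$p[c(1, 3, 4)] == 1))
  expect_error(fit_mixed_anova(rnorm(7), meta[-1, ]), "unbalanced")
})

test_that("SS decomposition is exact for the balanced design", {
  set.seed(51)
  sim <- two_module_sim(n_invariant = 20, noise_sd = 0.3)
  meta <- sim$experiment$meta
  for (g in sample(rownames(sim$experiment$values), 10)) {
    y <- sim$experiment$values[g, ]
    fit <- fit_mixed_anova(y, meta)
    expect_equal(sum(fit$ss), sum((y - mean(y))^2), tolerance = 1e-12)
    expect_equal(sum(fit$df), length(y) - 1)
  }
})

test_that("a strongly shifted gene is called with very small tissue p", {
  mods <- list(module_spec("M1", 2, 2, c(3, 0, 0, 0, 0, 0, 0),
                           amplitude = 1))
  sim <- generate_tissue_experiment(tissue_design(), mods, 1,
                                    noise_sd = 0.1, seed = 13)
  fit <- fit_mixed_anova(sim$experiment$values["M1a_001", ],
                         sim$experiment$meta)
  expect_lt(fit$p[1], 1e-6)
})

test_that("classification recovers planted invariant and variable
          genes", {
  sim <- two_module_sim(noise_sd = 0.2, n_invariant = 100,
                        n_violators = 0, seed = 7)
  cls <- classify_genes(sim$experiment)
  truth <- sim$truth
  cat_of <- cls$classification$category[
    match(truth$gene_id, cls$classification$gene_id)]
  inv_ok <- sum(truth$class == "invariant" & cat_of == "invariant")
  var_ok <- sum(truth$class == "module" &
                  cat_of %in% c("variable_high", "variable_low"))
  expect_gte(inv_ok, 95)
  expect_gte(var_ok, 95)
  # every tested gene lands in exactly one category
  tested <- cls$classification$category != "excluded"
  expect_true(all(cls$classification$category[tested] %in%
                    c("invariant", "variable_low", "variable_high")))
})

test_that("planted assumption violators are screened out with the right
          reasons", {
  sim <- two_module_sim(noise_sd = 0.2, n_invariant = 100,
                        n_violators = 10, seed = 7)
  cls <- classify_genes(sim$experiment)
  truth <- sim$truth
  scr <- cls$screen[match(truth$gene_id, cls$screen$gene_id), ]
  dye_v <- truth$violator_type %in% "dye_effect"
  expect_true(all(scr$status[dye_v] == "excluded"))
  expect_true(all(grepl("dye_effect", scr$reason[dye_v])))
  ht_v <- truth$violator_type %in% "heavy_tail"
  expect_gte(mean(scr$status[ht_v] == "excluded"), 0.8)
})

test_that("alpha_variable = 1 leaves no gene invariant", {
  sim <- two_module_sim(n_invariant = 30, seed = 3)
  cls <- classify_genes(sim$experiment, alpha_variable = 1,
                        alpha_high = 1e-4)
  expect_false(any(cls$classification$category == "invariant"))
})

test_that("tissue p-values are calibrated under the global null", {
  mods <- random_module_specs(1, 4, 4, seed = 1)  # discarded below
  sim <- generate_tissue_experiment(tissue_design(), mods,
                                    n_invariant = 1000,
                                    noise_sd = 0.2,
                                    tree_effect_sd = 0, seed = 17)
  cls <- classify_genes(sim$experiment, screen_adjust = "BH")
  null_genes <- sim$truth$gene_id[sim$truth$class == "invariant"]
  p <- cls$classification$tissue_p[
    match(null_genes, cls$classification$gene_id)]
  p <- p[!is.na(p)]
  for (alpha in c(0.01, 0.05)) {
    tol <- 3 * sqrt(alpha * (1 - alpha) / length(p))
    expect_lt(abs(mean(p < alpha) - alpha), tol)
  }
})
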