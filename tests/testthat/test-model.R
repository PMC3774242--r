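two_qtl_cfg <- function(seed, n = 343) {
  # two unlinked QTLs at 20% variance each for WUE
  ril_sim_config(
    seed = seed, n_lines = n,
    qtl = data.frame(chrom = c("1", "3"), pos = c(30, 50),
                     eff_wue = 2 * sqrt(0.2), eff_ft = 0),
    polygenic_sd = c(wue = 0, ft = 0),
    residual_sd = c(wue = sqrt(0.6), ft = 1),
    trait_location = c(wue = 0, ft = 0),
    trait_scale = c(wue = 1, ft = 1))
}

test_that("stepwise selection returns an empty model under infinite penalty", {
  sim <- simulate_ril_panel(two_qtl_cfg(seed = 71, n = 100))
  pr <- genotype_probabilities(sim$panel, build_grid(sim$map, 2))
  m <- stepwise_additive(pr, sim$panel$pheno$wue, penalty = 1e6)
  expect_equal(nrow(m), 0)
  expect_equal(attr(m, "model_lod"), 0)
  expect_error(stepwise_additive(pr, sim$panel$pheno$wue, penalty = -1),
               "positive")
})

test_that("stepwise selection stays empty on pure-noise phenotypes", {
  n_nonempty <- 0
  for (s in 1:20) {
    sim <- simulate_ril_panel(
      ril_sim_config(seed = 100 + s, n_lines = 200,
                     qtl = data.frame(chrom = "1", pos = 10,
                                      eff_wue = 0, eff_ft = 0),
                     polygenic_sd = c(wue = 0, ft = 0),
                     residual_sd = c(wue = 1, ft = 1)))
    pr <- genotype_probabilities(sim$panel, build_grid(sim$map, 2))
    y <- sim$panel$pheno$wue
    thr <- permutation_threshold(pr, y, n_perm = 300, alpha = 0.05,
                                 seed = s)
    m <- stepwise_additive(pr, y, penalty = as.numeric(thr))
    if (nrow(m) > 0) n_nonempty <- n_nonempty + 1
  }
  # expected false-positive rate ~5%; 4+ of 20 has probability < 2%
  expect_lte(n_nonempty, 3)
})

test_that("two unlinked QTLs are recovered near their true positions", {
  hits <- 0
  for (s in 1:10) {
    sim <- simulate_ril_panel(two_qtl_cfg(seed = 200 + s))
    pr <- genotype_probabilities(sim$panel, build_grid(sim$map, 2))
    y <- sim$panel$pheno$wue
    thr <- permutation_threshold(pr, y, n_perm = 300, alpha = 0.05,
                                 seed = s)
    m <- stepwise_additive(pr, y, penalty = as.numeric(thr))
    ok1 <- any(m$chrom == "1" & abs(m$pos - 30) <= 10)
    ok2 <- any(m$chrom == "3" & abs(m$pos - 50) <= 10)
    if (ok1 && ok2) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("position refinement is monotone and a fixed point at the optimum", {
  sim <- simulate_ril_panel(two_qtl_cfg(seed = 303))
  pr <- genotype_probabilities(sim$panel, build_grid(sim$map, 2))
  y <- sim$panel$pheno$wue
  # mis-initialize both QTLs ~10 cM off, at actual grid points
  near <- function(ch, target) {
    cand <- pr$grid$pos[pr$grid$chrom == ch]
    cand[which.min(abs(cand - target))]
  }
  bad <- qtl_model_at(pr$grid, c("1", "3"), c(near("1", 40), near("3", 60)))
  m0 <- fit_model(bad, pr, y)
  m1 <- refine_positions(m0, pr, y)
  expect_gte(attr(m1, "model_lod"), attr(m0, "model_lod") - 1e-9)
  # refined model is a fixed point
  m2 <- refine_positions(m1, pr, y)
  expect_equal(m2$pos, m1$pos)
  expect_equal(m2$chrom, m1$chrom)
})

test_that("refining a one-QTL model reproduces the scan argmax", {
  sim <- simulate_ril_panel(two_qtl_cfg(seed = 87))
  pr <- genotype_probabilities(sim$panel, build_grid(sim$map, 2))
  y <- sim$panel$pheno$wue
  prof <- scan_trait(pr, y)
  pk <- attr(prof, "peak")
  start_pos <- pr$grid$pos[pr$grid$chrom == "5"][5]  # far from any QTL
  m0 <- fit_model(qtl_model_at(pr$grid, "5", start_pos), pr, y)
  m1 <- refine_positions(m0, pr, y)
  expect_equal(attr(m1, "grid_index"), pk$index)
})

test_that("fitted models recover simulated effect and PVE", {
  cfg <- ril_sim_config(
    seed = 99, n_lines = 2000,
    qtl = data.frame(chrom = "2", pos = 40, eff_wue = 1, eff_ft = 0),
    polygenic_sd = c(wue = 0, ft = 0),
    residual_sd = c(wue = sqrt(0.75), ft = 1),
    trait_location = c(wue = 0, ft = 0),
    trait_scale = c(wue = 1, ft = 1))
  sim <- simulate_ril_panel(cfg)
  pr <- genotype_probabilities(sim$panel, build_grid(sim$map, 2))
  y <- sim$panel$pheno$wue
  prof <- scan_trait(pr, y)
  pk <- attr(prof, "peak")
  m <- fit_model(qtl_model_at(pr$grid, pk$chrom, pk$pos), pr, y)
  expect_equal(m$effect, 1, tolerance = 0.1)
  expect_equal(m$pve, 25, tolerance = 0.15)  # relative: 25 +/- ~3.7
  # empty model fits cleanly
  m0 <- fit_model(qtl_model_at(pr$grid, character(0), numeric(0)), pr, y)
  expect_equal(nrow(m0), 0)
  expect_equal(attr(m0, "model_lod"), 0)
})

test_that("collinear dosage columns get zero drop-one LOD with a warning", {
  sim <- simulate_ril_panel(two_qtl_cfg(seed = 55, n = 120))
  pr <- genotype_probabilities(sim$panel, build_grid(sim$map, 2))
  y <- sim$panel$pheno$wue
  p3 <- pr$grid$pos[pr$grid$chrom == "1"][3]
  expect_warning(
    m <- fit_model(qtl_model_at(pr$grid, c("1", "1"), c(p3, p3)), pr, y),
    "collinear")
  expect_equal(m$lod[2], 0)
})
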