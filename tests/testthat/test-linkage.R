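make_probs <- function(seed = 21, n = 343, ...) {
  sim <- simulate_ril_panel(ril_sim_config(seed = seed, n_lines = n, ...))
  grid <- build_grid(sim$map, 2)
  list(sim = sim,
       probs = genotype_probabilities(sim$panel, grid))
}

test_that("grid construction subdivides gaps without exceeding the step", {
  m <- genetic_map(c("a", "b"), c("1", "1"), c(0, 10))
  g <- build_grid(m, 2)
  expect_equal(g$pos, c(0, 2, 4, 6, 8, 10))
  m2 <- genetic_map(c("a", "b"), c("1", "1"), c(0, 3))
  g2 <- build_grid(m2, 2)
  expect_equal(g2$pos, c(0, 1.5, 3))
  m3 <- genetic_map("only", "2", 7)
  g3 <- build_grid(m3, 2)
  expect_equal(g3$pos, 7)
  expect_true(all(g3$is_marker))
  expect_error(build_grid(m, 0), "positive")
  # every true marker retained, gaps never exceed the step
  sim <- simulate_ril_panel(ril_sim_config(seed = 1))
  gg <- build_grid(sim$map, 2)
  expect_true(all(sim$map$pos %in% gg$pos[gg$is_marker]))
  for (ch in unique(gg$chrom)) {
    expect_lte(max(diff(gg$pos[gg$chrom == ch])), 2 + 1e-9)
  }
})

test_that("genotype probabilities are exact at markers and symmetric between", {
  mp <- make_probs(seed = 31, n = 40)
  P <- mp$probs$P
  grid <- mp$probs$grid
  geno <- mp$sim$panel$geno
  at_mk <- which(grid$is_marker)
  for (j in at_mk[1:20]) {
    expect_equal(unname(P[, j]), unname(as.numeric(geno[, grid$marker[j]])))
  }
  expect_true(all(P >= 0 & P <= 1))
})

test_that("flank conditioning matches the two-state chain oracle", {
  # two markers 20 cM apart, pseudo-marker at the midpoint
  cfg <- ril_sim_config(n_lines = 30, chr_lengths = 20,
                        n_markers_per_chrom = 2L,
                        marker_positions = list(c(0, 20)),
                        qtl = data.frame(chrom = "1", pos = 0,
                                         eff_wue = 0, eff_ft = 0),
                        seed = 8)
  sim <- simulate_ril_panel(cfg)
  grid <- build_grid(sim$map, 10)
  pr <- genotype_probabilities(sim$panel, grid)
  mid <- which(!grid$is_marker)
  expect_length(mid, 1)
  g <- sim$panel$geno
  for (i in seq_len(nrow(g))) {
    expect_equal(unname(pr$P[i, mid]),
                 chain_midpoint_oracle(g[i, 1], g[i, 2], 10, 10),
                 tolerance = 1e-12)
  }
  # discordant flanks at the exact midpoint give exactly 0.5
  disc <- which(g[, 1] != g[, 2])
  if (length(disc)) expect_equal(unname(pr$P[disc, mid]),
                                 rep(0.5, length(disc)))
  # concordant flanks: above 0.5 for AA, below for BB
  expect_true(all(pr$P[g[, 1] == 1 & g[, 2] == 1, mid] > 0.5))
  expect_true(all(pr$P[g[, 1] == 0 & g[, 2] == 0, mid] < 0.5))
})

test_that("a line missing a whole chromosome falls back to 0.5 with warning", {
  sim <- simulate_ril_panel(ril_sim_config(seed = 13, n_lines = 12,
                                           chr_lengths = c(30, 30),
                                           n_markers_per_chrom = c(4L, 4L)))
  sim$panel$geno[1, sim$map$marker[sim$map$chrom == "1"]] <- NA
  grid <- build_grid(sim$map, 2)
  expect_warning(pr <- genotype_probabilities(sim$panel, grid),
                 "no informative")
  expect_true(all(pr$P[1, pr$grid$chrom == "1"] == 0.5))
  expect_true(all(pr$P[1, pr$grid$chrom == "2"] %in% c(0, 1) |
                    !pr$grid$is_marker[pr$grid$chrom == "2"]))
})

test_that("scan handles degenerate phenotypes", {
  mp <- make_probs(seed = 41, n = 60)
  expect_warning(prof <- scan_trait(mp$probs, rep(1, 60)), "variance")
  expect_true(all(prof$lod == 0))
  # phenotype equal to the dosage at one marker: argmax there, huge LOD
  j <- which(mp$probs$grid$is_marker)[10]
  y <- mp$probs$P[, j]
  prof2 <- scan_trait(mp$probs, y)
  pk <- attr(prof2, "peak")
  expect_equal(pk$index, j)
  expect_gt(attr(prof2, "max_lod"), 100)
})

test_that("scan LOD equals the direct least-squares oracle at markers", {
  mp <- make_probs(seed = 51)
  y <- mp$sim$panel$pheno$wue
  prof <- scan_trait(mp$probs, y)
  at_mk <- which(mp$probs$grid$is_marker)
  for (j in sample(at_mk, 25)) {
    x <- as.numeric(mp$sim$panel$geno[, mp$probs$grid$marker[j]])
    rss0 <- sum(resid(lm(y ~ 1))^2)
    rss1 <- sum(resid(lm(y ~ x))^2)
    expect_equal(prof$lod[j], (length(y) / 2) * log10(rss0 / rss1),
                 tolerance = 1e-8)
  }
})

test_that("permutation threshold boundaries and determinism", {
  mp <- make_probs(seed = 61, n = 80)
  y <- mp$sim$panel$pheno$ft
  t1 <- permutation_threshold(mp$probs, y, n_perm = 150, alpha = 1,
                              seed = 5)
  expect_equal(as.numeric(t1), min(attr(t1, "maxima")))
  t2 <- permutation_threshold(mp$probs, y, n_perm = 150, alpha = 0.05,
                              seed = 7)
  t3 <- permutation_threshold(mp$probs, y, n_perm = 150, alpha = 0.05,
                              seed = 7)
  expect_identical(as.numeric(t2), as.numeric(t3))
  expect_error(permutation_threshold(mp$probs, y, n_perm = 50), "n_perm")
  expect_error(permutation_threshold(mp$probs, y, n_perm = 150, alpha = 0),
               "alpha")
})
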