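test_that("Nei per-SNP FST matches the closed form on a frequency grid", {
  # every (p1, p2) pair on a 0.1 grid, 10 accessions per class
  grid <- expand.grid(x1 = 0:10, x2 = 0:10)
  panel <- panel_from_counts(grid$x1, 10, grid$x2, 10)
  res <- per_snp_fst(panel, estimator = "nei")
  p1 <- grid$x1 / 10; p2 <- grid$x2 / 10
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  expected <- ifelse(ht > 0, (ht - hs) / ht, NA_real_)
  expect_equal(res$per_snp$fst, expected, tolerance = 1e-12)
  # the worked example: 0.2 vs 0.8 -> 0.36; equal freqs -> 0; fixed -> 1
  i <- which(p1 == 0.2 & p2 == 0.8)
  expect_equal(res$per_snp$fst[i], 0.36, tolerance = 1e-12)
  expect_true(all(abs(res$per_snp$fst[p1 == p2 & ht > 0]) < 1e-12))
  expect_equal(res$per_snp$fst[p1 == 1 & p2 == 0], 1)
  # monomorphic SNPs are skipped and counted
  expect_equal(res$n_skipped, 2)  # (0,0) and (1,1)
})

test_that("WC and Nei agree in sign and WC stabilizes with sample size", {
  set.seed(41)
  for (n in c(100, 400)) {
    ps <- simulate_accession_panel(
      panel_sim_config(seed = n, n_accessions = n, n_labeled = n,
                       focal_allele_frequency = 0.5, n_window_snps = 2,
                       n_genome_snps = 4000, fst_between_classes = 0.1,
                       n_geo_clusters = 2, n_null_clusters = 0))
    nei <- genomewide_fst(ps$panel, ps$truth$labels, "nei")
    wc <- genomewide_fst(ps$panel, ps$truth$labels, "wc")
    expect_gt(nei, 0)
    expect_gt(wc, 0)
    if (n == 100) first_wc <- wc else {
      # both sample sizes estimate the same differentiation
      expect_lt(abs(wc - first_wc), 0.05)
    }
  }
})

test_that("subset mean equals mean of the subset's per-SNP values", {
  ps <- simulate_accession_panel(
    panel_sim_config(seed = 14, n_accessions = 80, n_labeled = 80,
                     n_window_snps = 2, n_genome_snps = 300,
                     fst_between_classes = 0.1, n_geo_clusters = 2,
                     n_null_clusters = 0))
  res <- per_snp_fst(ps$panel, ps$truth$labels)
  sub <- which(ps$panel$snps$chrom == "2")
  sub_panel <- snp_panel(ps$panel$geno[, sub], ps$panel$snps[sub, ],
                         ps$panel$accessions)
  res_sub <- per_snp_fst(sub_panel, ps$truth$labels)
  expect_equal(res_sub$mean_fst, mean(res$per_snp$fst[sub], na.rm = TRUE))
})

test_that("thinning keeps the greedy 50-kb spacing", {
  pos <- c(0, 10000, 49000, 50000, 120000)
  geno <- matrix(rep(c(0L, 1L), length.out = 4 * 5), 4)
  snps <- data.frame(id = paste0("s", 1:5), chrom = "1", pos = pos)
  acc <- data.frame(id = paste0("a", 1:4),
                    class = c("functional", "functional",
                              "nonfunctional", "nonfunctional"))
  p <- snp_panel(geno, snps, acc)
  th <- thin_snps(p, 50000)
  expect_equal(th$snps$pos, c(0, 50000, 120000))
  # already sparse panels are unchanged
  p2 <- snp_panel(geno[, 1:3], data.frame(id = paste0("s", 1:3),
                                          chrom = "1",
                                          pos = c(0, 60000, 130000)), acc)
  expect_equal(thin_snps(p2, 50000)$snps$pos, p2$snps$pos)
  # duplicated positions: first kept
  p3 <- snp_panel(geno[, 1:3], data.frame(id = paste0("s", 1:3),
                                          chrom = "1",
                                          pos = c(100, 100, 60000)), acc)
  expect_equal(thin_snps(p3, 50000)$snps$id, c("s1", "s3"))
})

test_that("regional Ht/Hs FST reuses the per-SNP closed form", {
  # one cluster, every SNP at 0.2 vs 0.8 -> 0.36
  panel <- panel_from_counts(rep(2L, 30), 10, rep(8L, 30), 10,
                             spacing = 60000L)
  panel$accessions$cluster <- 1L
  reg <- regional_fst(panel, interval_bp = 50000)
  expect_equal(reg$fst, 0.36, tolerance = 1e-12)
  expect_false(reg$skipped)
  # identical class frequencies -> 0
  p0 <- panel_from_counts(rep(5L, 10), 10, rep(5L, 10), 10,
                          spacing = 60000L)
  p0$accessions$cluster <- 1L
  expect_equal(regional_fst(p0)$fst, 0, tolerance = 1e-12)
  # single-class cluster skipped with flag
  p1 <- panel
  p1$accessions$cluster <- c(rep(1L, 18), 2L, 2L)
  reg1 <- regional_fst(p1)
  expect_true(reg1$skipped[reg1$cluster == 2])
})

test_that("differentiated clusters are detected and null clusters are not", {
  ps <- simulate_accession_panel(
    panel_sim_config(seed = 33, n_accessions = 660, n_labeled = 660,
                     focal_allele_frequency = 0.5, n_window_snps = 2,
                     n_genome_snps = 3000, snp_spacing_bp = 60000,
                     fst_between_classes = 0.15,
                     n_geo_clusters = 11, n_null_clusters = 1))
  reg <- regional_fst(ps$panel, ps$truth$labels,
                      clusters = ps$panel$accessions$cluster,
                      interval_bp = 50000)
  null_cl <- ps$truth$null_clusters
  diff_fst <- reg$fst[!reg$cluster %in% null_cl & !reg$skipped]
  null_fst <- reg$fst[reg$cluster %in% null_cl & !reg$skipped]
  # elevated differentiation in exactly the 10 differentiated clusters
  expect_true(all(diff_fst > max(null_fst)))
})

test_that("permutation null p-values respect the +1 convention and seed", {
  ps <- simulate_accession_panel(
    panel_sim_config(seed = 19, n_accessions = 100, n_labeled = 100,
                     n_window_snps = 2, n_genome_snps = 600,
                     fst_between_classes = 0.15, n_geo_clusters = 2,
                     n_null_clusters = 0))
  a <- permutation_null(ps$panel, ps$truth$labels, K = 199, seed = 4)
  b <- permutation_null(ps$panel, ps$truth$labels, K = 199, seed = 4)
  expect_identical(a$resamples, b$resamples)
  expect_gt(a$p_value, 0)
  expect_lte(a$p_value, 1)
  # strong differentiation drives p to the floor
  expect_equal(a$p_value, 1 / 200)
  expect_error(permutation_null(ps$panel, ps$truth$labels, K = 50), "K")
})

test_that("frequency-matched bootstrap filters by MAF and reports shortfalls", {
  ps <- simulate_accession_panel(
    panel_sim_config(seed = 23, n_accessions = 150, n_labeled = 150,
                     focal_allele_frequency = 0.3, n_window_snps = 2,
                     n_genome_snps = 4000, fst_between_classes = 0.05,
                     n_geo_clusters = 2, n_null_clusters = 0))
  lab <- ps$truth$labels
  f <- mean(lab == "functional")
  f <- min(f, 1 - f)
  bn <- frequency_matched_bootstrap(ps$panel, lab, n_snps = 100,
                                    tolerance = 0.02, K = 150, seed = 2)
  maf <- pmin(colMeans(ps$panel$geno), 1 - colMeans(ps$panel$geno))
  expect_gte(bn$n_matched, 100)
  # every division SNP drawn has MAF within the tolerance of the focal freq
  drawn_maf <- maf[match(bn$snps_drawn, ps$panel$snps$id)]
  expect_true(all(abs(drawn_maf - f) <= 0.02))
  expect_equal(bn$K, 150)
  # vacuous tolerance matches every polymorphic SNP
  bn2 <- frequency_matched_bootstrap(ps$panel, lab, n_snps = 100,
                                     tolerance = 0.5, K = 100, seed = 2)
  expect_equal(bn2$n_matched, sum(maf > 0))
  # shortfall errors name the deficit
  expect_error(
    frequency_matched_bootstrap(ps$panel, lab, n_snps = 100000,
                                tolerance = 0.02, seed = 2),
    "match the focal frequency")
})

test_that("heavily missing SNPs are skipped", {
  panel <- panel_from_counts(c(2L, 5L), 10, c(8L, 5L), 10)
  panel$geno[1:6, 2] <- NA  # 30% missing at SNP 2
  res <- per_snp_fst(panel, max_missing = 0.2)
  expect_true(is.na(res$per_snp$fst[2]))
  expect_equal(res$n_used, 1)
})
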